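test_that("simulation is seed-deterministic and validates inputs", {
  tr <- balanced_tree(8)
  s1 <- simulate_repertoire(tr, 20, 0.1, seed = 7)
  s2 <- simulate_repertoire(tr, 20, 0.1, seed = 7)
  expect_identical(unclass(s1$matrix), unclass(s2$matrix))
  expect_identical(s1$truth$units, s2$truth$units)
  s3 <- simulate_repertoire(tr, 20, 0.1, seed = 8)
  expect_false(identical(unclass(s1$matrix), unclass(s3$matrix)))
  expect_error(simulate_repertoire(tr, 5, 1.2, seed = 1), "loss_prob")
  expect_error(balanced_tree(12), "power of 2")
})

test_that("lossless histories are recovered exactly", {
  tr <- balanced_tree(16)
  sim <- simulate_repertoire(tr, 50, 0, seed = 3)
  # presence is exactly the clade below the gain
  r <- simulation_recovery(sim)
  expect_equal(r$rate, 1)
  expect_equal(r$n_scored, 50L)
  for (u in names(sim$truth$units)) {
    expect_length(sim$truth$units[[u]]$loss_branches, 0L)
  }
})

test_that("certain loss confines survival to terminal-branch gains", {
  tr <- balanced_tree(8)
  sim <- simulate_repertoire(tr, 30, 1, seed = 5)
  for (u in names(sim$truth$units)) {
    tu <- sim$truth$units[[u]]
    if (length(tu$present_leaves)) {
      # only a gain on a terminal branch survives, as its own single leaf
      expect_equal(tu$present_leaves, tu$gain_branch)
    }
  }
})

test_that("simulated recovery agrees with the closed-form expectation", {
  tr <- balanced_tree(32)
  exp_rec <- expected_gain_recovery(tr, 0.05)
  expect_equal(expected_gain_recovery(tr, 0)$recovery, 1)
  expect_gt(exp_rec$recovery_nonempty, exp_rec$recovery)
  sim <- simulate_repertoire(tr, 200, 0.05, seed = 1)
  r <- simulation_recovery(sim)
  # binomial check at 4 sigma around the DP expectation
  sd4 <- 4 * sqrt(exp_rec$recovery_nonempty *
                    (1 - exp_rec$recovery_nonempty) / r$n_scored)
  expect_lt(abs(r$rate - exp_rec$recovery_nonempty), sd4)
})

test_that("architecture simulation respects the head-domain constraints", {
  tr <- balanced_tree(8)
  sim <- simulate_repertoire(tr, 10, 0.1, seed = 21)
  alphabet <- c("IQ", "PH", "MyTH4", "FERM", "SH3_1")

  frozen <- simulate_architectures(sim$truth, alphabet,
                                   mutation_rates = list(insert = 0,
                                                         delete = 0,
                                                         duplicate = 0),
                                   seed = 2)
  roots <- attr(frozen, "root_architectures")
  tab <- do.call(rbind, frozen)
  # zero rates: every emitted protein equals its unit's root architecture
  for (u in names(roots)) {
    sub <- tab[grepl(paste0("^", u, "_"), tab$protein_id), ]
    for (p in unique(sub$protein_id)) {
      expect_equal(sub$domain_name[sub$protein_id == p],
                   rep(roots[[u]]$tokens$name, roots[[u]]$tokens$count))
    }
  }

  mutated <- simulate_architectures(sim$truth, alphabet, seed = 2)
  tab2 <- do.call(rbind, mutated)
  # exactly one motor domain per protein under any rates
  heads <- tapply(tab2$domain_name == "Myosin_head", tab2$protein_id, sum)
  expect_true(all(heads == 1L))
  # determinism
  mutated2 <- simulate_architectures(sim$truth, alphabet, seed = 2)
  expect_identical(lapply(mutated, unclass), lapply(mutated2, unclass))
  expect_error(simulate_architectures(sim$truth, c("Myosin_head", "IQ")),
               "must not contain the head")
})

test_that("emitted simple6 tables round-trip through the reader", {
  tr <- balanced_tree(4)
  sim <- simulate_repertoire(tr, 5, 0.1, seed = 13)
  tabs <- simulate_architectures(sim$truth, c("IQ", "PH", "FERM"), seed = 4)
  dir <- withr::local_tempdir()
  write_annotation_tables(tabs, dir)
  for (sp in names(tabs)) {
    back <- read_domain_annotations(
      file.path(dir, paste0(sp, ".domains.tsv")), dialect = "simple6")
    expect_equal(back$protein_id, tabs[[sp]]$protein_id)
    expect_equal(back$domain_accession, tabs[[sp]]$domain_accession)
    expect_equal(back$domain_name, tabs[[sp]]$domain_name)
    expect_equal(back$env_start, as.numeric(tabs[[sp]]$env_start))
    expect_equal(back$env_end, as.numeric(tabs[[sp]]$env_end))
    expect_equal(back$species_id, tabs[[sp]]$species_id)
  }
})

test_that("simulated gene trees recover unit memberships", {
  tr <- balanced_tree(16)
  ok <- 0L; total <- 0L
  for (seed in 1:5) {
    sim <- simulate_repertoire(tr, 10, 0.15, seed = seed)
    gt <- simulate_gene_tree(sim$truth, seed = seed + 100)
    asg <- assign_by_clade(gt$tree, gt$seeds)
    truth_class <- sub("^.*\\|(U[0-9]+)_.*$", "\\1", asg$leaf_label)
    ok <- ok + sum(asg$class_id == truth_class & asg$status == "clear")
    total <- total + nrow(asg)
  }
  expect_gte(ok / total, 0.99)

  # determinism of the emitted newick
  sim <- simulate_repertoire(tr, 6, 0.1, seed = 2)
  g1 <- simulate_gene_tree(sim$truth, seed = 9)
  g2 <- simulate_gene_tree(sim$truth, seed = 9)
  expect_identical(g1$newick, g2$newick)
})

test_that("a single surviving unit yields a tree congruent with the species tree", {
  tr <- balanced_tree(8)
  sim <- simulate_repertoire(tr, 1, 0, seed = 17)
  tu <- sim$truth$units[[1]]
  gt <- simulate_gene_tree(sim$truth, seed = 1)
  phy <- gt$tree$phylo
  expect_setequal(phy$tip.label,
                  paste0(tu$present_leaves, "|U001_", tu$present_leaves))
  if (length(tu$present_leaves) >= 4) {
    pruned <- ape::keep.tip(tr, tu$present_leaves)
    phy2 <- phy
    phy2$tip.label <- sub("\\|.*$", "", phy2$tip.label)
    expect_equal(ape::dist.topo(ape::unroot(pruned), ape::unroot(phy2)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("the lossless pipeline reproduces the simulated matrix end-to-end", {
  tr <- balanced_tree(8)
  sim <- simulate_repertoire(tr, 12, 0, seed = 31)
  tabs <- simulate_architectures(sim$truth, c("IQ", "PH", "FERM", "MyTH4"),
                                 mutation_rates = list(insert = 0,
                                                       delete = 0,
                                                       duplicate = 0),
                                 seed = 31)
  dir <- withr::local_tempdir()
  write_annotation_tables(tabs, dir)
  hits <- do.call(rbind, lapply(list.files(dir, full.names = TRUE),
                                read_domain_annotations,
                                dialect = "simple6"))
  recs <- extract_target_proteins(hits, "PF00063")
  gt <- simulate_gene_tree(sim$truth, seed = 31)
  asg <- assign_by_clade(gt$tree, gt$seeds)
  taxonomy <- stats::setNames(tr$tip.label, tr$tip.label)
  m <- build_presence_matrix(asg, taxonomy, unclear_policy = "as_absent",
                             granularity = "unit")
  obs <- unclass(m)[rownames(sim$matrix), colnames(sim$matrix)]
  expect_equal(obs, unclass(sim$matrix), ignore_attr = TRUE)
  rec <- dollo_reconstruct(m, tr)
  for (u in names(sim$truth$units)) {
    expect_equal(unname(rec$gain[u]), sim$truth$units[[u]]$gain_branch)
    expect_length(rec$losses[[u]], 0L)
  }
})
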