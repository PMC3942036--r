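pfam_rows <- c(
  "# pfam_scan output",
  "sp1|P1   5 120   3 130 PF00063.24 Myosin_head Domain 1 128 130 250.3 1.2e-75 1 CL0023",
  "sp1|P1 150 200 148 205 PF00612.27 IQ          Motif  1  21  21  30.1 0.0015  1 No_clan",
  "sp2|P9  10  80   8  85 PF00069.26 Pkinase     Domain 1  64 260  55.0 2e-10   0 CL0016"
)

test_that("pfamscan15 rows parse field-by-field, with species from labels", {
  hits <- read_domain_annotations(pfam_rows, dialect = "pfamscan15")
  expect_equal(nrow(hits), 3L)
  expect_equal(hits$protein_id, c("sp1|P1", "sp1|P1", "sp2|P9"))
  expect_equal(hits$species_id, c("sp1", "sp1", "sp2"))
  expect_equal(hits$domain_accession, c("PF00063", "PF00612", "PF00069"))
  expect_equal(hits$domain_name, c("Myosin_head", "IQ", "Pkinase"))
  expect_equal(hits$env_start, c(3, 148, 8))
  expect_equal(hits$env_end, c(130, 205, 85))
  expect_equal(hits$bit_score, c(250.3, 30.1, 55.0))
  expect_equal(hits$e_value, c(1.2e-75, 0.0015, 2e-10))
  expect_equal(hits$clan_accession, c("CL0023", NA, "CL0016"))
  expect_equal(hits$significant, c(TRUE, TRUE, FALSE))
})

test_that("comment-only input gives an empty hit table", {
  hits <- read_domain_annotations(c("# header", "", "# more"),
                                  dialect = "pfamscan15")
  expect_equal(nrow(hits), 0L)
})

test_that("malformed rows are reported with their line number", {
  bad <- c(pfam_rows, "sp3|P2 10 80 90 85 PF00069.26 Pkinase Domain 1 64 260 55.0 2e-10 1 CL0016")
  expect_error(read_domain_annotations(bad, dialect = "pfamscan15"),
               "line 5.*env_start")
  short <- c(pfam_rows[1:2], "sp1|P1 1 2 3")
  expect_error(read_domain_annotations(short, dialect = "pfamscan15"),
               "line 3")
  expect_error(read_domain_annotations(sub("2e-10", "-1e-3", pfam_rows),
                                       dialect = "pfamscan15"),
               "negative e_value")
})

test_that("simple6 dialect parses and species maps resolve pfamscan ids", {
  s6 <- c("spA\tp1\tPF00063\tMyosin_head\t1\t700",
          "spA\tp1\tPF00612\tIQ\t710\t730")
  hits <- read_domain_annotations(s6, dialect = "simple6")
  expect_equal(hits$species_id, c("spA", "spA"))
  expect_equal(hits$protein_id, c("p1", "p1"))
  expect_true(all(hits$significant))

  rows <- sub("sp1\\|", "", pfam_rows[2:3])
  hits2 <- read_domain_annotations(
    rows, dialect = "pfamscan15",
    species_map = data.frame(protein_id = "P1", species_id = "Homo"))
  expect_equal(unique(hits2$species_id), "Homo")
  expect_error(read_domain_annotations(rows, dialect = "pfamscan15",
                                       species_map = c(Px = "y")),
               "no species mapping")
})

test_that("extract_target_proteins keeps exactly the motor-bearing genes", {
  h <- function(p, acc, s1, sig = TRUE) {
    data.frame(protein_id = p, species_id = "sp", domain_accession = acc,
               domain_name = acc, env_start = s1, env_end = s1 + 50,
               bit_score = 100, e_value = 1e-20, clan_accession = NA,
               significant = sig, stringsAsFactors = FALSE)
  }
  hits <- rbind(h("A", "PF00063", 1), h("A", "PF00612", 100),
                h("B", "PF00069", 1), h("C", "PF00063", 1))
  recs <- extract_target_proteins(hits, "PF00063")
  expect_equal(vapply(recs, `[[`, "", "protein_id"), c("A", "C"))
  # records carry all significant hits of the protein, not only the target
  expect_equal(recs[[1]]$hits$domain_accession, c("PF00063", "PF00612"))

  # a protein whose only motor hit is insignificant is dropped
  recs2 <- extract_target_proteins(rbind(h("D", "PF00063", 1, sig = FALSE)),
                                   "PF00063")
  expect_length(recs2, 0L)
  expect_length(extract_target_proteins(hits[0, ], "PF00063"), 0L)

  # two motor hits on one protein still give a single record (gene counted once)
  recs3 <- extract_target_proteins(rbind(h("E", "PF00063", 1),
                                         h("E", "PF00063", 700)), "PF00063")
  expect_length(recs3, 1L)
  expect_equal(nrow(recs3[[1]]$hits), 2L)

  # idempotent and order-insensitive
  shuffled <- hits[c(4, 2, 1, 3), ]
  expect_equal(extract_target_proteins(shuffled, "PF00063"), recs)
})

test_that("clan overlap resolution keeps the best same-clan hit only", {
  mk <- function(s, e, ev, clan) {
    data.frame(protein_id = "P", species_id = "sp",
               domain_accession = "PFx", domain_name = "X",
               env_start = s, env_end = e, bit_score = 1, e_value = ev,
               clan_accession = clan, significant = TRUE,
               stringsAsFactors = FALSE)
  }
  # same clan, overlapping: lowest e-value survives
  two <- rbind(mk(10, 100, 1e-10, "CLA"), mk(50, 140, 1e-3, "CLA"))
  out <- resolve_overlaps(two, "clan_best_evalue")
  expect_equal(nrow(out), 1L)
  expect_equal(out$e_value, 1e-10)
  # different clans: both retained
  out2 <- resolve_overlaps(rbind(mk(10, 100, 1e-10, "CLA"),
                                 mk(50, 140, 1e-3, "CLB")),
                           "clan_best_evalue")
  expect_equal(nrow(out2), 2L)
  # non-overlapping: unchanged, sorted
  out3 <- resolve_overlaps(rbind(mk(200, 300, 1e-3, "CLA"),
                                 mk(10, 100, 1e-10, "CLA")),
                           "clan_best_evalue")
  expect_equal(out3$env_start, c(10, 200))
  # keep_all is the identity up to sorting
  out4 <- resolve_overlaps(two[2:1, ], "keep_all")
  expect_equal(out4$env_start, c(10, 50))
})

test_that("clan resolution equals the pairwise-elimination oracle", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(2:6, 1)
    hits <- random_hit_table(n)
    got <- resolve_overlaps(hits, "clan_best_evalue")
    want <- oracle_resolve_overlaps(hits)
    expect_equal(got$e_value, want$e_value)
  }
})

test_that("canonical architectures collapse repeat runs and drop weak hits", {
  mk <- function(name, s, sig = TRUE) {
    data.frame(protein_id = "P", species_id = "sp",
               domain_accession = name, domain_name = name,
               env_start = s, env_end = s + 50, bit_score = 1,
               e_value = 1e-9, clan_accession = NA, significant = sig,
               stringsAsFactors = FALSE)
  }
  a <- canonical_architecture(rbind(mk("Myosin_N", 1), mk("Myosin_head", 60),
                                    mk("IQ", 800), mk("Myosin_tail_1", 830)))
  expect_equal(a$string, "Myosin_N-Myosin_head-IQ-Myosin_tail_1")

  b <- canonical_architecture(rbind(mk("Myosin_head", 1), mk("IQ", 700),
                                    mk("IQ", 730), mk("Myosin_TH1", 760)))
  expect_equal(b$tokens$name, c("Myosin_head", "IQ", "Myosin_TH1"))
  expect_equal(b$tokens$count, c(1L, 2L, 1L))
  expect_equal(b$string, "Myosin_head-IQ(x2)-Myosin_TH1")

  expect_equal(canonical_architecture(mk("Myosin_head", 1))$string,
               "Myosin_head")
  # insignificant hits never contribute; all-insignificant errors
  c1 <- canonical_architecture(rbind(mk("Myosin_head", 1),
                                     mk("IQ", 700, sig = FALSE)))
  expect_equal(c1$string, "Myosin_head")
  expect_error(canonical_architecture(mk("IQ", 1, sig = FALSE)),
               "empty architecture")
})

test_that("architecture strings round-trip and collapsing is idempotent", {
  set.seed(7)
  pool <- c("Myosin_head", "IQ", "MyTH4", "FERM", "SH3_1", "PH")
  for (i in 1:50) {
    toks <- sample(pool, sample(1:6, 1), replace = TRUE)
    a <- architecture(toks)
    expect_equal(parse_architecture(a$string)$tokens, a$tokens)
    # collapsing twice equals collapsing once
    expect_equal(architecture(a$tokens$name, a$tokens$count)$tokens,
                 a$tokens)
  }
  expect_error(architecture("My-Dom"), "may not contain")
  expect_error(parse_architecture(""), "empty")
})

test_that("repeat-insensitive equality ignores copy counts only", {
  expect_true(architectures_equal("Myosin_head-IQ(x3)-Myosin_TH1",
                                  "Myosin_head-IQ-Myosin_TH1"))
  expect_false(architectures_equal("Myosin_head-IQ(x3)-Myosin_TH1",
                                   "Myosin_head-IQ-Myosin_TH1",
                                   mode = "exact"))
  expect_false(architectures_equal("Myosin_head-IQ", "IQ-Myosin_head"))
})
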