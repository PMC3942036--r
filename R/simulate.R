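#' Balanced species tree
#'
#' A fully balanced rooted binary tree on `n_leaves` tips (a power of two),
#' with tips `t1..tn` — a convenient null topology for gain/loss
#' simulations.
#'
#' @param n_leaves number of tips (power of 2, >= 2).
#' @return An ape `"phylo"` tree.
#' @export
balanced_tree <- function(n_leaves) {
  if (n_leaves < 2 || bitwAnd(n_leaves, n_leaves - 1L) != 0L) {
    stop("n_leaves must be a power of 2, >= 2")
  }
  build <- function(lo, hi) {
    if (lo == hi) return(paste0("t", lo))
    mid <- (lo + hi) %/% 2L
    paste0("(", build(lo, mid), ",", build(mid + 1L, hi), ")")
  }
  read_species_tree(paste0(build(1L, n_leaves), ";"))
}

#' Simulate Dollo gain/loss histories on a species tree
#'
#' Each unit is gained on a branch drawn uniformly over all branches of the
#' rooted tree (including the notional root branch `"ROOT"`). Below the
#' gain, every branch independently becomes a loss with probability
#' `loss_prob`; subtrees below a loss are skipped (no further draws — under
#' Dollo a unit cannot re-appear). Leaf states follow. The same seed always
#' reproduces the same output.
#'
#' @param tree a rooted ape `"phylo"` (>= 2 leaves).
#' @param n_units number of units to simulate.
#' @param loss_prob per-branch loss probability in `[0, 1]`.
#' @param seed integer seed; all randomness flows from it.
#' @param unit_prefix prefix of the generated unit names.
#' @return A list with `matrix` (the observed `"presence_matrix"`) and
#'   `truth` (class `"simulation_truth"`): per unit the true `gain_branch`,
#'   `loss_branches`, `present_leaves` and `alive_nodes`, plus the
#'   parameters and seed.
#' @export
simulate_repertoire <- function(tree, n_units, loss_prob, seed,
                                unit_prefix = "U") {
  if (loss_prob < 0 || loss_prob > 1) stop("loss_prob must lie in [0, 1]")
  idx <- .tree_index(tree)
  if (idx$n_tip < 2L) stop("tree needs at least 2 leaves")
  set.seed(seed)
  units <- sprintf("%s%03d", unit_prefix, seq_len(n_units))

  pre <- rev(idx$postorder)
  sim_one <- function() {
    g <- sample.int(idx$n_all, 1L)
    alive <- logical(idx$n_all)
    alive[g] <- TRUE
    loss <- character(0)
    for (w in pre) {
      if (!alive[w]) next
      for (ch in idx$children[[w]]) {
        if (stats::runif(1L) < loss_prob) {
          loss <- c(loss, idx$labels[ch])
        } else {
          alive[ch] <- TRUE
        }
      }
    }
    gb <- if (g == idx$root) "ROOT" else idx$labels[g]
    list(gain_branch = gb,
         loss_branches = sort(loss),
         present_leaves = idx$labels[which(alive[seq_len(idx$n_tip)])],
         alive_nodes = idx$labels[which(alive)])
  }
  truth_units <- stats::setNames(lapply(units, function(u) sim_one()), units)

  m <- matrix("0", nrow = idx$n_tip, ncol = n_units,
              dimnames = list(tree$tip.label, units))
  for (u in units) m[truth_units[[u]]$present_leaves, u] <- "1"

  truth <- structure(list(seed = seed, tree = tree, units = truth_units,
                          parameters = list(n_units = n_units,
                                            loss_prob = loss_prob)),
                     class = "simulation_truth")
  list(matrix = presence_matrix(m, granularity = "unit"), truth = truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("simulated Dollo history: %d units, loss_prob = %g, seed = %d\n",
              x$parameters$n_units, x$parameters$loss_prob, x$seed))
  invisible(x)
}

#' Closed-form gain-recovery expectation
#'
#' For the generating process of [simulate_repertoire()], computes by
#' dynamic programming the probability that the Dollo reconstruction
#' recovers the true gain branch of a unit. A gain at node `g` is recovered
#' exactly when surviving presence leaves remain in at least two child
#' subtrees of `g` (so that `MRCA(P) = g`); gains on terminal branches are
#' always recovered. Per subtree, the probability `q` that a child branch
#' leaves no surviving leaf satisfies `q = p + (1 - p) * prod(q_children)`.
#'
#' @param tree a rooted ape `"phylo"`.
#' @param loss_prob per-branch loss probability.
#' @return A list: `recovery` (expected recovery over a uniform gain site),
#'   `recovery_nonempty` (expectation conditional on at least one surviving
#'   leaf — the reconstructable units), and `p_empty` (probability a unit
#'   survives nowhere).
#' @export
expected_gain_recovery <- function(tree, loss_prob) {
  idx <- .tree_index(tree)
  q <- numeric(idx$n_all)            # branch+subtree leaves no survivor
  for (v in idx$postorder) {
    q[v] <- if (v <= idx$n_tip) loss_prob else
      loss_prob + (1 - loss_prob) * prod(q[idx$children[[v]]])
  }
  p_rec <- p_alive <- numeric(idx$n_all)
  for (v in seq_len(idx$n_all)) {
    if (v <= idx$n_tip) { p_rec[v] <- 1; p_alive[v] <- 1; next }
    qc <- q[idx$children[[v]]]
    none <- prod(qc)
    one <- sum(vapply(seq_along(qc), function(i)
      (1 - qc[i]) * prod(qc[-i]), numeric(1L)))
    p_rec[v] <- 1 - none - one
    p_alive[v] <- 1 - none
  }
  list(recovery = mean(p_rec),
       recovery_nonempty = sum(p_rec) / sum(p_alive),
       p_empty = 1 - mean(p_alive))
}

#' Gain-branch recovery of a reconstruction against simulation truth
#'
#' Runs [dollo_reconstruct()] on the simulated presence matrix and scores,
#' among units with at least one surviving presence leaf (the
#' reconstructable ones), the fraction whose inferred gain branch equals
#' the simulated truth.
#'
#' @param sim result of [simulate_repertoire()].
#' @return A list with `rate`, `n_scored`, `n_matched` and the
#'   reconstruction itself (`dollo`).
#' @export
simulation_recovery <- function(sim) {
  rec <- dollo_reconstruct(sim$matrix, sim$truth$tree)
  units <- names(sim$truth$units)
  nonempty <- units[vapply(sim$truth$units,
                           function(u) length(u$present_leaves) > 0L,
                           logical(1L))]
  matched <- vapply(nonempty, function(u)
    identical(rec$gain[[u]], sim$truth$units[[u]]$gain_branch), logical(1L))
  list(rate = if (length(nonempty)) mean(matched) else NA_real_,
       n_scored = length(nonempty), n_matched = sum(matched), dollo = rec)
}

#' Simulate evolving domain architectures and annotation tables
#'
#' Each simulated unit receives a root architecture — the head domain plus
#' 0 to 4 flanking domains drawn from `alphabet` — which then evolves down
#' the surviving branches of its gain subtree: per branch each non-head
#' token is deleted or duplicated at the given rates, and with probability
#' `insert` one random domain is inserted at a random position. The head
#' domain is never deleted nor duplicated, so every emitted protein has
#' exactly one motor domain. Surviving leaves emit one protein per unit in
#' `simple6` annotation rows.
#'
#' @param truth a `"simulation_truth"` from [simulate_repertoire()].
#' @param alphabet character vector of domain names (must not contain
#'   `head_domain`).
#' @param mutation_rates list with elements `insert`, `delete`, `duplicate`
#'   (per-branch probabilities; defaults 0.1, 0.05, 0.05).
#' @param seed integer seed.
#' @param head_domain name of the motor domain (accession `PF00063`).
#' @return A named list (species id to data.frame) of `simple6` tables with
#'   columns `species_id, protein_id, domain_accession, domain_name,
#'   env_start, env_end`, with attribute `"root_architectures"` (named list
#'   of [architecture()] objects).
#' @export
simulate_architectures <- function(truth, alphabet,
                                   mutation_rates = list(insert = 0.1,
                                                         delete = 0.05,
                                                         duplicate = 0.05),
                                   seed = truth$seed,
                                   head_domain = "Myosin_head") {
  stopifnot(inherits(truth, "simulation_truth"))
  if (head_domain %in% alphabet) stop("alphabet must not contain the head")
  set.seed(seed)
  idx <- .tree_index(truth$tree)
  acc <- stats::setNames(sprintf("PFX%04d", seq_along(alphabet)), alphabet)
  acc[head_domain] <- "PF00063"

  mutate <- function(tokens) {
    out <- character(0)
    for (t in tokens) {
      if (t == head_domain) { out <- c(out, t); next }
      r <- stats::runif(1L)
      if (r < mutation_rates$delete) next
      if (r < mutation_rates$delete + mutation_rates$duplicate) {
        out <- c(out, t, t)
      } else {
        out <- c(out, t)
      }
    }
    if (stats::runif(1L) < mutation_rates$insert) {
      pos <- sample.int(length(out) + 1L, 1L)
      out <- append(out, sample(alphabet, 1L), after = pos - 1L)
    }
    out
  }

  rows <- list()
  roots <- list()
  for (u in names(truth$units)) {
    tu <- truth$units[[u]]
    if (!length(tu$present_leaves)) next
    k <- sample(0:4, 1L)
    flank <- if (k) sample(alphabet, k, replace = TRUE) else character(0)
    pos <- sample.int(k + 1L, 1L)
    root_tokens <- append(flank, head_domain, after = pos - 1L)
    roots[[u]] <- architecture(root_tokens)
    alive <- idx$labels %in% tu$alive_nodes
    g <- if (tu$gain_branch == "ROOT") idx$root else
      .node_by_label(idx, tu$gain_branch)
    tok <- stats::setNames(vector("list", idx$n_all), NULL)
    tok[[g]] <- root_tokens
    for (w in rev(idx$postorder)) {
      if (!alive[w] || is.null(tok[[w]])) next
      for (ch in idx$children[[w]]) {
        if (alive[ch]) tok[[ch]] <- mutate(tok[[w]])
      }
    }
    for (leaf in tu$present_leaves) {
      i <- .node_by_label(idx, leaf)
      tt <- tok[[i]]
      n <- length(tt)
      rows[[length(rows) + 1L]] <- data.frame(
        species_id = leaf,
        protein_id = paste0(u, "_", leaf),
        domain_accession = unname(acc[tt]),
        domain_name = tt,
        env_start = (seq_len(n) - 1L) * 110L + 1L,
        env_end = (seq_len(n) - 1L) * 110L + 100L,
        stringsAsFactors = FALSE
      )
    }
  }
  all_rows <- do.call(rbind, rows)
  out <- split(all_rows, all_rows$species_id)
  out <- lapply(out, function(d) { rownames(d) <- NULL; d })
  attr(out, "root_architectures") <- roots
  out
}

#' Write simple6 annotation tables to a directory
#'
#' @param tables named list of simple6 data.frames (see
#'   [simulate_architectures()]).
#' @param dir output directory (created if needed); one
#'   `<species>.domains.tsv` per species.
#' @return The directory path, invisibly.
#' @export
write_annotation_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (sp in names(tables)) {
    utils::write.table(tables[[sp]],
                       file.path(dir, paste0(sp, ".domains.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(dir)
}

#' Simulate a gene tree with seeded class clades
#'
#' Builds a gene tree in which each surviving unit forms a clade mirroring
#' the species tree restricted to the unit's presence leaves; clades are
#' joined in random order into a caterpillar backbone. Within-clade nodes
#' receive high bootstrap supports (90–100) and joining nodes low ones
#' (0–50), so that [assign_by_clade()] with one seed per unit recovers the
#' unit memberships. Leaf labels follow `"species|protein"` with the
#' protein ids of [simulate_architectures()].
#'
#' @param truth a `"simulation_truth"` from [simulate_repertoire()].
#' @param seed integer seed.
#' @return A list with `newick` (string), `tree` (a `"gene_tree"`) and
#'   `seeds` (data.frame `leaf_label, class_id`, one seed per unit).
#' @export
simulate_gene_tree <- function(truth, seed = truth$seed) {
  stopifnot(inherits(truth, "simulation_truth"))
  set.seed(seed)
  idx <- .tree_index(truth$tree)
  units <- names(truth$units)[vapply(truth$units, function(u)
    length(u$present_leaves) > 0L, logical(1L))]
  if (!length(units)) stop("no surviving unit to build a gene tree from")

  clade_newick <- function(u) {
    tips <- truth$units[[u]]$present_leaves
    rec <- function(v) {
      if (v <= idx$n_tip) {
        if (idx$labels[v] %in% tips) {
          return(paste0(idx$labels[v], "|", u, "_", idx$labels[v]))
        }
        return(NULL)
      }
      subs <- Filter(Negate(is.null), lapply(idx$children[[v]], rec))
      if (!length(subs)) return(NULL)
      if (length(subs) == 1L) return(subs[[1L]])
      paste0("(", paste(unlist(subs), collapse = ","), ")",
             sample(90:100, 1L))
    }
    rec(idx$root)
  }

  parts <- vapply(units, clade_newick, character(1L))
  ord <- sample(seq_along(parts))
  nwk <- parts[ord[1L]]
  for (i in ord[-1L]) {
    nwk <- paste0("(", nwk, ",", parts[i], ")", sample(0:50, 1L))
  }
  if (!startsWith(nwk, "(")) nwk <- paste0("(", nwk, ")")
  nwk <- paste0(nwk, ";")
  seeds <- data.frame(
    leaf_label = vapply(units, function(u) {
      sp <- sort(truth$units[[u]]$present_leaves)[1L]
      paste0(sp, "|", u, "_", sp)
    }, character(1L)),
    class_id = units,
    stringsAsFactors = FALSE
  )
  rownames(seeds) <- NULL
  list(newick = nwk, tree = read_gene_tree(nwk), seeds = seeds)
}
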