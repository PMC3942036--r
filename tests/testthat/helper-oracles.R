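# Independent oracles used to cross-check the implementation.

# --- Dollo oracle built on ape/phangorn primitives -------------------------
# For a presence tip set P on a rooted phylo: gain node = MRCA(P); a node is
# present iff it lies in the MRCA clade and its tip set intersects P; losses
# are edges from a present parent to an absent child.
oracle_dollo <- function(tree, taxa_present) {
  tips <- match(taxa_present, tree$tip.label)
  stopifnot(!anyNA(tips))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  if (length(tips) == 0L) return(list(gain = NA, n_losses = 0L))
  mrca <- if (length(tips) == 1L) tips else ape::getMRCA(tree, tips)
  desc_tips <- function(v) {
    if (v <= n_tip) return(v)
    unlist(phangorn::Descendants(tree, v, type = "tips"))
  }
  in_clade <- function(v) {
    if (v == mrca) return(TRUE)
    # ancestors of v via repeated edge lookup
    p <- v
    while (p != root) {
      p <- tree$edge[tree$edge[, 2L] == p, 1L]
      if (p == mrca) return(TRUE)
    }
    mrca == root
  }
  all_nodes <- seq_len(n_tip + tree$Nnode)
  present <- vapply(all_nodes, function(v)
    in_clade(v) && length(intersect(desc_tips(v), tips)) > 0L, logical(1L))
  losses <- sum(vapply(seq_len(nrow(tree$edge)), function(i) {
    present[tree$edge[i, 1L]] && !present[tree$edge[i, 2L]]
  }, logical(1L)))
  list(gain = mrca, n_losses = losses, present = present)
}

# --- exhaustive minimal-history search (small trees) -----------------------
# Enumerates every (gain node, loss-edge subset) consistent with the leaf
# pattern and returns the minimum number of losses. Feasible for <= 6 tips.
oracle_exhaustive_min_losses <- function(tree, taxa_present) {
  n_tip <- length(tree$tip.label)
  tips <- match(taxa_present, tree$tip.label)
  root <- n_tip + 1L
  parent_of <- function(v) tree$edge[tree$edge[, 2L] == v, 1L]
  path_edges <- function(g, t) {       # child nodes of edges on path g -> t
    out <- integer(0)
    v <- t
    while (v != g) {
      out <- c(out, v)
      if (v == root) return(NULL)      # g not an ancestor of t
      v <- parent_of(v)
    }
    out
  }
  tipset <- function(v) {
    if (v <= n_tip) v else unlist(phangorn::Descendants(tree, v, "tips"))
  }
  is_below <- function(v, g) {         # is g a strict ancestor of v?
    while (v != root) {
      v <- parent_of(v)
      if (v == g) return(TRUE)
    }
    FALSE
  }
  best <- Inf
  for (g in seq_len(n_tip + tree$Nnode)) {
    below <- tipset(g)
    if (!all(tips %in% below)) next
    # candidate loss edges: all edges strictly below g
    sub_edges <- Filter(function(v) is_below(v, g),
                        seq_len(n_tip + tree$Nnode))
    ne <- length(sub_edges)
    if (ne > 14L) stop("tree too large for exhaustive oracle")
    for (mask in 0:(2^ne - 1L)) {
      S <- sub_edges[bitwAnd(bitwShiftL(1L, seq_len(ne) - 1L), mask) != 0L]
      if (length(S) >= best) next
      implied <- vapply(seq_len(n_tip), function(t) {
        pe <- path_edges(g, t)
        if (is.null(pe)) return(FALSE)
        !any(pe %in% S)
      }, logical(1L))
      if (identical(which(implied), sort(tips))) best <- length(S)
    }
  }
  best
}

# --- exhaustive stable-set oracle for clan overlap resolution --------------
# The surviving set S is characterised by: (i) no two members of S clan-
# overlap, and (ii) every eliminated hit clan-overlaps a *surviving* hit of
# lower e-value. This oracle enumerates all 2^n subsets, keeps the stable
# ones, and asserts uniqueness (distinct e-values assumed).
oracle_resolve_overlaps <- function(hits) {
  n <- nrow(hits)
  conflict <- function(a, b) {
    !is.na(hits$clan_accession[a]) && !is.na(hits$clan_accession[b]) &&
      hits$clan_accession[a] == hits$clan_accession[b] &&
      hits$env_start[a] <= hits$env_end[b] &&
      hits$env_start[b] <= hits$env_end[a]
  }
  stable <- list()
  for (mask in 0:(2^n - 1L)) {
    S <- which(bitwAnd(bitwShiftL(1L, seq_len(n) - 1L), mask) != 0L)
    out <- setdiff(seq_len(n), S)
    ok <- TRUE
    for (a in S) for (b in S) {
      if (a < b && conflict(a, b)) ok <- FALSE
    }
    if (ok) for (d in out) {
      beats <- any(vapply(S, function(s)
        hits$e_value[s] < hits$e_value[d] && conflict(s, d), logical(1L)))
      if (!beats) ok <- FALSE
    }
    if (ok) stable[[length(stable) + 1L]] <- S
  }
  stopifnot(length(stable) == 1L)
  sort_hits(hits[stable[[1L]], , drop = FALSE])
}

# --- small random generators ----------------------------------------------
random_hit_table <- function(n, protein = "sp1|P1", clans = c("CLA", "CLB", NA)) {
  starts <- sample.int(300, n, replace = TRUE)
  data.frame(
    protein_id = protein,
    species_id = "sp1",
    domain_accession = sprintf("PF%05d", sample.int(99, n, replace = TRUE)),
    domain_name = sprintf("Dom%d", sample.int(9, n, replace = TRUE)),
    env_start = starts,
    env_end = starts + sample.int(120, n, replace = TRUE),
    bit_score = round(stats::runif(n, 10, 300), 1),
    e_value = stats::runif(n, 1e-40, 1e-2),
    clan_accession = sample(clans, n, replace = TRUE),
    significant = TRUE,
    stringsAsFactors = FALSE
  )
}

random_rooted_tree <- function(n_tip) {
  phy <- ape::rtree(n_tip, rooted = TRUE, br = NULL)
  phy$tip.label <- paste0("s", seq_len(n_tip))
  phy
}
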