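#' Read a rooted species tree with named internal nodes
#'
#' @param input newick file path or newick string. Internal node labels name
#'   ancestors (e.g. `LECA`, `LBikCA`, `LACA`, `LOCA`, `LHolCA`); unlabelled
#'   nodes are auto-named `N<id>`. Multifurcations are allowed.
#' @return An ape `"phylo"` tree.
#' @export
read_species_tree <- function(input) {
  txt <- if (length(input) == 1L && !grepl("[(;]", input) &&
             file.exists(input)) {
    paste(readLines(input, warn = FALSE), collapse = "")
  } else {
    paste(input, collapse = "")
  }
  phy <- ape::read.tree(text = txt)
  if (is.null(phy)) stop("could not parse newick input")
  phy
}

#' Dollo reconstruction of ancestral repertoires
#'
#' Reconstructs the gain/loss history of every unit (class, subclass or
#' type) over a rooted species tree under Dollo parsimony: each unit is
#' gained exactly once and may only be lost thereafter. For a unit observed
#' in the leaf set `P`, the gain is placed on the branch above `MRCA(P)`;
#' every node on a path from `MRCA(P)` to a leaf of `P` is inferred present;
#' and each maximal subtree under `MRCA(P)` containing no leaf of `P`
#' contributes exactly one loss, on its root branch. This loss set is the
#' unique minimum for the observed pattern. A unit present on both sides of
#' the root has its gain reported on the notional branch `"ROOT"`. Units
#' absent from every leaf have no gain and all-absent states.
#'
#' Branches are identified by the label of their child node. Matrix cells
#' must be resolved to present/absent first (see [resolve_unclear()]).
#' Tree leaves without a matrix row are treated as absent.
#'
#' @param matrix a `"presence_matrix"` with cells in `{"1","0"}`; rownames
#'   must all be tree leaves.
#' @param tree a rooted ape `"phylo"` (or newick string/path).
#' @return An object of class `"dollo"`: a list with `tree`, `labels`
#'   (node labels, tips first), `units`, `gain` (named character; `NA` for
#'   all-absent units), `losses` (named list of branch labels) and `states`
#'   (nodes-by-units logical matrix of inferred presence).
#' @seealso [ancestor_complement()], [gains_losses_table()],
#'   [compare_rootings()]
#' @export
dollo_reconstruct <- function(matrix, tree) {
  if (!inherits(tree, "phylo")) tree <- read_species_tree(tree)
  m <- unclass(matrix)
  if (any(m == "?")) {
    stop("matrix contains unclear cells; resolve them first (resolve_unclear)")
  }
  idx <- .tree_index(tree)
  missing <- setdiff(rownames(m), tree$tip.label)
  if (length(missing)) {
    stop("taxon in matrix missing from tree: ",
         paste(missing, collapse = ", "))
  }

  units <- colnames(m)
  n_all <- idx$n_all
  states <- matrix(FALSE, nrow = n_all, ncol = length(units),
                   dimnames = list(idx$labels, units))
  gain <- stats::setNames(rep(NA_character_, length(units)), units)
  losses <- stats::setNames(vector("list", length(units)), units)

  for (u in units) {
    taxa <- rownames(m)[m[, u] == "1"]
    tips <- match(taxa, tree$tip.label)
    if (!length(tips)) { losses[[u]] <- character(0); next }
    cnt <- .subtree_counts(idx, tips)
    # MRCA: walk up from any presence tip until the subtree covers P
    v <- tips[1L]
    while (cnt[v] < length(tips)) v <- idx$parent[v]
    mrca <- v
    # present = below-or-equal mrca AND subtree holds a presence leaf
    in_clade <- logical(n_all)
    in_clade[mrca] <- TRUE
    for (w in rev(idx$postorder)) {      # preorder
      if (w != mrca && !identical(idx$parent[w], 0L) &&
          in_clade[idx$parent[w]]) {
        in_clade[w] <- in_clade[w] || TRUE
      }
    }
    pres <- in_clade & cnt > 0L
    states[, u] <- pres
    gain[u] <- if (mrca == idx$root) "ROOT" else idx$labels[mrca]
    # losses: child branches hanging off present nodes into dark subtrees
    loss <- character(0)
    for (w in which(pres)) {
      for (ch in idx$children[[w]]) {
        if (cnt[ch] == 0L) loss <- c(loss, idx$labels[ch])
      }
    }
    losses[[u]] <- sort(loss)
  }

  structure(list(tree = tree, labels = idx$labels, n_tip = idx$n_tip,
                 units = units, gain = gain, losses = losses,
                 states = states),
            class = "dollo")
}

#' @export
print.dollo <- function(x, ...) {
  n_gained <- sum(!is.na(x$gain))
  cat(sprintf("Dollo reconstruction: %d units on %d leaves\n",
              length(x$units), x$n_tip))
  cat(sprintf("  gains: %d (one per observed unit), losses: %d\n",
              n_gained, sum(lengths(x$losses))))
  root_units <- x$units[!is.na(x$gain) & x$gain == "ROOT"]
  cat("  root complement: ",
      if (length(root_units)) paste(sort(root_units), collapse = ", ")
      else "(empty)", "\n", sep = "")
  invisible(x)
}

#' @export
summary.dollo <- function(object, ...) {
  df <- data.frame(
    unit = object$units,
    gain_branch = unname(object$gain[object$units]),
    n_losses = unname(lengths(object$losses[object$units])),
    n_present_leaves = colSums(object$states[seq_len(object$n_tip), ,
                                             drop = FALSE]),
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  df
}

#' @export
plot.dollo <- function(x, ...) {
  ntab <- table(factor(x$gain[!is.na(x$gain) & x$gain != "ROOT"],
                       levels = x$labels))
  ltab <- table(factor(unlist(x$losses), levels = x$labels))
  ape::plot.phylo(x$tree, show.node.label = TRUE, ...)
  lab <- function(tab, sym) ifelse(tab > 0, paste0(sym, as.integer(tab)), "")
  child <- x$tree$edge[, 2L]
  txt <- trimws(paste(lab(ntab, "+")[child], lab(ltab, "-")[child]))
  ape::edgelabels(text = txt, frame = "none",
                  col = ifelse(grepl("\\+", txt), "darkgreen", "red"))
  invisible(x)
}

#' Ancestral complement at a named node
#'
#' The set of units inferred present at a node of the species tree. For a
#' leaf this equals the observed presence row.
#'
#' @param result a `"dollo"` reconstruction.
#' @param node_name a tip label or internal node label (e.g. `"LECA"`).
#' @return Character vector of unit names (sorted).
#' @export
ancestor_complement <- function(result, node_name) {
  stopifnot(inherits(result, "dollo"))
  i <- match(node_name, result$labels)
  if (is.na(i)) stop("unknown node: ", node_name)
  sort(result$units[result$states[i, ]])
}

#' Table of gain and loss events
#'
#' One gain row per unit observed in at least one leaf, plus one loss row
#' per inferred loss branch; sorted by unit, then branch.
#'
#' @param result a `"dollo"` reconstruction.
#' @return A data.frame with columns `unit, branch, event`.
#' @export
gains_losses_table <- function(result) {
  stopifnot(inherits(result, "dollo"))
  rows <- lapply(result$units, function(u) {
    if (is.na(result$gain[[u]])) return(NULL)
    g <- data.frame(unit = u, branch = result$gain[[u]], event = "gain",
                    stringsAsFactors = FALSE)
    l <- result$losses[[u]]
    if (length(l)) {
      g <- rbind(g, data.frame(unit = u, branch = l, event = "loss",
                               stringsAsFactors = FALSE))
    }
    g
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(unit = character(), branch = character(),
                      event = character(), stringsAsFactors = FALSE))
  }
  out <- out[order(out$unit, out$branch), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare reconstructions under alternative rootings
#'
#' Re-runs the Dollo reconstruction under each supplied rooted tree and
#' reports the root complement of each, to assess how sensitive the
#' ancestral repertoire is to the rooting hypothesis.
#'
#' @param matrix a resolved `"presence_matrix"`.
#' @param rootings a named list of rooted `"phylo"` trees (or newick
#'   strings/paths), each covering the matrix taxa.
#' @return A data.frame with columns `rooting, n_units, complement`
#'   (the complement comma-joined, sorted), plus the attribute
#'   `"complements"` holding the complements as a named list.
#' @export
compare_rootings <- function(matrix, rootings) {
  stopifnot(is.list(rootings), length(names(rootings)) == length(rootings))
  comps <- lapply(rootings, function(tr) {
    r <- dollo_reconstruct(matrix, tr)
    root_lab <- r$labels[.tree_index(r$tree)$root]
    ancestor_complement(r, root_lab)
  })
  out <- data.frame(
    rooting = names(rootings),
    n_units = vapply(comps, length, integer(1L)),
    complement = vapply(comps, function(x) paste(x, collapse = ","),
                        character(1L)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "complements") <- comps
  out
}
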