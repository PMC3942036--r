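#' Read a support-annotated gene tree
#'
#' Reads a newick gene tree whose internal-node labels carry statistical
#' support in one of three dialects: a plain number in (1, 100] is taken as
#' a bootstrap percentage, a number in [0, 1] as a Bayesian posterior
#' probability, and a combined `"bs/bpp"` label (e.g. `"79/0.99"`) carries
#' both. Leaf labels follow the `"species|protein"` convention.
#'
#' @param input a newick file path or a newick string.
#' @return An object of class `"gene_tree"`: a list with `phylo` (the ape
#'   tree), and numeric vectors `bs` and `bpp` (one entry per internal
#'   node, `NA` where the label does not carry that support type).
#' @export
read_gene_tree <- function(input) {
  txt <- if (length(input) == 1L && !grepl("[(;]", input) &&
             file.exists(input)) {
    paste(readLines(input, warn = FALSE), collapse = "")
  } else {
    paste(input, collapse = "")
  }
  phy <- ape::read.tree(text = txt)
  if (is.null(phy)) stop("could not parse newick input")
  nl <- phy$node.label
  if (is.null(nl)) nl <- rep("", phy$Nnode)
  bs <- rep(NA_real_, phy$Nnode)
  bpp <- rep(NA_real_, phy$Nnode)
  for (i in seq_along(nl)) {
    lab <- nl[i]
    if (is.na(lab) || lab == "") next
    if (grepl("/", lab, fixed = TRUE)) {
      parts <- strsplit(lab, "/", fixed = TRUE)[[1L]]
      bs[i] <- suppressWarnings(as.numeric(parts[1L]))
      bpp[i] <- suppressWarnings(as.numeric(parts[2L]))
    } else {
      v <- suppressWarnings(as.numeric(lab))
      if (is.na(v)) next
      if (v <= 1) bpp[i] <- v else bs[i] <- v
    }
  }
  if (any(bs < 0 | bs > 100, na.rm = TRUE)) {
    stop("bootstrap supports must lie in [0, 100]")
  }
  structure(list(phylo = phy, bs = bs, bpp = bpp), class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("gene tree: %d leaves, %d internal nodes (%d with BS, %d with BPP)\n",
              length(x$phylo$tip.label), x$phylo$Nnode,
              sum(!is.na(x$bs)), sum(!is.na(x$bpp))))
  invisible(x)
}

#' Assign gene-tree leaves to classes by clade membership
#'
#' Classification is purely phylogenetic: a query leaf is assigned to class
#' `c` when the smallest clade containing the query and at least one seed
#' contains seeds of class `c` only. The assignment is `"clear"` when that
#' clade's support meets `min_bs` *or* `min_bpp` (either suffices — classes
#' with modest bootstrap but high posterior are accepted), `"unclear"`
#' otherwise. When the smallest seed-containing clade mixes seed classes the
#' query is an orphan (a lineage-restricted myosin belonging to no defined
#' class). Seeds are returned with their own class, status `"clear"`.
#'
#' @param tree a `"gene_tree"` (see [read_gene_tree()]) or ape `"phylo"`.
#' @param seeds reference leaves of known class: a data.frame with columns
#'   `leaf_label, class_id`, or a named character vector
#'   (`names` = leaf labels, values = class ids).
#' @param min_bs minimum bootstrap percentage (default 50).
#' @param min_bpp minimum posterior probability (default 0.95).
#' @param label_sep separator of the `"species|protein"` leaf convention.
#' @return A data.frame with columns `leaf_label, species_id, protein_id,
#'   class_id, status, support_bs, support_bpp`.
#' @export
assign_by_clade <- function(tree, seeds, min_bs = 50, min_bpp = 0.95,
                            label_sep = "|") {
  if (inherits(tree, "phylo")) {
    tree <- read_gene_tree(ape::write.tree(tree))
  }
  stopifnot(inherits(tree, "gene_tree"))
  phy <- tree$phylo
  if (is.data.frame(seeds)) {
    seeds <- stats::setNames(as.character(seeds[[2L]]),
                             as.character(seeds[[1L]]))
  }
  if (!length(seeds)) stop("at least one seed is required")
  missing <- setdiff(names(seeds), phy$tip.label)
  if (length(missing)) {
    stop("seed label absent from tree: ", missing[1L])
  }

  idx <- .tree_index(phy, unique_labels = FALSE)
  n_tip <- idx$n_tip
  seed_tip <- match(names(seeds), phy$tip.label)
  seed_class <- unname(seeds)

  # per node: classes of seeds in its subtree
  seed_sets <- vector("list", idx$n_all)
  for (k in seq_along(seed_tip)) seed_sets[[seed_tip[k]]] <- seed_class[k]
  for (v in idx$postorder) {
    if (v > n_tip) {
      below <- unique(unlist(seed_sets[idx$children[[v]]]))
      seed_sets[[v]] <- if (is.null(below)) character(0) else below
    }
  }

  res <- lapply(seq_len(n_tip), function(tip) {
    lab <- phy$tip.label[tip]
    parts <- strsplit(lab, label_sep, fixed = TRUE)[[1L]]
    sp <- if (length(parts) >= 2L) parts[1L] else NA_character_
    pid <- if (length(parts) >= 2L) parts[2L] else lab
    if (tip %in% seed_tip) {
      return(data.frame(leaf_label = lab, species_id = sp, protein_id = pid,
                        class_id = seeds[[lab]], status = "clear",
                        support_bs = NA_real_, support_bpp = NA_real_,
                        stringsAsFactors = FALSE))
    }
    anc <- .ancestors(idx, tip)
    host <- NA_integer_
    for (a in anc) {
      if (length(seed_sets[[a]])) { host <- a; break }
    }
    if (is.na(host)) {
      cls <- "orphan"; status <- "orphan"; sbs <- NA_real_; sbpp <- NA_real_
    } else {
      classes <- seed_sets[[host]]
      j <- host - n_tip
      sbs <- tree$bs[j]; sbpp <- tree$bpp[j]
      if (length(classes) > 1L) {
        cls <- "orphan"; status <- "orphan"
      } else {
        cls <- classes
        ok <- (!is.na(sbs) && sbs >= min_bs) ||
          (!is.na(sbpp) && sbpp >= min_bpp)
        status <- if (ok) "clear" else "unclear"
      }
    }
    data.frame(leaf_label = lab, species_id = sp, protein_id = pid,
               class_id = cls, status = status,
               support_bs = sbs, support_bpp = sbpp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
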