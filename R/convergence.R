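#' Default convergence motif library
#'
#' The three architecture signatures whose repeated, phylogenetically
#' independent acquisition is of most interest in the myosin family:
#' the MyTH4 domain followed by a FERM domain (the tail signature of
#' amorphean membrane-binding myosins, re-invented in ciliate class XIV),
#' a C-terminal chitin-synthase domain (fungal class XVII versus the
#' annelid/mollusc members of class XVI), and an N-terminal protein kinase
#' preceding the motor domain.
#'
#' @return A named list of ordered motifs (character vectors of domain
#'   names).
#' @export
default_motifs <- function() {
  list(
    MyTH4_FERM    = c("MyTH4", "FERM"),
    chitin_synth  = "Chitin_synth_2",
    kinase_head   = c("Pkinase", "Myosin_head")
  )
}

#' Detect convergent domain-architecture acquisition
#'
#' A signature (a full architecture in `"exact"` mode, or an ordered motif
#' in `"motif"` mode) is convergent when at least two classes bear it and
#' their acquisitions are phylogenetically independent. Independence is
#' topological: the classes' gain branches in the Dollo reconstruction are
#' distinct and neither is ancestral to the other
#' (evidence `"independent_gain_branches"`). When gain branches form an
#' ancestor–descendant chain the signature is *not* reported — unless a
#' class-level tree is supplied and the bearer classes are non-sister in
#' it (evidence `"non_sister_classes"`), the situation of non-orthologous
#' classes that independently picked up the same domain.
#'
#' In motif mode a class bears the signature when the motif occurs as an
#' ordered — not necessarily contiguous — subsequence of the token names of
#' any of its architectures (intervening domains are allowed, as in
#' MyTH4–SH3–FERM tails).
#'
#' @param class_architectures named list: class id to an
#'   [architecture()] (or canonical string), or a list of them (canonical
#'   architecture plus variants).
#' @param reconstruction a `"dollo"` reconstruction whose units are the
#'   classes; classes without a gain (absent everywhere) are skipped.
#' @param motifs ordered motifs for `"motif"` mode (default
#'   [default_motifs()]); must be non-empty in motif mode.
#' @param match_mode `"motif"` (default) or `"exact"`.
#' @param class_tree optional class-level tree (`"phylo"` or newick) with
#'   the class ids as tips, enabling the non-sister evidence route.
#' @return A list of convergence events; each is a list with `signature`,
#'   `contexts` (data.frame `class_id, gain_branch`) and `evidence`.
#' @export
detect_convergent_architectures <- function(class_architectures,
                                            reconstruction,
                                            motifs = default_motifs(),
                                            match_mode = c("motif", "exact"),
                                            class_tree = NULL) {
  match_mode <- match.arg(match_mode)
  stopifnot(inherits(reconstruction, "dollo"))
  archs <- lapply(class_architectures, function(a) {
    if (inherits(a, "architecture") || is.character(a)) a <- list(a)
    lapply(a, as_architecture)
  })
  idx <- .tree_index(reconstruction$tree)
  if (!is.null(class_tree)) {
    if (!inherits(class_tree, "phylo")) {
      class_tree <- read_species_tree(class_tree)
    }
    cidx <- .tree_index(class_tree)
  }

  if (match_mode == "motif") {
    if (!length(motifs)) stop("motif mode requires a non-empty motif list")
    if (is.null(names(motifs))) {
      names(motifs) <- vapply(motifs, paste, character(1L), collapse = "-")
    }
    signatures <- motifs
    bearers <- lapply(motifs, function(mo) {
      names(archs)[vapply(archs, function(as) {
        any(vapply(as, function(a) .is_subsequence(mo, a$tokens$name),
                   logical(1L)))
      }, logical(1L))]
    })
  } else {
    canon <- lapply(archs, function(as) {
      unique(vapply(as, function(a) .arch_string(
        data.frame(name = a$tokens$name, count = 1L)), character(1L)))
    })
    all_sigs <- sort(unique(unlist(canon)))
    signatures <- stats::setNames(as.list(all_sigs), all_sigs)
    bearers <- lapply(all_sigs, function(s) {
      names(canon)[vapply(canon, function(x) s %in% x, logical(1L))]
    })
    names(bearers) <- all_sigs
  }

  events <- list()
  for (s in names(signatures)) {
    cls <- intersect(bearers[[s]], reconstruction$units)
    cls <- cls[!is.na(reconstruction$gain[cls])]
    if (length(cls) < 2L) next
    gains <- reconstruction$gain[cls]
    indep <- FALSE
    for (i in seq_along(cls)) {
      for (j in seq_along(cls)) {
        if (i >= j) next
        a <- gains[[i]]; b <- gains[[j]]
        if (!identical(a, b) && !.branch_ancestral(idx, a, b) &&
            !.branch_ancestral(idx, b, a)) {
          indep <- TRUE
        }
      }
    }
    evidence <- NULL
    if (indep) {
      evidence <- "independent_gain_branches"
    } else if (!is.null(class_tree)) {
      present <- intersect(cls, class_tree$tip.label)
      if (length(present) >= 2L) {
        tipids <- match(present, class_tree$tip.label)
        parents <- cidx$parent[tipids]
        # any two bearers that are not each other's sister tip
        if (length(unique(parents)) > 1L) evidence <- "non_sister_classes"
      }
    }
    if (is.null(evidence)) next
    events[[length(events) + 1L]] <- list(
      signature = signatures[[s]],
      signature_id = s,
      contexts = data.frame(class_id = cls,
                            gain_branch = unname(gains),
                            stringsAsFactors = FALSE),
      evidence = evidence
    )
  }
  events
}

.is_subsequence <- function(motif, tokens) {
  i <- 1L
  for (t in tokens) {
    if (i <= length(motif) && identical(t, motif[i])) i <- i + 1L
  }
  i > length(motif)
}

#' Write convergence events as TSV
#'
#' @param events result of [detect_convergent_architectures()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_convergence_table <- function(events, path) {
  rows <- lapply(events, function(e) {
    data.frame(
      signature = paste(unlist(e$signature), collapse = "-"),
      contexts = paste(sprintf("%s@%s", e$contexts$class_id,
                               e$contexts$gain_branch), collapse = ";"),
      evidence = e$evidence,
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(signature = character(), contexts = character(),
               evidence = character())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
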