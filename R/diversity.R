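#' Concurrent domains per species
#'
#' A concurrent domain is any domain annotated within the same predicted
#' open reading frame as the motor domain. For each species this returns
#' the union of domain names over its motor-containing proteins, excluding
#' the accessions in `exclude` (the motor domain itself by default). Only
#' significant hits contribute. A species whose myosins carry nothing but
#' the head domain maps to an empty set. When one domain name is used by
#' several distinct accessions, the ambiguous names are disambiguated as
#' `name.accession`.
#'
#' @param records per-protein records from [extract_target_proteins()].
#' @param exclude accessions excluded from the count (default `"PF00063"`).
#' @return A named list: species id to character vector of domain names.
#' @export
concurrent_domains <- function(records, exclude = "PF00063") {
  if (!length(records)) return(stats::setNames(list(), character(0)))
  hits <- do.call(rbind, lapply(records, `[[`, "hits"))
  hits <- hits[hits$significant, , drop = FALSE]
  # disambiguate duplicate names across accessions
  key <- unique(hits[, c("domain_name", "domain_accession")])
  dup <- key$domain_name[duplicated(key$domain_name)]
  hits$display <- ifelse(hits$domain_name %in% dup,
                         paste(hits$domain_name, hits$domain_accession,
                               sep = "."),
                         hits$domain_name)
  species <- sort(unique(vapply(records, `[[`, character(1L), "species_id")))
  out <- lapply(species, function(sp) {
    h <- hits[hits$species_id == sp & !(hits$domain_accession %in% exclude), ,
              drop = FALSE]
    sort(unique(h$display))
  })
  stats::setNames(out, species)
}

#' Per-species diversity summary
#'
#' Counts, for each species: the number of myosin genes (distinct motor
#' proteins), the number of myosin classes with at least one clear
#' assignment, and the number of distinct concurrent domains.
#'
#' @param records per-protein records from [extract_target_proteins()].
#' @param assignments class assignments from [assign_by_clade()].
#' @param concurrent per-species domain sets from [concurrent_domains()].
#' @param species optional species universe; defaults to the union of the
#'   three inputs. Species absent from the inputs get all-zero rows.
#' @return A data.frame with columns `species_id, n_myosin_genes,
#'   n_classes, n_concurrent_domains`.
#' @export
diversity_summary <- function(records, assignments = NULL,
                              concurrent = NULL, species = NULL) {
  rec_sp <- vapply(records, `[[`, character(1L), "species_id")
  rec_p <- vapply(records, `[[`, character(1L), "protein_id")
  if (is.null(species)) {
    species <- sort(unique(c(rec_sp, assignments$species_id,
                             names(concurrent))))
  }
  out <- data.frame(
    species_id = species,
    n_myosin_genes = vapply(species, function(sp)
      length(unique(rec_p[rec_sp == sp])), integer(1L)),
    n_classes = vapply(species, function(sp) {
      if (is.null(assignments)) return(0L)
      a <- assignments[assignments$species_id == sp &
                         assignments$status == "clear", , drop = FALSE]
      length(unique(a$class_id))
    }, integer(1L)),
    n_concurrent_domains = vapply(species, function(sp) {
      s <- concurrent[[sp]]
      if (is.null(s)) 0L else length(s)
    }, integer(1L)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Venn partition of domain sets
#'
#' Places every domain into exactly one region: the subset of groups whose
#' sets contain it. Region counts therefore sum to the size of the union.
#'
#' @param group_sets a named list of 2 to 4 character vectors (e.g. the
#'   concurrent-domain union of each lineage group).
#' @return An object of class `"venn_partition"`: list with `groups` and
#'   `regions`, the latter a named list (names like `"A&B"`) of lists with
#'   `groups`, `count` and `members`.
#' @export
venn_partition <- function(group_sets) {
  ng <- length(group_sets)
  if (ng < 2L || ng > 4L) stop("venn_partition needs 2 to 4 groups")
  if (is.null(names(group_sets)) || any(!nzchar(names(group_sets)))) {
    stop("group sets must be named")
  }
  groups <- names(group_sets)
  group_sets <- lapply(group_sets, unique)
  universe <- sort(unique(unlist(group_sets)))
  membership <- vapply(group_sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)

  regions <- list()
  for (k in seq_len(ng)) {
    for (cmb in utils::combn(groups, k, simplify = FALSE)) {
      sel <- rowSums(membership[, cmb, drop = FALSE]) == k &
        rowSums(membership) == k
      members <- universe[sel]
      regions[[paste(cmb, collapse = "&")]] <-
        list(groups = cmb, count = length(members), members = members)
    }
  }
  structure(list(groups = groups, regions = regions),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition of", length(x$groups), "groups:",
      paste(x$groups, collapse = ", "), "\n")
  for (nm in names(x$regions)) {
    r <- x$regions[[nm]]
    if (r$count) cat(sprintf("  %-20s %d\n", nm, r$count))
  }
  invisible(x)
}
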