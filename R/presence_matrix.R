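#' Presence/absence matrices
#'
#' A presence matrix records, for each taxon (row) and classification unit
#' (column — a myosin class, subclass or type), one of three states:
#' `"1"` (present), `"0"` (absent) or `"?"` (unclear, i.e. supported only by
#' putative orthologs below the support thresholds).
#'
#' @param x a character matrix with values in `{"1","0","?"}` (logical
#'   matrices are accepted and coerced), with taxa as rownames and units as
#'   colnames.
#' @param granularity the unit granularity: `"class"`, `"subclass"`,
#'   `"type"`, or any descriptive label.
#' @return An object of class `"presence_matrix"`.
#' @export
presence_matrix <- function(x, granularity = "class") {
  if (is.logical(x)) {
    m <- matrix(ifelse(x, "1", "0"), nrow = nrow(x), dimnames = dimnames(x))
  } else {
    m <- as.matrix(x)
    storage.mode(m) <- "character"
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("presence matrix needs taxon rownames and unit colnames")
  }
  if (!all(m %in% c("1", "0", "?"))) {
    stop("presence states must be one of '1', '0', '?'")
  }
  structure(m, class = c("presence_matrix", "matrix"),
            granularity = granularity)
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence matrix: %d taxa x %d units (granularity: %s)\n",
              nrow(x), ncol(x), attr(x, "granularity")))
  print(unclass(x), quote = FALSE)
  invisible(x)
}

#' Read / write a presence matrix as TSV
#'
#' The TSV format has the taxon in the first column (`taxon`) and one
#' column per unit, cells in `{1, 0, ?}`.
#'
#' @param path file path.
#' @param granularity granularity label recorded on the object.
#' @return For `read_presence_matrix`, a `"presence_matrix"`.
#' @export
read_presence_matrix <- function(path, granularity = "class") {
  d <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  presence_matrix(m, granularity = granularity)
}

#' @rdname read_presence_matrix
#' @param m a `"presence_matrix"`.
#' @export
write_presence_matrix <- function(m, path) {
  d <- data.frame(taxon = rownames(m), unclass(m), check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a presence matrix from class assignments
#'
#' A cell is present (`"1"`) when the taxon has at least one assignment of
#' the unit with status `"clear"`; cells supported only by `"unclear"`
#' assignments take the value dictated by `unclear_policy` (`"keep"` retains
#' `"?"`). Orphan assignments never contribute a unit column. Taxa listed in
#' `taxonomy` but without any assignment yield all-absent rows.
#'
#' @param assignments a data.frame as returned by [assign_by_clade()], with
#'   columns `protein_id, species_id, class_id, status`.
#' @param taxonomy optional species-to-taxon map: a named character vector,
#'   or a data.frame whose first column is the species and second the taxon
#'   (lineage) it belongs to. When given, every species in `assignments`
#'   must appear in it, rows are taxa, and all mapped taxa are represented.
#' @param unclear_policy `"as_absent"` (default, conservative),
#'   `"as_present"`, or `"keep"`.
#' @param granularity granularity label for the result.
#' @return A `"presence_matrix"` with one row per taxon.
#' @export
build_presence_matrix <- function(assignments, taxonomy = NULL,
                                  unclear_policy = c("as_absent",
                                                     "as_present", "keep"),
                                  granularity = "class") {
  unclear_policy <- match.arg(unclear_policy)
  stopifnot(is.data.frame(assignments))
  a <- assignments[assignments$status != "orphan", , drop = FALSE]

  if (!is.null(taxonomy)) {
    if (is.data.frame(taxonomy)) {
      taxonomy <- stats::setNames(as.character(taxonomy[[2L]]),
                                  as.character(taxonomy[[1L]]))
    }
    missing <- setdiff(unique(assignments$species_id), names(taxonomy))
    if (length(missing)) {
      stop("species absent from taxonomy: ", paste(missing, collapse = ", "))
    }
    taxa <- unique(unname(taxonomy))
    a$taxon <- unname(taxonomy[a$species_id])
  } else {
    taxa <- sort(unique(a$species_id))
    a$taxon <- a$species_id
  }

  units <- sort(unique(a$class_id))
  m <- matrix("0", nrow = length(taxa), ncol = length(units),
              dimnames = list(taxa, units))
  for (i in seq_len(nrow(a))) {
    cur <- m[a$taxon[i], a$class_id[i]]
    if (a$status[i] == "clear") {
      m[a$taxon[i], a$class_id[i]] <- "1"
    } else if (cur == "0") {
      m[a$taxon[i], a$class_id[i]] <- "?"
    }
  }
  m <- presence_matrix(m, granularity = granularity)
  if (unclear_policy != "keep") m <- resolve_unclear(m, unclear_policy)
  m
}

#' Resolve unclear cells of a presence matrix
#'
#' @param m a `"presence_matrix"`.
#' @param policy `"as_absent"` or `"as_present"`.
#' @return The matrix with `"?"` cells replaced.
#' @export
resolve_unclear <- function(m, policy = c("as_absent", "as_present")) {
  policy <- match.arg(policy)
  g <- attr(m, "granularity")
  x <- unclass(m)
  x[x == "?"] <- if (policy == "as_absent") "0" else "1"
  presence_matrix(x, granularity = g)
}

#' Aggregate a presence matrix to a coarser granularity
#'
#' Maps each source unit (column) to a target unit and combines states with
#' an any-present rule: the target cell is present if any source cell is
#' present, else unclear if any is unclear, else absent.
#'
#' @param m a `"presence_matrix"`.
#' @param unit_map named character vector mapping every column of `m` to its
#'   target unit (e.g. subclass to class, or class to type).
#' @param granularity granularity label for the result.
#' @return A `"presence_matrix"` with the target units as columns.
#' @export
aggregate_granularity <- function(m, unit_map, granularity = "type") {
  unmapped <- setdiff(colnames(m), names(unit_map))
  if (length(unmapped)) {
    stop("unmapped column(s): ", paste(unmapped, collapse = ", "))
  }
  targets <- unique(unname(unit_map[colnames(m)]))
  out <- matrix("0", nrow = nrow(m), ncol = length(targets),
                dimnames = list(rownames(m), targets))
  for (t in targets) {
    src <- colnames(m)[unit_map[colnames(m)] == t]
    sub <- unclass(m)[, src, drop = FALSE]
    out[, t] <- apply(sub, 1L, function(r) {
      if (any(r == "1")) "1" else if (any(r == "?")) "?" else "0"
    })
  }
  presence_matrix(out, granularity = granularity)
}
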