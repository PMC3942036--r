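#' Domain architectures
#'
#' An architecture is the ordered sequence of domain types along a protein,
#' canonicalised so that runs of the same domain collapse into a single token
#' with a copy count. `"Myosin_head-IQ(x2)-Myosin_TH1"` denotes a motor domain
#' followed by two IQ motifs and a TH1 tail. Because many myosin classes carry
#' a variable number of repeats (IQ motifs in particular), the default
#' comparison mode ignores copy counts.
#'
#' @param names character vector of domain names, in N- to C-terminal order.
#'   Names must not contain the separator `"-"` nor `"("`.
#' @param counts integer vector of copy counts (recycled), all `>= 1`.
#' @return An object of class `"architecture"`: a list with elements
#'   `tokens` (data.frame with columns `name`, `count`) and `string`
#'   (the canonical rendering).
#' @examples
#' architecture(c("Myosin_head", "IQ", "IQ", "Myosin_TH1"))
#' @export
architecture <- function(names, counts = 1L) {
  names <- as.character(names)
  if (length(names) == 0L) stop("empty architecture")
  counts <- rep_len(as.integer(counts), length(names))
  if (any(is.na(names)) || any(counts < 1L)) {
    stop("architecture tokens need a name and a copy count >= 1")
  }
  bad <- grepl("[-()]", names)
  if (any(bad)) {
    stop("domain names may not contain '-', '(' or ')': ", names[bad][1L])
  }
  # collapse adjacent runs of the same domain
  expanded <- rep(names, counts)
  r <- rle(expanded)
  tokens <- data.frame(name = r$values, count = r$lengths,
                       stringsAsFactors = FALSE)
  structure(list(tokens = tokens, string = .arch_string(tokens)),
            class = "architecture")
}

.arch_string <- function(tokens) {
  paste(ifelse(tokens$count > 1L,
               sprintf("%s(x%d)", tokens$name, tokens$count),
               tokens$name),
        collapse = "-")
}

#' Parse a canonical architecture string
#'
#' Inverse of the `string` rendering produced by [architecture()]:
#' `parse_architecture(a$string)` reproduces `a`.
#'
#' @param x a canonical string such as `"Myosin_head-IQ(x2)-Myosin_TH1"`.
#' @return An `"architecture"` object.
#' @export
parse_architecture <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!nzchar(x)) stop("empty architecture")
  parts <- strsplit(x, "-", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^(.*)\\(x([0-9]+)\\)$", parts))
  names <- vapply(seq_along(parts), function(i) {
    if (length(m[[i]])) m[[i]][2L] else parts[i]
  }, character(1L))
  counts <- vapply(seq_along(parts), function(i) {
    if (length(m[[i]])) as.integer(m[[i]][3L]) else 1L
  }, integer(1L))
  architecture(names, counts)
}

#' @export
format.architecture <- function(x, ...) x$string

#' @export
print.architecture <- function(x, ...) {
  cat("<architecture> ", x$string, "\n", sep = "")
  invisible(x)
}

#' Compare two architectures
#'
#' In `"repeat_insensitive"` mode (the default) copy counts are ignored, so
#' `IQ(x3)` matches `IQ`; classes are diagnosed by which domains occur in
#' which order, not by repeat number. `"exact"` also requires equal counts.
#'
#' @param a,b `"architecture"` objects (or canonical strings).
#' @param mode `"repeat_insensitive"` or `"exact"`.
#' @return `TRUE` or `FALSE`.
#' @export
architectures_equal <- function(a, b,
                                mode = c("repeat_insensitive", "exact")) {
  mode <- match.arg(mode)
  a <- as_architecture(a); b <- as_architecture(b)
  if (!identical(a$tokens$name, b$tokens$name)) return(FALSE)
  if (mode == "exact") return(identical(a$tokens$count, b$tokens$count))
  TRUE
}

#' @rdname architectures_equal
#' @param x object to coerce (string or architecture).
#' @export
as_architecture <- function(x) {
  if (inherits(x, "architecture")) x else parse_architecture(x)
}

#' Canonical architecture of an annotated protein
#'
#' Builds the [architecture()] of one protein from its overlap-resolved
#' domain hits: hits are taken in coordinate order, insignificant hits (those
#' failing the curated gathering threshold) are dropped, and runs of the same
#' domain collapse into one token with a copy count.
#'
#' @param hits a data.frame of domain hits for a single protein, as returned
#'   by [read_domain_annotations()] (and usually [resolve_overlaps()]).
#' @return An `"architecture"` object.
#' @export
canonical_architecture <- function(hits) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) && length(unique(hits$protein_id)) > 1L) {
    stop("hits span more than one protein")
  }
  hits <- hits[hits$significant, , drop = FALSE]
  if (!nrow(hits)) stop("empty architecture")
  hits <- sort_hits(hits)
  architecture(hits$domain_name)
}
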