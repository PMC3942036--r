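#' Read protein domain annotation tables
#'
#' Parses per-protein domain annotations into a hit table with one row per
#' domain occurrence. Two dialects are supported:
#'
#' * `"pfamscan15"`: the 15-column whitespace-delimited output of a Pfam
#'   domain scan — `seq_id, aln_start, aln_end, env_start, env_end, hmm_acc,
#'   hmm_name, type, hmm_start, hmm_end, hmm_length, bit_score, e_value,
#'   significance, clan`. The `significance` flag (0/1) records whether the
#'   hit passed the family's curated gathering threshold; failing rows are
#'   retained but marked `significant = FALSE`. A clan of `"No_clan"`, `"-"`
#'   or `"NA"` becomes `NA`.
#' * `"simple6"`: a plain TSV with columns `species_id, protein_id,
#'   domain_accession, domain_name, env_start, env_end`; every hit is
#'   treated as significant.
#'
#' Comment lines starting with `#` and blank lines are skipped. Coordinates
#' are 1-based and inclusive (envelope coordinates).
#'
#' For the pfamscan15 dialect the species of each protein is resolved either
#' from `species_map` (a two-column data.frame `protein_id, species_id` or a
#' named character vector) or, when `species_map` is `NULL`, from a
#' `"species|protein"` sequence-label convention (separator `label_sep`).
#'
#' @param input path to a file, or a character vector of lines (anything of
#'   length > 1, or containing a newline/tab, is treated as literal lines).
#' @param dialect `"pfamscan15"` or `"simple6"`.
#' @param species_map optional protein-to-species mapping (see Details).
#' @param label_sep separator of the `"species|protein"` label convention.
#' @return A data.frame of domain hits with columns `protein_id, species_id,
#'   domain_accession, domain_name, env_start, env_end, bit_score, e_value,
#'   clan_accession, significant`.
#' @seealso [extract_target_proteins()], [resolve_overlaps()],
#'   [canonical_architecture()]
#' @export
read_domain_annotations <- function(input,
                                    dialect = c("pfamscan15", "simple6"),
                                    species_map = NULL,
                                    label_sep = "|") {
  dialect <- match.arg(dialect)
  lines <- .read_lines(input)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(.empty_hits())

  fields <- strsplit(trimws(lines), "\t|\\s+")
  ncol_needed <- if (dialect == "pfamscan15") 15L else 6L
  nf <- lengths(fields)
  if (any(nf != ncol_needed)) {
    i <- which(nf != ncol_needed)[1L]
    stop(sprintf("malformed row at line %d: expected %d fields, found %d",
                 lineno[i], ncol_needed, nf[i]))
  }
  m <- do.call(rbind, fields)

  if (dialect == "pfamscan15") {
    hits <- data.frame(
      protein_id       = m[, 1L],
      species_id       = NA_character_,
      domain_accession = sub("\\.\\d+$", "", m[, 6L]),
      domain_name      = m[, 7L],
      env_start        = .num_field(m[, 4L], lineno, "env_start"),
      env_end          = .num_field(m[, 5L], lineno, "env_end"),
      bit_score        = .num_field(m[, 12L], lineno, "bit_score"),
      e_value          = .num_field(m[, 13L], lineno, "e_value"),
      clan_accession   = ifelse(m[, 15L] %in% c("No_clan", "-", "NA", ""),
                                NA_character_, m[, 15L]),
      significant      = m[, 14L] == "1",
      stringsAsFactors = FALSE
    )
    if (!all(m[, 14L] %in% c("0", "1"))) {
      i <- which(!(m[, 14L] %in% c("0", "1")))[1L]
      stop(sprintf("malformed row at line %d: field significance must be 0 or 1",
                   lineno[i]))
    }
    hits$species_id <- .resolve_species(hits$protein_id, species_map,
                                        label_sep)
  } else {
    hits <- data.frame(
      protein_id       = m[, 2L],
      species_id       = m[, 1L],
      domain_accession = m[, 3L],
      domain_name      = m[, 4L],
      env_start        = .num_field(m[, 5L], lineno, "env_start"),
      env_end          = .num_field(m[, 6L], lineno, "env_end"),
      bit_score        = NA_real_,
      e_value          = 0,
      clan_accession   = NA_character_,
      significant      = TRUE,
      stringsAsFactors = FALSE
    )
  }

  bad <- hits$env_start < 1 | hits$env_start > hits$env_end
  if (any(bad)) {
    stop(sprintf("malformed row at line %d: env_start/env_end invalid (%d > %d or < 1)",
                 lineno[which(bad)[1L]],
                 hits$env_start[which(bad)[1L]], hits$env_end[which(bad)[1L]]))
  }
  if (any(hits$e_value < 0)) {
    stop(sprintf("malformed row at line %d: negative e_value",
                 lineno[which(hits$e_value < 0)[1L]]))
  }
  rownames(hits) <- NULL
  hits
}

.read_lines <- function(input) {
  if (is.character(input) &&
      (length(input) > 1L || grepl("[\n\t]", input) || !file.exists(input))) {
    if (length(input) == 1L && grepl("\n", input)) {
      return(strsplit(input, "\n", fixed = TRUE)[[1L]])
    }
    if (length(input) == 1L && !file.exists(input) && !grepl("\t", input)) {
      stop("file not found: ", input)
    }
    return(input)
  }
  readLines(input, warn = FALSE)
}

.num_field <- function(x, lineno, field) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) {
    i <- which(is.na(v))[1L]
    stop(sprintf("malformed row at line %d: field %s is not numeric (%s)",
                 lineno[i], field, x[i]))
  }
  v
}

.resolve_species <- function(protein_id, species_map, label_sep) {
  if (!is.null(species_map)) {
    if (is.data.frame(species_map)) {
      map <- stats::setNames(as.character(species_map[[2L]]),
                             as.character(species_map[[1L]]))
    } else {
      map <- species_map
    }
    sp <- unname(map[protein_id])
    if (anyNA(sp)) {
      stop("no species mapping for protein: ",
           protein_id[which(is.na(sp))[1L]])
    }
    return(sp)
  }
  parts <- strsplit(protein_id, label_sep, fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    stop("protein id lacks the 'species", label_sep,
         "protein' convention and no species_map was given: ",
         protein_id[which(lengths(parts) < 2L)[1L]])
  }
  vapply(parts, `[[`, character(1L), 1L)
}

.empty_hits <- function() {
  data.frame(protein_id = character(), species_id = character(),
             domain_accession = character(), domain_name = character(),
             env_start = numeric(), env_end = numeric(),
             bit_score = numeric(), e_value = numeric(),
             clan_accession = character(), significant = logical(),
             stringsAsFactors = FALSE)
}

#' Sort hits by envelope coordinates
#'
#' Ascending `env_start`, ties broken by `env_end`, then accession.
#'
#' @param hits a hit table.
#' @return The sorted hit table.
#' @export
sort_hits <- function(hits) {
  out <- hits[order(hits$env_start, hits$env_end, hits$domain_accession), ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract proteins containing a target domain
#'
#' Keeps every protein with at least one *significant* hit of
#' `target_accession` (the motor domain, by default), together with all of
#' that protein's significant hits — not only the target ones. Proteins
#' without the target are dropped; a protein with several target hits is
#' still a single record (genes are counted once).
#'
#' @param hits a hit table from [read_domain_annotations()].
#' @param target_accession domain accession to select on (default the
#'   myosin motor domain, `"PF00063"`).
#' @return A list of per-protein records; each element is a list with
#'   `protein_id`, `species_id` and `hits` (the protein's significant hits,
#'   coordinate-sorted and overlap-resolved per `policy`).
#' @param policy overlap policy forwarded to [resolve_overlaps()].
#' @export
extract_target_proteins <- function(hits, target_accession = "PF00063",
                                    policy = c("clan_best_evalue",
                                               "keep_all")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(hits))
  hits <- hits[hits$significant, , drop = FALSE]
  if (!nrow(hits)) return(list())
  with_target <- unique(hits$protein_id[hits$domain_accession ==
                                          target_accession])
  with_target <- sort(with_target)
  lapply(with_target, function(p) {
    h <- hits[hits$protein_id == p, , drop = FALSE]
    h <- resolve_overlaps(h, policy = policy)
    list(protein_id = p, species_id = h$species_id[1L], hits = h)
  })
}

#' Resolve overlapping domain hits within one protein
#'
#' Under `"clan_best_evalue"`, when two hits overlap in coordinates *and*
#' belong to the same clan, only the hit with the lowest E-value survives
#' (the usual treatment of clan-internal redundancy in Pfam scans). Hits of
#' different clans, or with no clan, are never removed. `"keep_all"` only
#' sorts. Overlap means any shared position under 1-based inclusive
#' envelope coordinates.
#'
#' @param hits hit table for a single protein.
#' @param policy `"clan_best_evalue"` or `"keep_all"`.
#' @return The surviving hits, sorted by `env_start`.
#' @export
resolve_overlaps <- function(hits, policy = c("clan_best_evalue",
                                              "keep_all")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(hits))
  if (nrow(hits) && length(unique(hits$protein_id)) > 1L) {
    stop("hits span more than one protein")
  }
  if (policy == "keep_all" || nrow(hits) < 2L) return(sort_hits(hits))
  # process in order of increasing e-value: a hit is kept unless it
  # clan-overlaps an already kept (better) hit
  ord <- order(hits$e_value, hits$env_start, hits$env_end)
  keep <- logical(nrow(hits))
  for (i in ord) {
    kept <- which(keep)
    clash <- FALSE
    for (j in kept) {
      same_clan <- !is.na(hits$clan_accession[i]) &&
        !is.na(hits$clan_accession[j]) &&
        hits$clan_accession[i] == hits$clan_accession[j]
      overlap <- hits$env_start[i] <= hits$env_end[j] &&
        hits$env_start[j] <= hits$env_end[i]
      if (same_clan && overlap) { clash <- TRUE; break }
    }
    if (!clash) keep[i] <- TRUE
  }
  sort_hits(hits[keep, , drop = FALSE])
}
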