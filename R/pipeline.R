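#' Pipeline configuration
#'
#' Collects the tunable parameters of the full analysis with their
#' defaults: the extraction target (the motor domain), the annotation
#' dialect, the clade-support thresholds, the treatment of unclear
#' presence calls, the reporting granularity, the rooting, the accessions
#' excluded from concurrent-domain counts, and the seed.
#'
#' @param target_accession accession selecting motor proteins.
#' @param dialect annotation dialect (see [read_domain_annotations()]).
#' @param min_bs,min_bpp clade-support thresholds (see [assign_by_clade()]).
#' @param unclear_policy `"as_absent"` or `"as_present"`.
#' @param granularity reporting granularity for the reconstruction.
#' @param rooting name of the rooting used for reporting.
#' @param exclude accessions excluded from concurrent-domain counts.
#' @param seed integer seed recorded in the run log.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(target_accession = "PF00063",
                            dialect = "simple6",
                            min_bs = 50, min_bpp = 0.95,
                            unclear_policy = "as_absent",
                            granularity = "class",
                            rooting = "unikont_bikont",
                            exclude = "PF00063",
                            seed = 1L) {
  stopifnot(dialect %in% c("pfamscan15", "simple6"),
            unclear_policy %in% c("as_absent", "as_present"),
            min_bs >= 0, min_bs <= 100, min_bpp >= 0, min_bpp <= 1)
  structure(list(target_accession = target_accession, dialect = dialect,
                 min_bs = min_bs, min_bpp = min_bpp,
                 unclear_policy = unclear_policy,
                 granularity = granularity, rooting = rooting,
                 exclude = exclude, seed = as.integer(seed)),
            class = "pipeline_config")
}

.config_digest <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Orchestrates all stages on a set of inputs and writes a report bundle:
#' `presence_matrix.tsv`, `gains_losses.tsv`, `complements.json`,
#' `rootings.tsv`, `diversity.tsv`, `venn.json`, `convergence.tsv` and a
#' `run_log.txt` recording the configuration, its digest, the seed and the
#' input digests. Every output file starts with (or carries) the config
#' digest so a bundle can be traced to the configuration that produced it.
#'
#' Inputs are supplied as a list; two entry points are supported:
#' raw annotations + gene tree (`annotations`, `gene_tree`, `seeds`) from
#' which assignments and the presence matrix are derived, or a ready-made
#' `presence` matrix. `species_tree` is always required for the
#' reconstruction; `taxonomy`, `rootings` (named list of trees),
#' `class_architectures`, `class_tree` and `venn_groups` (named list of
#' character sets) are optional.
#'
#' @param inputs a list, see Details.
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the stage results (`assignments`,
#'   `presence`, `dollo`, `diversity`, `venn`, `convergence`,
#'   `config_digest`).
#' @export
run_pipeline <- function(inputs, config = pipeline_config(),
                         out_dir = tempfile("myoevo_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  digest <- .config_digest(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  log_lines <- c(sprintf("config_digest\t%s", digest),
                 sprintf("seed\t%d", config$seed),
                 sprintf("config\t%s",
                         jsonlite::toJSON(unclass(config),
                                          auto_unbox = TRUE)))

  results <- list(config_digest = digest)

  assignments <- inputs$assignments
  records <- NULL
  if (!is.null(inputs$annotations)) {
    hits <- stage("annotation_io", {
      if (is.data.frame(inputs$annotations)) inputs$annotations
      else do.call(rbind, lapply(inputs$annotations, function(f) {
        log_lines <<- c(log_lines,
                        sprintf("input\t%s\t%s", basename(f),
                                unname(tools::md5sum(f))))
        read_domain_annotations(f, dialect = config$dialect,
                                species_map = inputs$species_map)
      }))
    })
    records <- stage("extract", {
      extract_target_proteins(hits, config$target_accession)
    })
  }
  if (is.null(assignments) && !is.null(inputs$gene_tree)) {
    assignments <- stage("classification", {
      gt <- if (inherits(inputs$gene_tree, "gene_tree")) inputs$gene_tree
      else read_gene_tree(inputs$gene_tree)
      assign_by_clade(gt, inputs$seeds, min_bs = config$min_bs,
                      min_bpp = config$min_bpp)
    })
  }
  results$assignments <- assignments

  presence <- inputs$presence
  if (is.null(presence)) {
    presence <- stage("matrix", {
      build_presence_matrix(assignments, taxonomy = inputs$taxonomy,
                            unclear_policy = config$unclear_policy,
                            granularity = config$granularity)
    })
  } else if (any(unclass(presence) == "?")) {
    presence <- resolve_unclear(presence, config$unclear_policy)
  }
  if (!is.null(inputs$unit_map)) {
    presence <- stage("aggregate", {
      aggregate_granularity(presence, inputs$unit_map,
                            granularity = config$granularity)
    })
  }
  results$presence <- presence
  write_presence_matrix(presence, file.path(out_dir, "presence_matrix.tsv"))

  if (!is.null(inputs$species_tree)) {
    rec <- stage("dollo", dollo_reconstruct(presence, inputs$species_tree))
    results$dollo <- rec
    gl <- gains_losses_table(rec)
    utils::write.table(gl, file.path(out_dir, "gains_losses.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    named <- setdiff(rec$labels[(rec$n_tip + 1L):length(rec$labels)],
                     character(0))
    comp <- lapply(stats::setNames(named, named),
                   function(n) ancestor_complement(rec, n))
    jsonlite::write_json(list(config_digest = digest, complements = comp),
                         file.path(out_dir, "complements.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    if (!is.null(inputs$rootings)) {
      rt <- stage("rootings", compare_rootings(presence, inputs$rootings))
      utils::write.table(rt, file.path(out_dir, "rootings.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$rootings <- rt
    }
  }

  if (!is.null(records)) {
    conc <- stage("diversity", concurrent_domains(records, config$exclude))
    div <- stage("diversity", {
      diversity_summary(records, assignments, conc)
    })
    results$diversity <- div
    utils::write.table(div, file.path(out_dir, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(inputs$venn_groups)) {
      sets <- lapply(inputs$venn_groups, function(members) {
        sort(unique(unlist(conc[intersect(members, names(conc))])))
      })
      vp <- stage("venn", venn_partition(sets))
      results$venn <- vp
      jsonlite::write_json(
        list(config_digest = digest,
             regions = lapply(vp$regions, function(r)
               list(count = r$count, members = r$members))),
        file.path(out_dir, "venn.json"), auto_unbox = TRUE, pretty = TRUE)
    }
  }

  if (!is.null(inputs$class_architectures) && !is.null(results$dollo)) {
    ev <- stage("convergence", {
      detect_convergent_architectures(inputs$class_architectures,
                                      results$dollo,
                                      class_tree = inputs$class_tree)
    })
    results$convergence <- ev
    write_convergence_table(ev, file.path(out_dir, "convergence.tsv"))
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(results)
}
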