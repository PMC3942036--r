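#' Packaged myosin census fixtures
#'
#' The package ships a curated census of the myosin gene family across 62
#' eukaryotic genomes in 14 lineage groups: the 31-class classification
#' table with subclasses, type groups and canonical domain architectures;
#' the lineage-level presence/absence matrix at the finest unit granularity
#' (subclasses where defined, classes otherwise); the species-to-lineage
#' taxonomy; a rooted species tree with the named ancestors LECA, LBikCA,
#' LACA, LOCA and LHolCA under the unikont–bikont rooting, plus two
#' alternative rootings (on the opisthokont and on the excavate stem); and
#' a class-level tree of the phylogenetic relationships among classes.
#' Presence cells not pinned down by published per-class statements are
#' best-effort transcriptions.
#'
#' @param name one of `"classes"`, `"presence"`, `"taxonomy"`,
#'   `"species_tree"`, `"species_tree_opisthokont_root"`,
#'   `"species_tree_excavate_root"`, `"class_tree"`, `"groups"`.
#' @return The parsed object: a data.frame, `"presence_matrix"`, `"phylo"`
#'   or list, depending on `name`.
#' @examples
#' cls <- myoevo_fixture("classes")
#' length(unique(cls$class_id))   # 31 myosin classes
#' @export
myoevo_fixture <- function(name = c("classes", "presence", "taxonomy",
                                    "species_tree",
                                    "species_tree_opisthokont_root",
                                    "species_tree_excavate_root",
                                    "class_tree", "groups")) {
  name <- match.arg(name)
  path <- function(f) system.file("extdata", f, package = "myoevo",
                                  mustWork = TRUE)
  switch(name,
    classes = {
      d <- utils::read.delim(path("classes.tsv"), check.names = FALSE,
                             colClasses = "character")
      d[d == "."] <- ""
      d
    },
    presence = read_presence_matrix(path("presence_lineages.tsv"),
                                    granularity = "unit"),
    taxonomy = utils::read.delim(path("taxonomy.tsv"), check.names = FALSE,
                                 colClasses = "character"),
    species_tree = read_species_tree(path("species_tree.nwk")),
    species_tree_opisthokont_root =
      read_species_tree(path("species_tree_opisthokont_root.nwk")),
    species_tree_excavate_root =
      read_species_tree(path("species_tree_excavate_root.nwk")),
    class_tree = read_species_tree(path("class_tree.nwk")),
    groups = yaml::read_yaml(path("groups.yaml"))
  )
}

#' Unit maps of the packaged classification
#'
#' Named character vectors mapping the census units (presence-matrix
#' columns) to their class and to their type group, for use with
#' [aggregate_granularity()].
#'
#' @param classes the classification table (default the packaged fixture).
#' @return A list with elements `class` and `type`.
#' @export
fixture_unit_maps <- function(classes = myoevo_fixture("classes")) {
  list(class = stats::setNames(classes$class_id, classes$unit_id),
       type = stats::setNames(classes$type_group, classes$unit_id))
}

#' Architectures of the packaged classes
#'
#' @param classes the classification table (default the packaged fixture).
#' @param variants include variant architectures alongside the canonical
#'   one (default `TRUE`).
#' @return A named list: class id to list of [architecture()] objects.
#' @export
fixture_class_architectures <- function(classes = myoevo_fixture("classes"),
                                        variants = TRUE) {
  cls <- classes[classes$subclass_id == "", , drop = FALSE]
  out <- lapply(seq_len(nrow(cls)), function(i) {
    a <- cls$architecture[i]
    v <- cls$variant_architectures[i]
    s <- a
    if (variants && nzchar(v)) {
      s <- c(s, strsplit(v, ";", fixed = TRUE)[[1L]])
    }
    lapply(s, parse_architecture)
  })
  stats::setNames(out, cls$class_id)
}

#' Ancestral architecture of each type group
#'
#' For every type group of the census, the canonical architecture of its
#' earliest-listed unit — the architecture attributed to the type's
#' ancestral paralog.
#'
#' @param classes the classification table (default the packaged fixture).
#' @return A named list: type group to [architecture()].
#' @export
fixture_type_architectures <- function(classes = myoevo_fixture("classes")) {
  types <- unique(classes$type_group)
  out <- lapply(types, function(t) {
    parse_architecture(classes$architecture[classes$type_group == t][1L])
  })
  stats::setNames(out, types)
}

#' Dollo reconstruction of the packaged census
#'
#' Convenience wrapper running presence-matrix aggregation and
#' [dollo_reconstruct()] on the packaged fixtures.
#'
#' @param granularity `"type"`, `"class"` or `"unit"` (no aggregation).
#' @param unclear_policy how `"?"` cells are resolved before
#'   reconstruction.
#' @param rooting `"unikont_bikont"` (default), `"opisthokont"` or
#'   `"excavate"`.
#' @return A `"dollo"` reconstruction.
#' @export
fixture_reconstruction <- function(granularity = c("type", "class", "unit"),
                                   unclear_policy = c("as_absent",
                                                      "as_present"),
                                   rooting = c("unikont_bikont",
                                               "opisthokont", "excavate")) {
  granularity <- match.arg(granularity)
  unclear_policy <- match.arg(unclear_policy)
  rooting <- match.arg(rooting)
  m <- resolve_unclear(myoevo_fixture("presence"), unclear_policy)
  maps <- fixture_unit_maps()
  if (granularity != "unit") {
    m <- aggregate_granularity(m, maps[[granularity]],
                               granularity = granularity)
  }
  tree <- switch(rooting,
                 unikont_bikont = myoevo_fixture("species_tree"),
                 opisthokont =
                   myoevo_fixture("species_tree_opisthokont_root"),
                 excavate = myoevo_fixture("species_tree_excavate_root"))
  dollo_reconstruct(m, tree)
}
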