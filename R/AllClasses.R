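#' @import methods
NULL

PROTEIN_COLS <- c("protein_id", "species_code", "length", "sequence",
                  "annotation_source", "fog_id")
FOG_COLS <- c("fog_id", "hog_id", "parent_fog", "status")
FOG_STATUSES <- c("predicted", "electronically_modified", "manually_curated")
ANNOTATION_SOURCES <- c("genome_annotation", "rescue")

#' Hierarchical ortholog catalog
#'
#' Holds the protein -> FOG -> HOG assignment of a database snapshot.  FOGs
#' (fine-grained ortholog groups) nest inside HOGs (homolog groups) and may
#' point at a parent FOG in the same HOG, giving the multi-level hierarchy
#' used for paralogous groups such as the two acetyl-CoA synthetase groups.
#' Unassigned proteins are kept with `fog_id = NA`, never dropped, so that
#' "fraction of the pan-proteome assigned" statistics stay computable.
#'
#' @slot proteins data.frame with columns `protein_id`, `species_code`,
#'   `length`, `sequence` (optional, `NA` allowed), `annotation_source`
#'   (`genome_annotation` or `rescue`) and `fog_id` (`NA` = unassigned).
#' @slot fogs data.frame with columns `fog_id`, `hog_id`, `parent_fog`
#'   (`NA` = top-level) and `status` (`predicted`,
#'   `electronically_modified` or `manually_curated`).
#' @slot metadata list of free-form provenance fields preserved by the
#'   readers and writers.
#' @export
setClass("OrthologCatalog",
  slots = c(proteins = "data.frame", fogs = "data.frame", metadata = "list"),
  prototype = prototype(
    proteins = data.frame(protein_id = character(), species_code = character(),
                          length = integer(), sequence = character(),
                          annotation_source = character(), fog_id = character(),
                          stringsAsFactors = FALSE),
    fogs = data.frame(fog_id = character(), hog_id = character(),
                      parent_fog = character(), status = character(),
                      stringsAsFactors = FALSE),
    metadata = list()))

setValidity("OrthologCatalog", function(object) {
  msg <- character()
  if (!all(PROTEIN_COLS %in% names(object@proteins)))
    msg <- c(msg, paste("proteins must have columns",
                        paste(PROTEIN_COLS, collapse = ", ")))
  if (!all(FOG_COLS %in% names(object@fogs)))
    msg <- c(msg, paste("fogs must have columns",
                        paste(FOG_COLS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an ortholog catalog
#'
#' Normalises column types and fills optional columns.  Structural checks
#' (column presence) are enforced; domain invariants are reported, not
#' thrown, by [validateCatalog()] so that broken catalogs read from disk can
#' still be inspected.
#'
#' @param proteins data.frame with at least `protein_id`, `species_code` and
#'   `length`; optional `sequence`, `annotation_source`, `fog_id`.
#' @param fogs data.frame with at least `fog_id` and `hog_id`; optional
#'   `parent_fog` and `status`.
#' @param metadata list of provenance fields.
#' @return an [OrthologCatalog-class] object.
#' @examples
#' pr <- data.frame(protein_id = c("sce_P1", "klc_P2"),
#'                  species_code = c("sce", "klc"), length = c(100L, 120L),
#'                  fog_id = c("FOG00001", "FOG00001"))
#' fg <- data.frame(fog_id = "FOG00001", hog_id = "HOG00001")
#' cat <- OrthologCatalog(pr, fg)
#' nProteins(cat)
#' @export
OrthologCatalog <- function(proteins, fogs = NULL, metadata = list()) {
  proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  if (is.null(proteins$sequence))
    proteins$sequence <- rep(NA_character_, nrow(proteins))
  if (is.null(proteins$annotation_source))
    proteins$annotation_source <- rep("genome_annotation", nrow(proteins))
  if (is.null(proteins$fog_id))
    proteins$fog_id <- rep(NA_character_, nrow(proteins))
  proteins$protein_id <- as.character(proteins$protein_id)
  proteins$species_code <- as.character(proteins$species_code)
  proteins$length <- as.integer(proteins$length)
  proteins$sequence <- as.character(proteins$sequence)
  proteins$fog_id <- as.character(proteins$fog_id)
  proteins <- proteins[PROTEIN_COLS]
  rownames(proteins) <- NULL
  if (is.null(fogs)) {
    fogs <- data.frame(fog_id = character(), hog_id = character(),
                       stringsAsFactors = FALSE)
  }
  fogs <- as.data.frame(fogs, stringsAsFactors = FALSE)
  if (is.null(fogs$parent_fog))
    fogs$parent_fog <- rep(NA_character_, nrow(fogs))
  if (is.null(fogs$status)) fogs$status <- rep("predicted", nrow(fogs))
  if (nrow(fogs)) {
    fogs$fog_id <- as.character(fogs$fog_id)
    fogs$hog_id <- as.character(fogs$hog_id)
    fogs$parent_fog <- as.character(fogs$parent_fog)
    fogs$status <- as.character(fogs$status)
  }
  fogs <- fogs[FOG_COLS]
  rownames(fogs) <- NULL
  new("OrthologCatalog", proteins = proteins, fogs = fogs, metadata = metadata)
}

#' Gene tree with node support and event labels
#'
#' Wraps an [ape::phylo] tree whose tips are protein identifiers of the form
#' `<species code>_<accession>`.  Internal nodes carry bootstrap support
#' (0-100, `NA` when the tree file had no label) and, once inferred on a
#' rooted tree, a speciation/duplication/unresolved event label.
#'
#' @slot tree a `phylo` object.
#' @slot support integer vector, one entry per internal node in `phylo`
#'   node order.
#' @slot event character vector parallel to `support`; `NA` until events
#'   are inferred.
#' @slot rooted logical flag.
#' @slot speciesMap named character vector mapping tip labels to species
#'   codes; tips absent from the map fall back to the prefix before the
#'   first underscore.
#' @export
setClass("GeneTree",
  slots = c(tree = "ANY", support = "integer", event = "character",
            rooted = "logical", speciesMap = "character"))

setValidity("GeneTree", function(object) {
  msg <- character()
  if (!inherits(object@tree, "phylo")) msg <- c(msg, "tree must be a phylo")
  else {
    nn <- object@tree$Nnode
    if (length(object@support) != nn)
      msg <- c(msg, "support must have one entry per internal node")
    if (length(object@event) != nn)
      msg <- c(msg, "event must have one entry per internal node")
    bad <- !is.na(object@support) &
      (object@support < 0L | object@support > 100L)
    if (any(bad)) msg <- c(msg, "support values must lie in [0, 100]")
    ev <- object@event
    if (any(!is.na(ev) & !ev %in% c("speciation", "duplication", "unresolved")))
      msg <- c(msg, "event labels must be speciation/duplication/unresolved")
    if (!object@rooted && any(!is.na(ev)))
      msg <- c(msg, "event labels are only defined on rooted trees")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a gene tree
#'
#' @param tree a `phylo` object.
#' @param support integer vector of bootstrap supports per internal node;
#'   defaults to integer `node.label`s when present.
#' @param event optional character vector of event labels.
#' @param rooted logical; defaults to [ape::is.rooted()].
#' @param speciesMap optional named character vector tip label -> species
#'   code, overriding the prefix-before-underscore convention.
#' @return a [GeneTree-class] object.
#' @export
geneTree <- function(tree, support = NULL, event = NULL, rooted = NULL,
                     speciesMap = character()) {
  stopifnot(inherits(tree, "phylo"))
  nn <- tree$Nnode
  if (is.null(support)) {
    if (!is.null(tree$node.label)) {
      lab <- tree$node.label
      lab[lab == ""] <- NA_character_
      support <- suppressWarnings(as.integer(lab))
      if (any(!is.na(lab) & is.na(support)))
        stop("internal node labels must be integer bootstrap values 0-100")
    } else {
      support <- rep(NA_integer_, nn)
    }
  }
  if (is.null(event)) event <- rep(NA_character_, nn)
  if (is.null(rooted)) rooted <- ape::is.rooted(tree)
  new("GeneTree", tree = tree, support = as.integer(support),
      event = as.character(event), rooted = isTRUE(rooted),
      speciesMap = speciesMap)
}

#' Species tree with taxonomic group labels
#'
#' @slot tree rooted `phylo` whose tips are species codes.
#' @slot groupOf named character vector species code -> taxonomic group
#'   label; the groups partition the species set.
#' @slot divergenceBand named character vector group -> approximate
#'   divergence range with the focal species, in million years.
#' @export
setClass("SpeciesTaxonomy",
  slots = c(tree = "ANY", groupOf = "character", divergenceBand = "character"))

setValidity("SpeciesTaxonomy", function(object) {
  msg <- character()
  if (!inherits(object@tree, "phylo")) msg <- c(msg, "tree must be a phylo")
  else {
    if (!ape::is.rooted(object@tree)) msg <- c(msg, "species tree must be rooted")
    missing <- setdiff(object@tree$tip.label, names(object@groupOf))
    if (length(missing))
      msg <- c(msg, paste("species without a group label:",
                          paste(missing, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a species taxonomy
#'
#' @param tree rooted `phylo` over species codes.
#' @param groupOf named character vector species code -> group label.
#' @param divergenceBand optional named character vector group -> divergence
#'   range (million years).
#' @return a [SpeciesTaxonomy-class] object.
#' @export
speciesTaxonomy <- function(tree, groupOf, divergenceBand = character()) {
  new("SpeciesTaxonomy", tree = tree, groupOf = groupOf,
      divergenceBand = divergenceBand)
}

#' Simulated gene-family ground truth
#'
#' Output of [simulateGeneFamily()]: the true gene tree (supports 100), the
#' true per-node event labels from the birth-death process, the true
#' hierarchical ortholog partition and event counts.
#'
#' @slot geneTree a [GeneTree-class] with true event labels.
#' @slot partition named character vector protein id -> group label.
#' @slot parentGroup named character vector group label -> parent group
#'   label (`NA` at the top level).
#' @slot dupCount integer, duplication events drawn.
#' @slot lossCount integer, loss events drawn.
#' @slot seed integer seed used.
#' @export
setClass("FamilyTruth",
  slots = c(geneTree = "GeneTree", partition = "character",
            parentGroup = "character", dupCount = "integer",
            lossCount = "integer", seed = "integer"))

#' Congruence report between two ortholog databases
#'
#' @slot perFog data.frame with one row per comparable FOG: `fog_id`,
#'   `category` (congruent/over/under/over_and_under/none), `n_labeled`,
#'   `n_unlabeled` (coverage note for mixed groups).
#' @slot summary data.frame with `category`, `count`, `pct_raw`, `pct`
#'   (integer-rounded) over comparable FOGs.
#' @slot nComparable integer.
#' @export
setClass("CongruenceReport",
  slots = c(perFog = "data.frame", summary = "data.frame",
            nComparable = "integer"))

#' External database labelling
#'
#' @slot labels named character vector protein id -> external group label
#'   (proteins absent from the external database are simply missing).
#' @slot speciesCovered character vector of species codes present in the
#'   external database.
#' @export
setClass("ExternalLabeling",
  slots = c(labels = "character", speciesCovered = "character"))

#' Construct an external labelling
#'
#' @param labels named character vector protein id -> external group label.
#' @param speciesCovered character vector of covered species codes.
#' @return an [ExternalLabeling-class] object.
#' @export
externalLabeling <- function(labels, speciesCovered) {
  labels <- labels[!is.na(labels)]
  new("ExternalLabeling", labels = labels,
      speciesCovered = as.character(speciesCovered))
}
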