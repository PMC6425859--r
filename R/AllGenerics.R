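## Accessors and show methods.

#' @rdname OrthologCatalog-class
#' @param object,catalog an `OrthologCatalog`.
#' @export
setGeneric("proteinTable", function(catalog) standardGeneric("proteinTable"))

#' @rdname OrthologCatalog-class
#' @export
setMethod("proteinTable", "OrthologCatalog", function(catalog) catalog@proteins)

#' @rdname OrthologCatalog-class
#' @export
setGeneric("fogTable", function(catalog) standardGeneric("fogTable"))

#' @rdname OrthologCatalog-class
#' @export
setMethod("fogTable", "OrthologCatalog", function(catalog) catalog@fogs)

#' FOG assignment of each protein
#'
#' @param catalog an `OrthologCatalog`.
#' @return named character vector protein id -> FOG id (`NA` = unassigned).
#' @export
fogOf <- function(catalog) {
  stats::setNames(catalog@proteins$fog_id, catalog@proteins$protein_id)
}

#' HOG of each FOG
#'
#' @param catalog an `OrthologCatalog`.
#' @return named character vector FOG id -> HOG id.
#' @export
hogOf <- function(catalog) {
  stats::setNames(catalog@fogs$hog_id, catalog@fogs$fog_id)
}

#' Parent FOG of each FOG
#'
#' @param catalog an `OrthologCatalog`.
#' @return named character vector FOG id -> parent FOG id (`NA` = top level).
#' @export
parentFogOf <- function(catalog) {
  stats::setNames(catalog@fogs$parent_fog, catalog@fogs$fog_id)
}

#' Curation status of each FOG
#'
#' @param catalog an `OrthologCatalog`.
#' @return named character vector FOG id -> status.
#' @export
statusOf <- function(catalog) {
  stats::setNames(catalog@fogs$status, catalog@fogs$fog_id)
}

#' @rdname OrthologCatalog-class
#' @export
nProteins <- function(catalog) nrow(catalog@proteins)

#' @rdname OrthologCatalog-class
#' @export
nFogs <- function(catalog) length(unique(catalog@fogs$fog_id))

#' @rdname OrthologCatalog-class
#' @export
nHogs <- function(catalog) length(unique(catalog@fogs$hog_id))

setMethod("show", "OrthologCatalog", function(object) {
  assigned <- sum(!is.na(object@proteins$fog_id))
  cat("OrthologCatalog with", nrow(object@proteins), "proteins (",
      assigned, "assigned ),", nFogs(object), "FOGs,",
      nHogs(object), "HOGs\n")
  st <- table(object@fogs$status)
  if (length(st))
    cat("  status:", paste(names(st), st, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "GeneTree", function(object) {
  cat("GeneTree with", length(object@tree$tip.label), "tips,",
      object@tree$Nnode, "internal nodes;",
      if (object@rooted) "rooted" else "unrooted", "\n")
  ev <- table(object@event, useNA = "no")
  if (length(ev))
    cat("  events:", paste(names(ev), ev, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "SpeciesTaxonomy", function(object) {
  cat("SpeciesTaxonomy with", length(object@tree$tip.label), "species in",
      length(unique(object@groupOf)), "groups\n")
})

setMethod("show", "CongruenceReport", function(object) {
  cat("CongruenceReport over", object@nComparable, "comparable FOGs\n")
  print(object@summary, row.names = FALSE)
})

setMethod("show", "FamilyTruth", function(object) {
  cat("FamilyTruth:", length(object@geneTree@tree$tip.label), "proteins,",
      object@dupCount, "duplications,", object@lossCount, "losses,",
      length(unique(object@partition)), "ortholog groups\n")
})

#' Species tree of a taxonomy
#'
#' @param taxonomy a `SpeciesTaxonomy`.
#' @return the underlying `phylo`.
#' @export
speciesTree <- function(taxonomy) taxonomy@tree

#' Group label of each species
#'
#' @param taxonomy a `SpeciesTaxonomy`.
#' @return named character vector species code -> group label.
#' @export
groupOf <- function(taxonomy) taxonomy@groupOf

#' Species code of every tip of a gene tree
#'
#' Tips named `<species>_<accession>` resolve to the token before the first
#' underscore unless the tree carries an explicit tip -> species map
#' (accessions themselves may contain underscores).
#'
#' @param gtree a `GeneTree`.
#' @return character vector parallel to `tree$tip.label`.
#' @export
leafSpecies <- function(gtree) {
  tips <- gtree@tree$tip.label
  sp <- sub("^([^_]+)_.*$", "\\1", tips)
  if (length(gtree@speciesMap)) {
    hit <- tips %in% names(gtree@speciesMap)
    sp[hit] <- unname(gtree@speciesMap[tips[hit]])
  }
  sp
}

#' Bootstrap supports of a gene tree
#'
#' @param gtree a `GeneTree`.
#' @return integer vector, one entry per internal node.
#' @export
treeSupport <- function(gtree) gtree@support

#' Event labels of a gene tree
#'
#' @param gtree a `GeneTree`.
#' @return character vector, one entry per internal node (`NA` until
#'   [inferNodeEvents()] has run).
#' @export
nodeEvents <- function(gtree) gtree@event

#' Field-by-field catalog comparison
#'
#' Row order is not meaningful in a catalog; two catalogs are identical when
#' their protein and FOG tables agree after sorting.  Used for the
#' write-then-read round-trip checks.
#'
#' @param a,b `OrthologCatalog` objects.
#' @return logical scalar.
#' @export
catalogIdentical <- function(a, b) {
  normP <- function(x) {
    p <- x@proteins[order(x@proteins$protein_id), PROTEIN_COLS]
    rownames(p) <- NULL
    p
  }
  normF <- function(x) {
    f <- unique(x@fogs[order(x@fogs$fog_id), FOG_COLS])
    rownames(f) <- NULL
    f
  }
  identical(normP(a), normP(b)) && identical(normF(a), normF(b))
}
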