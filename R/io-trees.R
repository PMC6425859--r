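## Newick gene-tree I/O.  Internal node labels, when present, are bootstrap
## supports (integers 0-100); unlabeled nodes get support NA.  Event labels
## are an in-memory annotation and are never serialised, so reading a
## written tree can never corrupt them.

#' Read a gene tree from Newick
#'
#' @param source a file path (gzip accepted) or a literal Newick string
#'   (detected by a terminal semicolon).
#' @param taxonomy optional [SpeciesTaxonomy-class]; when given, every tip's
#'   species code must be one of its species.
#' @param speciesMap optional named character vector tip label -> species
#'   code, overriding the prefix-before-first-underscore convention.
#' @return a [GeneTree-class].
#' @examples
#' gt <- readGeneTree("((sce_P1:1,klc_P2:1)79:1,spo_P3:1);")
#' treeSupport(gt)
#' @export
readGeneTree <- function(source, taxonomy = NULL, speciesMap = character()) {
  txt <- if (length(source) == 1L && grepl(";\\s*$", source)) source
         else paste(readInputLines(source), collapse = "")
  opened <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  closed <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (opened != closed)
    stop("unbalanced parentheses in Newick near character ",
         max(nchar(sub("\\).*$", "", txt)), 1L))
  phy <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(phy)) stop("could not parse Newick input")
  gt <- geneTree(phy, speciesMap = speciesMap)
  bad <- !is.na(gt@support) & (gt@support < 0L | gt@support > 100L)
  if (any(bad))
    stop("bootstrap support outside [0, 100]: ", gt@support[which(bad)[1L]])
  if (!is.null(taxonomy)) {
    sp <- leafSpecies(gt)
    unknown <- which(!sp %in% taxonomy@tree$tip.label)
    if (length(unknown))
      stop("leaf not resolvable to a known species: ",
           phy$tip.label[unknown[1L]])
  }
  gt
}

#' Write a gene tree to Newick
#'
#' Supports are written as internal node labels only where defined; branch
#' lengths and topology round-trip through [readGeneTree()].
#'
#' @param gtree a [GeneTree-class].
#' @param path optional output file; when `NULL` the Newick string is
#'   returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
writeGeneTree <- function(gtree, path = NULL) {
  phy <- gtree@tree
  phy$node.label <- ifelse(is.na(gtree@support), "",
                           as.character(gtree@support))
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
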