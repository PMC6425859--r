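## Assignment-table readers and writers: TSV, JSON, orthoXML.
##
## The TSV dialect has a header and the columns
##   protein_id  species_code  fog_id  hog_id  parent_fog  status  length  annotation_source
## with empty fields for missing values, one row per protein, rows sorted by
## (species_code, protein_id) on output for deterministic diffs.
##
## The JSON schema (this package defines its own, documented here) is
##   { "proteins": [ {protein_id, species_code, length, annotation_source,
##                    fog_id|null} ... ],
##     "fogs":     [ {fog_id, hog_id, parent_fog|null, status} ... ],
##     "metadata": { ... } }
##
## orthoXML follows the 0.3 layout; the HOG id, parent FOG and status travel
## as <property> tags on each <orthologGroup> because orthoXML has no native
## multi-level group pairing, and protein length / annotation source are
## carried as extra attributes on <gene> so the format round-trips.

ASSIGNMENT_FORMATS <- c("tsv", "json", "orthoxml")

#' Read an ortholog-assignment table
#'
#' @param path file path (gzip accepted) of a TSV, JSON or orthoXML
#'   assignment file.
#' @param format one of `"tsv"`, `"json"`, `"orthoxml"`.
#' @return an [OrthologCatalog-class].
#' @seealso [writeAssignments()]
#' @export
readAssignments <- function(path, format = c("tsv", "json", "orthoxml")) {
  format <- match.arg(format)
  switch(format,
         tsv = readAssignmentsTsv(path),
         json = readAssignmentsJson(path),
         orthoxml = readAssignmentsOrthoxml(path))
}

#' Write an ortholog-assignment table
#'
#' @param catalog an [OrthologCatalog-class]; must pass [validateCatalog()].
#' @param path output file path.
#' @param format one of `"tsv"`, `"json"`, `"orthoxml"`.
#' @return `path`, invisibly.
#' @export
writeAssignments <- function(catalog, path,
                             format = c("tsv", "json", "orthoxml")) {
  format <- match.arg(format)
  viol <- validateCatalog(catalog)
  if (nrow(viol))
    stop("refusing to write an invalid catalog: ", viol$message[1L],
         " (", viol$ids[1L], ")")
  switch(format,
         tsv = writeAssignmentsTsv(catalog, path),
         json = writeAssignmentsJson(catalog, path),
         orthoxml = writeAssignmentsOrthoxml(catalog, path))
  invisible(path)
}

## ---- TSV ----

TSV_COLS <- c("protein_id", "species_code", "fog_id", "hog_id",
              "parent_fog", "status", "length", "annotation_source")

readAssignmentsTsv <- function(path) {
  lines <- readInputLines(path)
  if (!length(lines)) stop("empty assignment file: ", path)
  tab <- utils::read.delim(text = lines, stringsAsFactors = FALSE,
                           na.strings = "", colClasses = "character")
  missing <- setdiff(c("protein_id", "species_code", "fog_id", "hog_id"),
                     names(tab))
  if (length(missing))
    stop("assignment TSV is missing required column(s): ",
         paste(missing, collapse = ", "))
  dup <- tab$protein_id[duplicated(tab$protein_id)]
  if (length(dup))
    stop("duplicate protein_id in assignment table: ", dup[1L])
  badRows <- which(!is.na(tab$fog_id) & is.na(tab$hog_id))
  if (length(badRows))
    stop("FOG without HOG at line ", badRows[1L] + 1L, " (",
         tab$protein_id[badRows[1L]], ")")
  if (is.null(tab$length)) tab$length <- NA_character_
  if (is.null(tab$parent_fog)) tab$parent_fog <- NA_character_
  if (is.null(tab$status)) tab$status <- NA_character_
  if (is.null(tab$annotation_source)) tab$annotation_source <- NA_character_
  proteins <- data.frame(
    protein_id = tab$protein_id,
    species_code = tab$species_code,
    length = suppressWarnings(as.integer(tab$length)),
    annotation_source = ifelse(is.na(tab$annotation_source),
                               "genome_annotation", tab$annotation_source),
    fog_id = tab$fog_id, stringsAsFactors = FALSE)
  assigned <- !is.na(tab$fog_id)
  fogs <- unique(data.frame(
    fog_id = tab$fog_id[assigned],
    hog_id = tab$hog_id[assigned],
    parent_fog = tab$parent_fog[assigned],
    status = ifelse(is.na(tab$status[assigned]), "predicted",
                    tab$status[assigned]),
    stringsAsFactors = FALSE))
  fogs <- fogs[order(fogs$fog_id), , drop = FALSE]
  OrthologCatalog(proteins, fogs)
}

writeAssignmentsTsv <- function(catalog, path) {
  pr <- catalog@proteins
  fg <- catalog@fogs
  idx <- match(pr$fog_id, fg$fog_id)
  tab <- data.frame(
    protein_id = pr$protein_id,
    species_code = pr$species_code,
    fog_id = pr$fog_id,
    hog_id = fg$hog_id[idx],
    parent_fog = fg$parent_fog[idx],
    status = fg$status[idx],
    length = pr$length,
    annotation_source = pr$annotation_source,
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$species_code, tab$protein_id), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
}

## ---- JSON ----

readAssignmentsJson <- function(path) {
  obj <- jsonlite::fromJSON(paste(readInputLines(path), collapse = "\n"),
                            simplifyVector = TRUE)
  if (is.null(obj$proteins))
    stop("assignment JSON is missing the 'proteins' array")
  pr <- as.data.frame(obj$proteins, stringsAsFactors = FALSE)
  dup <- pr$protein_id[duplicated(pr$protein_id)]
  if (length(dup)) stop("duplicate protein_id in assignment JSON: ", dup[1L])
  fg <- if (!is.null(obj$fogs) && length(obj$fogs))
    as.data.frame(obj$fogs, stringsAsFactors = FALSE) else NULL
  OrthologCatalog(pr, fg, metadata = as.list(obj$metadata %||% list()))
}

writeAssignmentsJson <- function(catalog, path) {
  pr <- catalog@proteins
  pr <- pr[order(pr$species_code, pr$protein_id),
           c("protein_id", "species_code", "length", "annotation_source",
             "fog_id")]
  fg <- catalog@fogs[order(catalog@fogs$fog_id), , drop = FALSE]
  obj <- list(proteins = pr, fogs = fg, metadata = catalog@metadata)
  jsonlite::write_json(obj, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

## ---- orthoXML ----

ORTHOXML_NS <- "http://orthoXML.org/2011/"

readAssignmentsOrthoxml <- function(path) {
  txt <- paste(readInputLines(path), collapse = "\n")
  doc <- tryCatch(xml2::read_xml(txt), error = function(e)
    stop("malformed orthoXML: ", conditionMessage(e)))
  ns <- c(ox = ORTHOXML_NS)
  geneNodes <- xml2::xml_find_all(doc, ".//ox:gene", ns)
  if (!length(geneNodes)) {
    ns <- character()
    geneNodes <- xml2::xml_find_all(doc, ".//gene")
  }
  getAll <- function(xpath) {
    if (length(ns)) xml2::xml_find_all(doc, xpath, ns)
    else xml2::xml_find_all(doc, gsub("ox:", "", xpath, fixed = TRUE))
  }
  ids <- xml2::xml_attr(geneNodes, "id")
  protIds <- xml2::xml_attr(geneNodes, "protId")
  lengths <- suppressWarnings(as.integer(xml2::xml_attr(geneNodes, "length")))
  src <- xml2::xml_attr(geneNodes, "annotationSource")
  species <- vapply(geneNodes, function(g) {
    anc <- xml2::xml_find_first(g, "ancestor::*[local-name()='species']")
    xml2::xml_attr(anc, "name")
  }, character(1))
  dup <- protIds[duplicated(protIds)]
  if (length(dup)) stop("duplicate protein id in orthoXML: ", dup[1L])

  groupNodes <- getAll(".//ox:orthologGroup")
  fogRows <- list()
  geneFog <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (g in groupNodes) {
    fog <- xml2::xml_attr(g, "id")
    props <- xml2::xml_find_all(g, "./*[local-name()='property']")
    pv <- stats::setNames(xml2::xml_attr(props, "value"),
                          xml2::xml_attr(props, "name"))
    refs <- xml2::xml_find_all(g, "./*[local-name()='geneRef']")
    refIds <- xml2::xml_attr(refs, "id")
    geneFog[refIds] <- fog
    fogRows[[length(fogRows) + 1L]] <- data.frame(
      fog_id = fog,
      hog_id = unname(pv["hog_id"]),
      parent_fog = if ("parent_fog" %in% names(pv)) unname(pv["parent_fog"])
                   else NA_character_,
      status = if ("status" %in% names(pv)) unname(pv["status"])
               else "predicted",
      stringsAsFactors = FALSE)
  }
  proteins <- data.frame(
    protein_id = protIds, species_code = species, length = lengths,
    annotation_source = ifelse(is.na(src), "genome_annotation", src),
    fog_id = unname(geneFog[ids]), stringsAsFactors = FALSE)
  fogs <- if (length(fogRows)) do.call(rbind, fogRows) else NULL
  if (!is.null(fogs)) fogs <- fogs[order(fogs$fog_id), , drop = FALSE]
  OrthologCatalog(proteins, fogs)
}

writeAssignmentsOrthoxml <- function(catalog, path) {
  pr <- catalog@proteins
  pr <- pr[order(pr$species_code, pr$protein_id), , drop = FALSE]
  fg <- catalog@fogs[order(catalog@fogs$fog_id), , drop = FALSE]
  geneNum <- stats::setNames(seq_len(nrow(pr)), pr$protein_id)

  doc <- xml2::xml_new_root("orthoXML", xmlns = ORTHOXML_NS, version = "0.3",
                            origin = "OrthoCurator",
                            originVersion = as.character(
                              utils::packageVersion("OrthoCurator")))
  for (sp in unique(pr$species_code)) {
    spNode <- xml2::xml_add_child(doc, "species", name = sp, NCBITaxId = "0")
    db <- xml2::xml_add_child(spNode, "database", name = "catalog",
                              version = "0")
    genes <- xml2::xml_add_child(db, "genes")
    rows <- which(pr$species_code == sp)
    for (i in rows) {
      xml2::xml_add_child(genes, "gene",
                          id = as.character(geneNum[[pr$protein_id[i]]]),
                          protId = pr$protein_id[i],
                          length = as.character(pr$length[i]),
                          annotationSource = pr$annotation_source[i])
    }
  }
  groups <- xml2::xml_add_child(doc, "groups")
  for (i in seq_len(nrow(fg))) {
    grp <- xml2::xml_add_child(groups, "orthologGroup", id = fg$fog_id[i])
    xml2::xml_add_child(grp, "property", name = "hog_id",
                        value = fg$hog_id[i])
    if (!is.na(fg$parent_fog[i]))
      xml2::xml_add_child(grp, "property", name = "parent_fog",
                          value = fg$parent_fog[i])
    xml2::xml_add_child(grp, "property", name = "status",
                        value = fg$status[i])
    members <- pr$protein_id[!is.na(pr$fog_id) & pr$fog_id == fg$fog_id[i]]
    for (m in members)
      xml2::xml_add_child(grp, "geneRef",
                          id = as.character(geneNum[[m]]))
  }
  xml2::write_xml(doc, path)
}
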