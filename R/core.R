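#' Check the domain invariants of a catalog
#'
#' Violations are data, not exceptions: a catalog read from a broken file can
#' be inspected and repaired.  The rules checked are the catalog invariants:
#' unique protein ids, positive lengths, sequence/length agreement, FOG and
#' HOG id format (`FOG`/`HOG` plus a zero-padded integer of at least five
#' digits), every assigned FOG present in the FOG table, every FOG mapped to
#' exactly one HOG, an acyclic parent map whose parents live in the same
#' HOG, and valid status / annotation-source labels.
#'
#' @param catalog an [OrthologCatalog-class].
#' @return data.frame with columns `rule`, `ids` (comma-separated offending
#'   identifiers) and `message`; zero rows iff the catalog is valid.
#' @examples
#' pr <- data.frame(protein_id = "sce_P1", species_code = "sce", length = 10L,
#'                  fog_id = "FOG00001")
#' fg <- data.frame(fog_id = "FOG00001", hog_id = "HOG00001")
#' validateCatalog(OrthologCatalog(pr, fg))
#' @export
validateCatalog <- function(catalog) {
  pr <- catalog@proteins
  fg <- catalog@fogs
  out <- list()
  flag <- function(rule, ids, message) {
    out[[length(out) + 1L]] <<- data.frame(
      rule = rule, ids = paste(unique(ids), collapse = ","),
      message = message, stringsAsFactors = FALSE)
  }

  dup <- pr$protein_id[duplicated(pr$protein_id)]
  if (length(dup))
    flag("unique_protein_id", dup, "duplicated protein identifiers")
  bad <- pr$protein_id[is.na(pr$length) | pr$length < 1L]
  if (length(bad)) flag("positive_length", bad, "protein length must be >= 1")
  hasSeq <- !is.na(pr$sequence)
  mism <- pr$protein_id[hasSeq & nchar(pr$sequence) != pr$length]
  if (length(mism))
    flag("sequence_length", mism, "sequence length disagrees with length field")
  badSrc <- pr$protein_id[!pr$annotation_source %in% ANNOTATION_SOURCES]
  if (length(badSrc))
    flag("annotation_source", badSrc, "unknown annotation source")

  badFog <- fg$fog_id[!grepl("^FOG[0-9]{5,}$", fg$fog_id)]
  if (length(badFog)) flag("fog_id_format", badFog,
                           "FOG ids must match FOG + zero-padded integer")
  badHog <- fg$hog_id[!is.na(fg$hog_id) & !grepl("^HOG[0-9]{5,}$", fg$hog_id)]
  if (length(badHog)) flag("hog_id_format", badHog,
                           "HOG ids must match HOG + zero-padded integer")
  noHog <- fg$fog_id[is.na(fg$hog_id)]
  if (length(noHog)) flag("fog_without_hog", noHog, "FOG without HOG")

  multi <- tapply(fg$hog_id, fg$fog_id, function(h) length(unique(h)))
  multi <- names(multi)[multi > 1L]
  if (length(multi))
    flag("one_hog_per_fog", multi, "FOG maps to more than one HOG")

  assigned <- pr$fog_id[!is.na(pr$fog_id)]
  orphan <- setdiff(assigned, fg$fog_id)
  if (length(orphan))
    flag("fog_declared", orphan, "protein assigned to undeclared FOG")

  badStatus <- fg$fog_id[!fg$status %in% FOG_STATUSES]
  if (length(badStatus)) flag("status", badStatus, "unknown FOG status")

  parent <- stats::setNames(fg$parent_fog, fg$fog_id)
  hog <- stats::setNames(fg$hog_id, fg$fog_id)
  hasParent <- !is.na(parent)
  unknownParent <- names(parent)[hasParent & !parent %in% fg$fog_id]
  if (length(unknownParent))
    flag("parent_declared", unknownParent, "parent FOG not in catalog")
  known <- names(parent)[hasParent & parent %in% fg$fog_id]
  crossHog <- known[hog[known] != hog[parent[known]]]
  if (length(crossHog))
    flag("parent_same_hog", crossHog, "parent FOG lies in a different HOG")

  ## cycle detection by walking each chain with a visited set
  inCycle <- character()
  state <- stats::setNames(rep(0L, length(parent)), names(parent)) # 0 new 1 open 2 done
  for (start in names(parent)) {
    if (state[start] != 0L) next
    chain <- character()
    x <- start
    while (!is.na(x) && x %in% names(state) && state[x] == 0L) {
      state[x] <- 1L
      chain <- c(chain, x)
      x <- parent[[x]]
    }
    if (!is.na(x) && x %in% names(state) && state[x] == 1L) {
      cycleStart <- match(x, chain)
      inCycle <- c(inCycle, chain[cycleStart:length(chain)])
    }
    state[chain] <- 2L
  }
  if (length(inCycle))
    flag("cycle", sort(unique(inCycle)), "parent_fog map contains a cycle")

  if (!length(out))
    return(data.frame(rule = character(), ids = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Summary statistics of a catalog
#'
#' The assigned fraction is reported both raw and rounded to the nearest
#' integer percent (half away from zero), mirroring how database release
#' tables print it.
#'
#' @param catalog an [OrthologCatalog-class] with at least one protein.
#' @return list with `nProteins`, `nAssigned`, `assignedPctRaw`,
#'   `assignedPct` (integer), `nFogs`, `nHogs` and `statusCounts` (named
#'   integer vector over FOG statuses).
#' @examples
#' pr <- data.frame(protein_id = sprintf("sce_P%d", 1:8),
#'                  species_code = "sce", length = 100L,
#'                  fog_id = c(rep("FOG00001", 3), rep(NA, 5)))
#' fg <- data.frame(fog_id = "FOG00001", hog_id = "HOG00001")
#' catalogStatistics(OrthologCatalog(pr, fg))$assignedPct  # 38
#' @export
catalogStatistics <- function(catalog) {
  pr <- catalog@proteins
  if (!nrow(pr)) stop("catalog has zero proteins")
  nAssigned <- sum(!is.na(pr$fog_id))
  raw <- 100 * nAssigned / nrow(pr)
  status <- statusOf(catalog)
  status <- status[!duplicated(names(status))]
  counts <- vapply(FOG_STATUSES, function(s) sum(status == s, na.rm = TRUE),
                   integer(1))
  list(nProteins = nrow(pr),
       nAssigned = nAssigned,
       assignedPctRaw = raw,
       assignedPct = as.integer(roundHalfUp(raw)),
       nFogs = nFogs(catalog),
       nHogs = nHogs(catalog),
       statusCounts = counts)
}
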