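## Stage 1: reconcile graph-based ortholog groups (FOGs) with an external
## homolog-family labelling into HOGs, then seed new FOGs for labelled but
## unclustered proteins.

## Majority homolog label per FOG; ties broken by the lexicographically
## smallest label so conflict resolution is deterministic.
majorityLabelPerFog <- function(catalog, labeling) {
  pr <- catalog@proteins
  assigned <- pr[!is.na(pr$fog_id), c("protein_id", "fog_id")]
  assigned$label <- unname(labeling[assigned$protein_id])
  labelled <- assigned[!is.na(assigned$label), , drop = FALSE]
  fogs <- sort(unique(assigned$fog_id))
  major <- stats::setNames(rep(NA_character_, length(fogs)), fogs)
  conflicts <- list()
  for (fog in unique(labelled$fog_id)) {
    counts <- sort(table(labelled$label[labelled$fog_id == fog]),
                   decreasing = TRUE)
    winners <- names(counts)[counts == max(counts)]
    major[fog] <- min(winners)
    if (length(counts) > 1L) {
      conflicts[[length(conflicts) + 1L]] <- data.frame(
        fog_id = fog, label = names(counts), count = as.integer(counts),
        stringsAsFactors = FALSE)
    }
  }
  conflicts <- if (length(conflicts)) do.call(rbind, conflicts)
  else data.frame(fog_id = character(), label = character(),
                  count = integer(), stringsAsFactors = FALSE)
  list(major = major, conflicts = conflicts)
}

#' Coalesce FOGs into HOGs by homolog-family labels
#'
#' Each FOG takes the majority homolog label of its labelled members (ties
#' go to the lexicographically smallest label); FOGs sharing a label share a
#' HOG.  FOGs whose members are all unlabelled each get a fresh singleton
#' HOG rather than being pooled, to avoid asserting homology the labelling
#' does not support.  Conflicting FOGs (two or more distinct member labels)
#' are reported, not rejected.  Protein -> FOG assignments are never
#' changed, only the FOG -> HOG map is filled.
#'
#' HOG ids are assigned deterministically: distinct labels in sorted order,
#' then unlabelled FOGs in FOG-id order.
#'
#' @param catalog an [OrthologCatalog-class]; any existing HOG ids are
#'   recomputed.
#' @param labeling named character vector protein id -> homolog label
#'   (proteins without a label simply absent or `NA`).
#' @return list with `catalog` (HOGs filled) and `conflicts` (data.frame
#'   `fog_id`, `label`, `count`, one block per conflicted FOG).
#' @export
coalesceFogsToHogs <- function(catalog, labeling) {
  res <- majorityLabelPerFog(catalog, labeling)
  major <- res$major
  fogs <- names(major)
  labels <- sort(unique(major[!is.na(major)]))
  hogOfLabel <- stats::setNames(formatGroupId("HOG", seq_along(labels)),
                                labels)
  unlab <- fogs[is.na(major)]
  hogOfUnlab <- stats::setNames(
    formatGroupId("HOG", length(labels) + seq_along(unlab)), unlab)
  fg <- catalog@fogs
  if (!nrow(fg) && length(fogs)) {
    fg <- data.frame(fog_id = fogs, hog_id = NA_character_,
                     parent_fog = NA_character_, status = "predicted",
                     stringsAsFactors = FALSE)
  }
  hog <- ifelse(is.na(major[fg$fog_id]),
                hogOfUnlab[fg$fog_id],
                hogOfLabel[major[fg$fog_id]])
  fg$hog_id <- unname(hog)
  out <- OrthologCatalog(catalog@proteins, fg, catalog@metadata)
  out@metadata$labelHog <- hogOfLabel
  list(catalog = out, conflicts = res$conflicts)
}

#' Seed singleton FOGs for labelled but unclustered proteins
#'
#' Every labelled protein that no FOG claimed receives a new singleton FOG
#' inside the HOG of its label (creating the HOG when the label was never
#' seen); unlabelled, unclustered proteins stay unassigned.  New FOGs are
#' flagged `electronically_modified`.
#'
#' @param catalog an [OrthologCatalog-class], normally the output of
#'   [coalesceFogsToHogs()].
#' @param labeling named character vector protein id -> homolog label.
#' @return the catalog with the new FOGs added.
#' @export
seedFogsForUnclustered <- function(catalog, labeling) {
  pr <- catalog@proteins
  orphan <- pr$protein_id[is.na(pr$fog_id)]
  orphanLab <- labeling[orphan]
  orphan <- orphan[!is.na(orphanLab)]
  if (!length(orphan)) return(catalog)
  orphan <- sort(orphan)

  hogOfLabel <- catalog@metadata$labelHog
  if (is.null(hogOfLabel)) {
    hogOfLabel <- majorityLabelToHog(catalog, labeling)
  }
  newFogs <- nextGroupIds(catalog@fogs$fog_id, length(orphan), "FOG")
  labs <- unname(labeling[orphan])
  newLabels <- sort(setdiff(unique(labs), names(hogOfLabel)))
  if (length(newLabels)) {
    fresh <- nextGroupIds(catalog@fogs$hog_id, length(newLabels), "HOG")
    hogOfLabel <- c(hogOfLabel, stats::setNames(fresh, newLabels))
  }
  fg <- rbind(catalog@fogs, data.frame(
    fog_id = newFogs, hog_id = unname(hogOfLabel[labs]),
    parent_fog = NA_character_, status = "electronically_modified",
    stringsAsFactors = FALSE))
  pr$fog_id[match(orphan, pr$protein_id)] <- newFogs
  out <- OrthologCatalog(pr, fg, catalog@metadata)
  out@metadata$labelHog <- hogOfLabel
  out
}

## Reconstruct the label -> HOG map from an already-coalesced catalog.
majorityLabelToHog <- function(catalog, labeling) {
  res <- majorityLabelPerFog(catalog, labeling)
  major <- res$major[!is.na(res$major)]
  if (!length(major)) return(stats::setNames(character(), character()))
  hog <- hogOf(catalog)
  hog <- hog[!duplicated(names(hog))]
  map <- tapply(unname(hog[names(major)]), unname(major), function(h) min(h))
  stats::setNames(as.character(map), names(map))
}
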