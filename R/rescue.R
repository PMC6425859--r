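## Stage 3: classify annotation gaps and admit rescued proteins into
## FOG/HOGs from parsed similarity and placement tables.

#' Classify an annotation gap
#'
#' A protein that is annotated but escaped clustering, yet has a genomic
#' similarity hit, is `misidentified`; a genomic hit with no annotated
#' protein at all is `unidentified`; anything else is no gap.
#'
#' @param genomeHit logical, a genomic (e.g. translated-search) hit exists.
#' @param annotated logical, the genome annotation contains the protein.
#' @param inFog logical, the protein is already in a FOG (implies
#'   `annotated`).
#' @return one of `"misidentified"`, `"unidentified"`, `"none"`.
#' @export
classifyGap <- function(genomeHit, annotated, inFog) {
  if (inFog && !annotated)
    stop("inconsistent flags: a protein in a FOG must be annotated")
  if (annotated && !inFog && genomeHit) return("misidentified")
  if (!annotated && genomeHit) return("unidentified")
  "none"
}

#' Filter rescue candidates by relative length
#'
#' Candidates shorter than `fraction` of the mean group member length are
#' discarded as likely gene-model fragments; a candidate exactly at the
#' boundary is kept.
#'
#' @param candidates data.frame with `candidate_id` and `length`.
#' @param fogMeanLength positive mean sequence length of the target group.
#' @param fraction length fraction in (0, 1]; default 0.75.
#' @return list with `kept` and `discarded` data.frames.
#' @export
lengthFilter <- function(candidates, fogMeanLength, fraction = 0.75) {
  stopifnot(fogMeanLength > 0, fraction > 0, fraction <= 1)
  if (!nrow(candidates))
    return(list(kept = candidates, discarded = candidates))
  keep <- candidates$length >= fraction * fogMeanLength
  list(kept = candidates[keep, , drop = FALSE],
       discarded = candidates[!keep, , drop = FALSE])
}

#' Assign a HOG by best similarity hit
#'
#' The candidate inherits the HOG of its best-scoring subject (maximal bit
#' score; ties broken by smaller expect value, then lexicographic subject
#' id).  Subjects without a HOG are ignored; a candidate with no usable hit
#' is flagged unplaceable.
#'
#' @param hits data.frame of hit records for one candidate (columns of
#'   [readHitTable()]).
#' @param catalog an [OrthologCatalog-class] supplying subject FOG/HOGs.
#' @return list with `hog_id` (`NA` when unplaceable), `subject_id` and
#'   `unplaceable` (logical).
#' @export
assignHogByBestHit <- function(hits, catalog) {
  fog <- fogOf(catalog)
  hog <- hogOf(catalog)
  hits <- hits[hits$subject_id %in% names(fog), , drop = FALSE]
  subjFog <- fog[hits$subject_id]
  hits <- hits[!is.na(subjFog), , drop = FALSE]
  if (!nrow(hits))
    return(list(hog_id = NA_character_, subject_id = NA_character_,
                unplaceable = TRUE))
  ord <- order(-hits$bit_score, hits$evalue, hits$subject_id)
  best <- hits[ord[1L], ]
  list(hog_id = unname(hog[fog[best$subject_id]]),
       subject_id = best$subject_id, unplaceable = FALSE)
}

#' Accept or reject a phylogenetic placement
#'
#' The FOG with the largest likelihood weight ratio is accepted iff its LWR
#' reaches the threshold (default 0.5, a strict majority of placement
#' mass).  Placements pointing outside the assigned HOG are an error:
#' the placement search is run within the HOG's reference alignment.
#'
#' @param placements data.frame of placement records for one candidate
#'   (columns of [readPlacements()]).
#' @param hogId the HOG the candidate was assigned by best hit.
#' @param catalog an [OrthologCatalog-class].
#' @param lwrThreshold acceptance threshold in `[0, 1]`.
#' @return list with `fog_id` (`NA` on rejection), `lwr` of the best
#'   placement, and `accepted` (logical).
#' @export
acceptPlacement <- function(placements, hogId, catalog, lwrThreshold = 0.5) {
  hog <- hogOf(catalog)
  outside <- placements$fog_id[is.na(hog[placements$fog_id]) |
                                 hog[placements$fog_id] != hogId]
  if (length(outside))
    stop("placement references FOG outside the assigned HOG: ", outside[1L])
  if (!nrow(placements))
    return(list(fog_id = NA_character_, lwr = NA_real_, accepted = FALSE))
  best <- placements[order(-placements$lwr, placements$fog_id)[1L], ]
  if (best$lwr >= lwrThreshold)
    list(fog_id = best$fog_id, lwr = best$lwr, accepted = TRUE)
  else
    list(fog_id = NA_character_, lwr = best$lwr, accepted = FALSE)
}

#' Rescue additional proteins into a catalog
#'
#' Runs the full admission chain for each candidate, in candidate-id order
#' for determinism: pre-filter hits at the configured expect-value ceiling,
#' assign a HOG by best hit, pick the best placement among the HOG's FOGs,
#' apply the relative-length filter against the placed FOG's mean member
#' length, and accept when the likelihood weight ratio reaches the
#' threshold.  Rescued proteins are added with
#' `annotation_source = "rescue"` and their FOG is flagged
#' `electronically_modified`; pre-existing proteins are never removed or
#' reassigned.
#'
#' @param catalog an [OrthologCatalog-class].
#' @param candidates data.frame with `candidate_id`, `species_code`,
#'   `length`, `source` (`misidentified`/`unidentified`).
#' @param hits data.frame of hit records (queries are candidates).
#' @param placements data.frame of placement records.
#' @param evalueMax expect-value pre-filter on hits (default 1e-20).
#' @param lengthFraction relative-length filter (default 0.75).
#' @param lwrThreshold placement acceptance threshold (default 0.5).
#' @return list with `catalog` and `log` (one row per candidate: `decision`
#'   in accepted/rejected_lwr/rejected_length/unplaceable, plus the ids
#'   involved).
#' @export
rescueProteins <- function(catalog, candidates, hits, placements,
                           evalueMax = 1e-20, lengthFraction = 0.75,
                           lwrThreshold = 0.5) {
  candidates <- candidates[order(candidates$candidate_id), , drop = FALSE]
  hits <- hits[hits$evalue <= evalueMax, , drop = FALSE]
  logs <- list()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    entry <- data.frame(candidate_id = cand$candidate_id,
                        hog_id = NA_character_, fog_id = NA_character_,
                        lwr = NA_real_, decision = NA_character_,
                        stringsAsFactors = FALSE)
    ch <- hits[hits$query_id == cand$candidate_id, , drop = FALSE]
    best <- assignHogByBestHit(ch, catalog)
    if (best$unplaceable) {
      entry$decision <- "unplaceable"
      logs[[i]] <- entry; next
    }
    entry$hog_id <- best$hog_id
    cp <- placements[placements$candidate_id == cand$candidate_id, ,
                     drop = FALSE]
    placed <- acceptPlacement(cp, best$hog_id, catalog, lwrThreshold)
    entry$lwr <- placed$lwr
    if (!placed$accepted) {
      entry$decision <- "rejected_lwr"
      logs[[i]] <- entry; next
    }
    members <- catalog@proteins[!is.na(catalog@proteins$fog_id) &
                                  catalog@proteins$fog_id == placed$fog_id, ]
    meanLen <- mean(members$length)
    lf <- lengthFilter(data.frame(candidate_id = cand$candidate_id,
                                  length = cand$length),
                       meanLen, lengthFraction)
    if (!nrow(lf$kept)) {
      entry$fog_id <- placed$fog_id
      entry$decision <- "rejected_length"
      logs[[i]] <- entry; next
    }
    entry$fog_id <- placed$fog_id
    entry$decision <- "accepted"
    pr <- rbind(catalog@proteins, data.frame(
      protein_id = cand$candidate_id, species_code = cand$species_code,
      length = as.integer(cand$length), sequence = NA_character_,
      annotation_source = "rescue", fog_id = placed$fog_id,
      stringsAsFactors = FALSE))
    fg <- catalog@fogs
    fg$status[fg$fog_id == placed$fog_id] <- "electronically_modified"
    catalog <- OrthologCatalog(pr, fg, catalog@metadata)
    logs[[i]] <- entry
  }
  log <- if (length(logs)) do.call(rbind, logs)
  else data.frame(candidate_id = character(), hog_id = character(),
                  fog_id = character(), lwr = numeric(),
                  decision = character(), stringsAsFactors = FALSE)
  list(catalog = catalog, log = log)
}
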