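## Per-FOG consistency review: localization-prediction outliers and length
## outliers, mirroring the manual curation aids of the web portal.

#' Flag localization-prediction outliers in a group
#'
#' A protein is flagged when the group as a whole is confidently predicted
#' to a compartment (median probability at or above `absCutoff`) yet this
#' protein falls at least `devCutoff` below that median -- the signature of
#' a truncated gene model losing its targeting sequence.  The median, not
#' the mean, is the group reference: it is robust to the very outliers
#' being sought.  Fewer than three scored members is underpowered and
#' yields no flags.
#'
#' @param members character vector of the group's protein ids.
#' @param localization data.frame of [readLocalization()] records.
#' @param predictor predictor name to review.
#' @param fogId group id recorded in the flags.
#' @param absCutoff minimal group median probability (default 0.5).
#' @param devCutoff minimal deviation below the median (default 0.5).
#' @return data.frame of flags: `protein_id`, `fog_id`, `check`,
#'   `observed`, `group_reference`, `note`; zero rows when nothing (or too
#'   little) to flag.
#' @export
localizationOutliers <- function(members, localization, predictor,
                                 fogId = NA_character_,
                                 absCutoff = 0.5, devCutoff = 0.5) {
  sub <- localization[localization$protein_id %in% members &
                        localization$predictor == predictor, , drop = FALSE]
  empty <- data.frame(protein_id = character(), fog_id = character(),
                      check = character(), observed = numeric(),
                      group_reference = numeric(), note = character(),
                      stringsAsFactors = FALSE)
  if (nrow(sub) < 3L) {
    attr(empty, "underpowered") <- TRUE
    return(empty)
  }
  med <- stats::median(sub$probability)
  if (med < absCutoff) return(empty)
  hit <- med - sub$probability >= devCutoff
  if (!any(hit)) return(empty)
  data.frame(protein_id = sub$protein_id[hit], fog_id = fogId,
             check = "localization", observed = sub$probability[hit],
             group_reference = med,
             note = paste0(predictor, " probability far below group median;",
                           " possible truncated N-terminus"),
             stringsAsFactors = FALSE)
}

#' Flag length outliers in a group
#'
#' Members shorter than `fraction` of the group mean length (mean over all
#' members) are flagged; the same relative-length rule used to screen
#' rescue candidates, reapplied as a consistency check.
#'
#' @param members data.frame with `protein_id` and `length` (at least two
#'   rows).
#' @param fraction length fraction (default 0.75).
#' @param fogId group id recorded in the flags.
#' @return data.frame of flags (same columns as
#'   [localizationOutliers()]).
#' @export
lengthOutliers <- function(members, fraction = 0.75, fogId = NA_character_) {
  empty <- data.frame(protein_id = character(), fog_id = character(),
                      check = character(), observed = numeric(),
                      group_reference = numeric(), note = character(),
                      stringsAsFactors = FALSE)
  if (nrow(members) < 2L) return(empty)
  m <- mean(members$length)
  hit <- members$length < fraction * m
  if (!any(hit)) return(empty)
  data.frame(protein_id = members$protein_id[hit], fog_id = fogId,
             check = "length", observed = as.numeric(members$length[hit]),
             group_reference = m,
             note = sprintf("length below %d%% of group mean",
                            as.integer(round(100 * fraction))),
             stringsAsFactors = FALSE)
}

#' Run all per-FOG consistency checks over a catalog
#'
#' @param catalog an [OrthologCatalog-class].
#' @param localization optional data.frame of localization records.
#' @param predictor predictor name for the localization check.
#' @param absCutoff,devCutoff,fraction check parameters, see
#'   [localizationOutliers()] and [lengthOutliers()].
#' @return data.frame of flags over all FOGs.
#' @export
catalogQC <- function(catalog, localization = NULL,
                      predictor = "MitoProtII", absCutoff = 0.5,
                      devCutoff = 0.5, fraction = 0.75) {
  pr <- catalog@proteins
  flags <- list()
  for (fog in sort(unique(pr$fog_id[!is.na(pr$fog_id)]))) {
    members <- pr[!is.na(pr$fog_id) & pr$fog_id == fog, , drop = FALSE]
    flags[[length(flags) + 1L]] <-
      lengthOutliers(members, fraction, fogId = fog)
    if (!is.null(localization)) {
      flags[[length(flags) + 1L]] <-
        localizationOutliers(members$protein_id, localization, predictor,
                             fogId = fog, absCutoff = absCutoff,
                             devCutoff = devCutoff)
    }
  }
  if (length(flags)) do.call(rbind, flags)
  else data.frame(protein_id = character(), fog_id = character(),
                  check = character(), observed = numeric(),
                  group_reference = numeric(), note = character(),
                  stringsAsFactors = FALSE)
}
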