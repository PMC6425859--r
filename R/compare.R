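## Stage 4: congruence classification against another ortholog database and
## similarity-score profiling by divergence group.

#' Restrict a comparison to comparable FOGs
#'
#' A FOG is comparable with an external database iff at least one member's
#' species is covered by that database; groups made of species the external
#' database never annotated cannot be judged.
#'
#' @param catalog an [OrthologCatalog-class].
#' @param external an [ExternalLabeling-class].
#' @return character vector of comparable FOG ids.
#' @export
restrictComparable <- function(catalog, external) {
  pr <- catalog@proteins
  assigned <- pr[!is.na(pr$fog_id), , drop = FALSE]
  covered <- assigned$species_code %in% external@speciesCovered
  sort(unique(assigned$fog_id[covered]))
}

#' Classify the congruence of one FOG
#'
#' Restricted to the FOG's proteins from covered species: no labelled
#' member at all gives `none`; two or more distinct external labels among
#' labelled members give under-clustering (the external database scattered
#' the orthologs); an external group that also holds a covered protein from
#' a *different* FOG gives over-clustering (it lumped in paralogs); both at
#' once give `over_and_under`; neither, `congruent`.  Members that are
#' unlabelled while others are labelled are ignored for the verdict but
#' reported as a coverage note.
#'
#' @param fogId the FOG to classify (must be comparable).
#' @param catalog an [OrthologCatalog-class].
#' @param external an [ExternalLabeling-class].
#' @return list with `category`, `n_labeled`, `n_unlabeled`.
#' @export
classifyCongruence <- function(fogId, catalog, external) {
  pr <- catalog@proteins
  members <- pr[!is.na(pr$fog_id) & pr$fog_id == fogId &
                  pr$species_code %in% external@speciesCovered, ,
                drop = FALSE]
  labs <- external@labels[members$protein_id]
  nLabeled <- sum(!is.na(labs))
  nUnlabeled <- nrow(members) - nLabeled
  if (nLabeled == 0L)
    return(list(category = "none", n_labeled = 0L,
                n_unlabeled = nUnlabeled))
  distinct <- unique(labs[!is.na(labs)])
  under <- length(distinct) >= 2L

  covered <- pr[!is.na(pr$fog_id) & pr$species_code %in%
                  external@speciesCovered, , drop = FALSE]
  coveredLabs <- external@labels[covered$protein_id]
  over <- any(!is.na(coveredLabs) & coveredLabs %in% distinct &
                covered$fog_id != fogId)

  category <- if (under && over) "over_and_under"
  else if (under) "under"
  else if (over) "over"
  else "congruent"
  list(category = category, n_labeled = nLabeled, n_unlabeled = nUnlabeled)
}

CONGRUENCE_CATEGORIES <- c("congruent", "over", "under", "over_and_under",
                           "none")

#' Summarise the congruence of two ortholog databases
#'
#' @param catalog an [OrthologCatalog-class].
#' @param external an [ExternalLabeling-class].
#' @return a [CongruenceReport-class]: per-FOG categories over the
#'   comparable FOGs plus category counts and percentages (raw and rounded
#'   to integer).
#' @export
summarizeComparison <- function(catalog, external) {
  comparable <- restrictComparable(catalog, external)
  rows <- lapply(comparable, function(f) {
    cl <- classifyCongruence(f, catalog, external)
    data.frame(fog_id = f, category = cl$category,
               n_labeled = cl$n_labeled, n_unlabeled = cl$n_unlabeled,
               stringsAsFactors = FALSE)
  })
  perFog <- if (length(rows)) do.call(rbind, rows)
  else data.frame(fog_id = character(), category = character(),
                  n_labeled = integer(), n_unlabeled = integer(),
                  stringsAsFactors = FALSE)
  counts <- vapply(CONGRUENCE_CATEGORIES,
                   function(cc) sum(perFog$category == cc), integer(1))
  n <- length(comparable)
  pctRaw <- if (n) 100 * counts / n else rep(0, length(counts))
  summary <- data.frame(category = CONGRUENCE_CATEGORIES,
                        count = unname(counts),
                        pct_raw = unname(pctRaw),
                        pct = as.integer(roundHalfUp(unname(pctRaw))),
                        stringsAsFactors = FALSE)
  new("CongruenceReport", perFog = perFog, summary = summary,
      nComparable = as.integer(n))
}

#' Profile similarity scores of a focal species' orthologs by divergence group
#'
#' Hits from a focal species' proteins to their co-orthologs (same FOG) are
#' bucketed by the subject species' taxonomic group, and quartiles of
#' percent identity, log10 bit score and capped negative log10 expect value
#' are reported per group.  Hit pairs that are not co-orthologous are
#' excluded and counted.
#'
#' @param hits data.frame of hit records ([readHitTable()] columns).
#' @param catalog an [OrthologCatalog-class].
#' @param taxonomy a [SpeciesTaxonomy-class] supplying group labels.
#' @param focalSpecies species code of the query side.
#' @param evalueCap cap for `-log10(0)` expect values (default 400).
#' @return list with `profile` (data.frame: group, metric, n, q25, median,
#'   q75) and `nExcluded`.
#' @export
similarityProfile <- function(hits, catalog, taxonomy, focalSpecies,
                              evalueCap = 400) {
  pr <- catalog@proteins
  fog <- fogOf(catalog)
  species <- stats::setNames(pr$species_code, pr$protein_id)
  qF <- fog[hits$query_id]
  sF <- fog[hits$subject_id]
  co <- !is.na(qF) & !is.na(sF) & qF == sF &
    !is.na(species[hits$query_id]) &
    species[hits$query_id] == focalSpecies
  nExcluded <- sum(!co)
  hits <- hits[co, , drop = FALSE]
  grp <- taxonomy@groupOf[species[hits$subject_id]]
  metrics <- list(pct_identity = hits$pct_identity,
                  log10_bit_score = log10(hits$bit_score),
                  neg_log10_evalue = negLog10Evalue(hits$evalue, evalueCap))
  rows <- list()
  for (g in sort(unique(grp))) {
    sel <- grp == g
    for (m in names(metrics)) {
      v <- metrics[[m]][sel]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, metric = m, n = sum(sel),
        q25 = q[1L], median = q[2L], q75 = q[3L], stringsAsFactors = FALSE)
    }
  }
  profile <- if (length(rows)) do.call(rbind, rows)
  else data.frame(group = character(), metric = character(), n = integer(),
                  q25 = numeric(), median = numeric(), q75 = numeric(),
                  stringsAsFactors = FALSE)
  list(profile = profile, nExcluded = nExcluded)
}
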