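## Tabular readers for parsed similarity hits, phylogenetic placements,
## localization predictions, and FASTA.  All expect a header row naming the
## required columns; numeric fields are range-validated on input.

readCheckedTable <- function(path, required, what) {
  lines <- readInputLines(path)
  if (!length(lines)) stop("empty ", what, " table: ", path)
  tab <- utils::read.delim(text = lines, stringsAsFactors = FALSE,
                           na.strings = "")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop(what, " table is missing required column(s): ",
         paste(missing, collapse = ", "))
  tab
}

#' Read a table of similarity hits
#'
#' Columns follow BLAST tabular conventions: `query_id`, `subject_id`,
#' `pct_identity` (0-100), `bit_score` (> 0), `evalue` (>= 0; exact zeros
#' are stored as zero and only capped downstream when a negative log is
#' taken) and `subject_length` (>= 1).
#'
#' @param path file path (gzip accepted).
#' @return data.frame of hit records.
#' @export
readHitTable <- function(path) {
  tab <- readCheckedTable(path, c("query_id", "subject_id", "pct_identity",
                                  "bit_score", "evalue", "subject_length"),
                          "hit")
  tab$pct_identity <- as.numeric(tab$pct_identity)
  tab$bit_score <- as.numeric(tab$bit_score)
  tab$evalue <- as.numeric(tab$evalue)
  tab$subject_length <- as.integer(tab$subject_length)
  if (any(is.na(tab$pct_identity) | tab$pct_identity < 0 |
            tab$pct_identity > 100))
    stop("pct_identity outside [0, 100] in hit table")
  if (any(is.na(tab$bit_score) | tab$bit_score <= 0))
    stop("bit_score must be positive in hit table")
  if (any(is.na(tab$evalue) | tab$evalue < 0))
    stop("evalue must be non-negative in hit table")
  if (any(is.na(tab$subject_length) | tab$subject_length < 1L))
    stop("subject_length must be >= 1 in hit table")
  tab
}

#' Read a table of phylogenetic placements
#'
#' @param path file path with columns `candidate_id`, `fog_id`, `lwr`
#'   (likelihood weight ratio in `[0, 1]`); at most one row per
#'   (candidate, FOG) pair.
#' @return data.frame of placement records.
#' @export
readPlacements <- function(path) {
  tab <- readCheckedTable(path, c("candidate_id", "fog_id", "lwr"),
                          "placement")
  tab$lwr <- as.numeric(tab$lwr)
  if (any(is.na(tab$lwr) | tab$lwr < 0 | tab$lwr > 1))
    stop("likelihood weight ratio outside [0, 1] in placement table")
  key <- paste(tab$candidate_id, tab$fog_id)
  if (anyDuplicated(key))
    stop("duplicate (candidate, FOG) placement: ", key[duplicated(key)][1L])
  tab
}

#' Read a table of localization predictions
#'
#' @param path file path with columns `protein_id`, `predictor`,
#'   `probability` (in `[0, 1]`).
#' @return data.frame of localization records.
#' @export
readLocalization <- function(path) {
  tab <- readCheckedTable(path, c("protein_id", "predictor", "probability"),
                          "localization")
  tab$probability <- as.numeric(tab$probability)
  if (any(is.na(tab$probability) | tab$probability < 0 | tab$probability > 1))
    stop("localization probability outside [0, 1]")
  tab
}

#' Read protein records from FASTA
#'
#' Sequence lengths are computed from the sequences; species codes are the
#' token before the first underscore of each record name.
#'
#' @param path FASTA file path (gzip accepted).
#' @return data.frame with `protein_id`, `species_code`, `length`,
#'   `sequence`.
#' @export
readFasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  data.frame(protein_id = ids,
             species_code = sub("^([^_]+)_.*$", "\\1", ids),
             length = Biostrings::width(seqs),
             sequence = as.character(seqs),
             stringsAsFactors = FALSE)
}

#' Negative log10 of expect values with a cap
#'
#' BLAST reports an expect value of exactly zero below its floating-point
#' floor; for score profiling these are mapped to a finite cap
#' (conventionally 400, configurable).
#'
#' @param evalue numeric vector of expect values (>= 0).
#' @param cap value substituted for `-log10(0)`.
#' @return numeric vector.
#' @export
negLog10Evalue <- function(evalue, cap = 400) {
  out <- -log10(evalue)
  out[!is.finite(out) | out > cap] <- cap
  out
}
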