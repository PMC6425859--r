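## Fixtures built in code, shared across test files.

toyCatalog <- function() {
  pr <- data.frame(
    protein_id = c("sce_P1", "klc_P2", "spo_P3"),
    species_code = c("sce", "klc", "spo"),
    length = c(100L, 110L, 120L),
    fog_id = c("FOG00001", "FOG00001", "FOG00002"),
    stringsAsFactors = FALSE)
  fg <- data.frame(fog_id = c("FOG00001", "FOG00002"),
                   hog_id = c("HOG00001", "HOG00001"),
                   stringsAsFactors = FALSE)
  OrthologCatalog(pr, fg)
}

## A random valid catalog: nSpecies species, nFogs FOGs grouped into HOGs,
## a fraction of proteins unassigned.
randomCatalog <- function(seed, nSpecies = 5L, nFogs = 8L,
                          maxPerFog = 4L, pUnassigned = 0.15) {
  set.seed(seed)
  species <- sprintf("sp%02d", seq_len(nSpecies))
  fogIds <- sprintf("FOG%05d", seq_len(nFogs))
  hogIdx <- sort(sample.int(max(1L, nFogs %/% 2L), nFogs, replace = TRUE))
  hogIds <- sprintf("HOG%05d", hogIdx)
  parent <- rep(NA_character_, nFogs)
  for (i in seq_len(nFogs)) {
    sib <- which(hogIds == hogIds[i])
    sib <- sib[sib < i]
    if (length(sib) && runif(1) < 0.4) parent[i] <- fogIds[max(sib)]
  }
  rows <- list()
  k <- 0L
  for (i in seq_len(nFogs)) {
    n <- sample.int(maxPerFog, 1L)
    for (j in seq_len(n)) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        protein_id = sprintf("%s_Q%04d", sample(species, 1L), k),
        species_code = NA_character_, length = sample(80:500, 1L),
        fog_id = fogIds[i], stringsAsFactors = FALSE)
    }
  }
  for (j in seq_len(3L)) {
    k <- k + 1L
    rows[[k]] <- data.frame(
      protein_id = sprintf("%s_Q%04d", sample(species, 1L), k),
      species_code = NA_character_, length = sample(80:500, 1L),
      fog_id = NA_character_, stringsAsFactors = FALSE)
  }
  pr <- do.call(rbind, rows)
  pr$species_code <- sub("_.*$", "", pr$protein_id)
  drop <- runif(nrow(pr)) < pUnassigned
  pr$fog_id[drop] <- NA_character_
  keep <- unique(pr$fog_id[!is.na(pr$fog_id)])
  fg <- data.frame(fog_id = fogIds, hog_id = hogIds, parent_fog = parent,
                   status = sample(c("predicted", "electronically_modified",
                                     "manually_curated"), nFogs,
                                   replace = TRUE),
                   stringsAsFactors = FALSE)
  fg <- fg[fg$fog_id %in% keep, , drop = FALSE]
  fg$parent_fog[!fg$parent_fog %in% fg$fog_id] <- NA_character_
  pr$fog_id[!pr$fog_id %in% fg$fog_id] <- NA_character_
  OrthologCatalog(pr, fg)
}

## Hexokinase-style over-clustering fixture: an ancestral gene duplicated in
## Pichiaceae (paralog in kph and opa), the ancestral copy lost in opa but
## kept in kph and in the outer species; OrthoMCL-style input lumps both
## copies into one FOG.
hxkFixture <- function(support = 79L) {
  ## the duplication node is the root (its children share kph); `support`
  ## is the root's bootstrap value
  nwk <- sprintf(paste0("((kph_H2:1,(dha_H2:1,(sce_H2:1,kla_H2:1)88:1)90:1)",
                        "92:1,(kph_H3:1,opa_H3:1)85:1)%d;"), support)
  gt <- readGeneTree(nwk)
  gt@rooted <- TRUE
  pr <- data.frame(
    protein_id = c("kph_H2", "dha_H2", "sce_H2", "kla_H2", "kph_H3",
                   "opa_H3"),
    species_code = c("kph", "dha", "sce", "kla", "kph", "opa"),
    length = 480L, fog_id = "FOG00001", stringsAsFactors = FALSE)
  fg <- data.frame(fog_id = "FOG00001", hog_id = "HOG00001",
                   stringsAsFactors = FALSE)
  list(tree = gt, catalog = OrthologCatalog(pr, fg),
       hxk2 = c("kph_H2", "dha_H2", "sce_H2", "kla_H2"),
       hxk3 = c("kph_H3", "opa_H3"))
}

## Flo8-style under-clustering fixture: one HOG, four FOGs, every species
## contributing exactly one protein.
flo8Fixture <- function() {
  species <- c("sce", "kla", "dha", "kph", "opa", "spo", "yli", "lst")
  pr <- data.frame(
    protein_id = paste0(species, "_F1"), species_code = species,
    length = 700L,
    fog_id = rep(sprintf("FOG%05d", 1:4), each = 2L),
    stringsAsFactors = FALSE)
  fg <- data.frame(fog_id = sprintf("FOG%05d", 1:4), hog_id = "HOG00001",
                   stringsAsFactors = FALSE)
  OrthologCatalog(pr, fg)
}

## Brute-force oracle for the under-clustering merge rule: merge iff >= 2
## FOGs and no species occurs twice among the HOG's proteins.
mergeOracle <- function(speciesByFog) {
  if (length(speciesByFog) < 2L) return(FALSE)
  all(table(unlist(speciesByFog)) < 2L)
}

## All set partitions of 1..n, each as a list of index vectors.
partitionsOfN <- function(n) {
  if (n == 1L) return(list(list(1L)))
  out <- list()
  for (p in partitionsOfN(n - 1L)) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(q[[i]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}
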