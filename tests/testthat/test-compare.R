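cmpCatalog <- function() {
  pr <- data.frame(
    protein_id = c("sce_1", "kla_1", "sce_2", "opa_1", "opa_2"),
    species_code = c("sce", "kla", "sce", "opa", "opa"),
    length = 100L,
    fog_id = c("FOG00001", "FOG00001", "FOG00002", "FOG00002", "FOG00003"),
    stringsAsFactors = FALSE)
  fg <- data.frame(fog_id = sprintf("FOG%05d", 1:3),
                   hog_id = sprintf("HOG%05d", 1:3),
                   stringsAsFactors = FALSE)
  OrthologCatalog(pr, fg)
}

selfLabeling <- function(catalog) {
  externalLabeling(fogOf(catalog),
                   unique(catalog@proteins$species_code))
}

test_that("comparability requires a covered species", {
  cat0 <- cmpCatalog()
  ext <- externalLabeling(c(sce_1 = "X1"), speciesCovered = c("sce", "kla"))
  cmp <- restrictComparable(cat0, ext)
  expect_setequal(cmp, c("FOG00001", "FOG00002")) # FOG00003 is opa-only
  expect_length(restrictComparable(cat0, externalLabeling(
    character(), character())), 0L)
})

test_that("self-comparison is congruent for every FOG", {
  for (seed in c(2, 3)) {
    cat0 <- randomCatalog(seed)
    rep <- summarizeComparison(cat0, selfLabeling(cat0))
    expect_identical(rep@summary$pct[rep@summary$category == "congruent"],
                     100L)
    expect_identical(sum(rep@summary$count), rep@nComparable)
  }
})

test_that("by-hand set comparisons classify over and under", {
  pr <- data.frame(protein_id = c("sce_1", "kla_1", "opa_1"),
                   species_code = c("sce", "kla", "opa"), length = 100L,
                   fog_id = c("FOG00001", "FOG00001", "FOG00002"),
                   stringsAsFactors = FALSE)
  fg <- data.frame(fog_id = c("FOG00001", "FOG00002"),
                   hog_id = c("HOG00001", "HOG00001"))
  cat0 <- OrthologCatalog(pr, fg)
  sp <- c("sce", "kla", "opa")

  ## one external group spanning both FOGs -> both over
  lumped <- externalLabeling(c(sce_1 = "E", kla_1 = "E", opa_1 = "E"), sp)
  expect_identical(classifyCongruence("FOG00001", cat0, lumped)$category,
                   "over")
  expect_identical(classifyCongruence("FOG00002", cat0, lumped)$category,
                   "over")

  ## external scatters FOG00001 across two groups -> under
  scattered <- externalLabeling(c(sce_1 = "E1", kla_1 = "E2", opa_1 = "E3"),
                                sp)
  expect_identical(classifyCongruence("FOG00001", cat0, scattered)$category,
                   "under")

  ## unlabeled FOG -> none, with the coverage note
  partial <- externalLabeling(c(sce_1 = "E1", kla_1 = "E1"), sp)
  cl <- classifyCongruence("FOG00002", cat0, partial)
  expect_identical(cl$category, "none")
  expect_identical(cl$n_unlabeled, 1L)

  ## both pathologies at once
  both <- externalLabeling(c(sce_1 = "E1", kla_1 = "E2", opa_1 = "E1"), sp)
  expect_identical(classifyCongruence("FOG00001", cat0, both)$category,
                   "over_and_under")
})

test_that("category counts partition the comparable FOGs", {
  for (seed in 4:6) {
    cat0 <- randomCatalog(seed)
    set.seed(seed)
    ids <- cat0@proteins$protein_id
    labs <- setNames(sample(c(NA, "E1", "E2", "E3"), length(ids), TRUE), ids)
    ext <- externalLabeling(labs, unique(cat0@proteins$species_code))
    rep <- summarizeComparison(cat0, ext)
    expect_identical(sum(rep@summary$count), rep@nComparable)
    expect_identical(nrow(rep@perFog), rep@nComparable)
  }
})

test_that("splitting an external group can only push FOGs toward under", {
  for (seed in 7:9) {
    cat0 <- randomCatalog(seed, nFogs = 10L)
    ext <- selfLabeling(cat0)
    base <- summarizeComparison(cat0, ext)
    labs <- ext@labels
    ## split the largest external group in two
    big <- names(sort(table(labs), decreasing = TRUE))[1]
    members <- names(labs)[labs == big]
    labs[members[seq_len(ceiling(length(members) / 2))]] <-
      paste0(big, "-bis")
    split <- summarizeComparison(
      cat0, externalLabeling(labs, ext@speciesCovered))
    under <- function(r)
      sum(r@summary$count[r@summary$category %in% c("under",
                                                    "over_and_under")])
    expect_gte(under(split), under(base))
  }
})

test_that("similarity profiles bucket by group with hand-checked quartiles", {
  pr <- data.frame(
    protein_id = c("sce_1", "rgr_1", "rgr_2", "kla_1"),
    species_code = c("sce", "rgr", "rgr", "kla"), length = 100L,
    fog_id = "FOG00001", stringsAsFactors = FALSE)
  fg <- data.frame(fog_id = "FOG00001", hog_id = "HOG00001")
  cat0 <- OrthologCatalog(pr, fg)
  tax <- yeastTaxonomy()
  hits <- data.frame(
    query_id = "sce_1",
    subject_id = c("rgr_1", "rgr_2", "kla_1", "zzz_9"),
    pct_identity = c(35, 45, 58, 99), bit_score = c(150, 200, 400, 500),
    evalue = c(1e-30, 1e-40, 0, 1e-99), subject_length = 100L)
  prof <- similarityProfile(hits, cat0, tax, "sce")
  expect_identical(prof$nExcluded, 1L) # zzz_9 is not a co-ortholog
  outg <- prof$profile[prof$profile$group == "Saccharomycotina outgroup" &
                         prof$profile$metric == "pct_identity", ]
  expect_equal(outg$median, 40) # hand: median of {35, 45}
  sacc <- prof$profile[prof$profile$group == "Saccharomycetaceae", ]
  expect_equal(sacc$median[sacc$metric == "pct_identity"], 58)
  expect_equal(sacc$median[sacc$metric == "neg_log10_evalue"], 400) # capped
})

test_that("deeper divergence groups show lower identity medians", {
  stax <- simulateSpeciesTree(12, seed = 51, nGroups = 4L)
  sim <- simulateFamilies(stax, 30, dupRate = 0, lossRate = 0, seed = 53)
  focal <- leafSpecies(sim$trees[[1]])[1]
  means <- setNames(c(30, 45, 60, 75), sort(unique(stax@groupOf)))
  hits <- simulateHits(sim$catalog, stax, focal, means, noiseSd = 2,
                       seed = 55)
  prof <- similarityProfile(hits, sim$catalog, stax, focal)
  med <- prof$profile[prof$profile$metric == "pct_identity", ]
  med <- med[match(names(means), med$group), ]
  med <- med[!is.na(med$n), ]
  expect_true(all(diff(med$median) > 0))
  ## bit score and evalue order the same way (monotone transforms)
  bits <- prof$profile[prof$profile$metric == "log10_bit_score", ]
  bits <- bits[match(med$group, bits$group), ]
  expect_true(all(diff(bits$median) > 0))
})
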