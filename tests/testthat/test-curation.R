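tax <- yeastTaxonomy()

test_that("outgroup rooting places the outgroup sister to the rest", {
  gt <- readGeneTree("(sce_P1:1,kla_P2:1,rgr_P3:4);")
  cfg <- curationConfig(outgroupSpecies = "rgr")
  rooted <- rootGeneTree(gt, tax, cfg)
  expect_true(rooted@rooted)
  phy <- rooted@tree
  root <- length(phy$tip.label) + 1L
  kids <- phy$edge[phy$edge[, 1] == root, 2]
  tipKids <- phy$tip.label[kids[kids <= length(phy$tip.label)]]
  expect_true("rgr_P3" %in% tipKids)
})

test_that("midpoint rooting matches the brute-force longest-path midpoint", {
  gt <- readGeneTree("((sce_P1:1,kla_P2:2):1,(spo_P3:5,yli_P4:1):1);")
  rooted <- rootGeneTree(gt, tax, curationConfig())
  ## brute force over all tip pairs: the longest path is kla_P2..spo_P3
  ## (2+1+1+5 = 9), so the midpoint sits 4.5 into the spo_P3 branch and the
  ## root must split spo_P3 from the rest
  phy <- rooted@tree
  root <- length(phy$tip.label) + 1L
  kids <- phy$edge[phy$edge[, 1] == root, 2]
  tipKids <- phy$tip.label[kids[kids <= length(phy$tip.label)]]
  expect_identical(tipKids, "spo_P3")
  d <- ape::dist.nodes(phy)
  tipD <- d[root, seq_along(phy$tip.label)]
  expect_equal(max(tipD), 4.5) # half the tree diameter
})

test_that("trees with fewer than three leaves cannot be rooted", {
  gt <- geneTree(ape::read.tree(text = "(sce_P1:1,kla_P2:1);"))
  expect_error(rootGeneTree(gt, tax), "3 leaves")
})

test_that("species overlap separates speciation from duplication cherries", {
  gt <- readGeneTree("((sce_P1:1,kla_P2:1)90:1,spo_P3:1)99;")
  gt@rooted <- TRUE
  ev <- nodeEvents(inferNodeEvents(gt))
  expect_identical(ev, c("speciation", "speciation"))

  ## same-species cherry: a species-lineage expansion is a duplication
  gt2 <- readGeneTree("((sce_P1:1,sce_P2:1)90:1,spo_P3:1)99;")
  gt2@rooted <- TRUE
  ev2 <- nodeEvents(inferNodeEvents(gt2))
  expect_identical(ev2[2], "duplication")

  ## below the support threshold a duplication is only 'unresolved'
  gt3 <- readGeneTree("((sce_P1:1,sce_P2:1)45:1,spo_P3:1)99;")
  gt3@rooted <- TRUE
  expect_identical(nodeEvents(inferNodeEvents(gt3))[2], "unresolved")
})

test_that("inferred events equal simulated truth on loss-free families", {
  stax <- simulateSpeciesTree(10, seed = 3)
  sim <- simulateFamilies(stax, 60, dupRate = 0.1, lossRate = 0, seed = 7)
  for (h in names(sim$truths)) {
    gt <- inferNodeEvents(sim$trees[[h]], curationConfig(70))
    expect_identical(nodeEvents(gt), sim$truths[[h]]@geneTree@event,
                     label = paste("events of", h))
  }
})

test_that("delineation of the ACS-like tree makes the deep clade the parent", {
  ## duplication at the root: one child spans all species incl. the basal
  ## outgroup (ancestral copy), the other only the derived lineages
  nwk <- paste0("((rgr_A1:1,((spo_A1:1,lst_A1:1)90:1,(sce_A1:1,kla_A1:1)",
                "95:1)92:1)88:1,(sce_A2:1,(kla_A2:1,lst_A2:1)80:1)79:1)85;")
  gt <- readGeneTree(nwk)
  gt@rooted <- TRUE
  part <- delineateOrthologGroups(gt, tax)
  m <- part$membership
  expect_length(unique(m), 2L)
  deep <- unique(m[c("rgr_A1", "spo_A1", "sce_A1")])
  derived <- unique(m[c("sce_A2", "kla_A2", "lst_A2")])
  expect_length(deep, 1L)
  expect_length(derived, 1L)
  expect_identical(unname(part$parent[derived]), unname(deep))
  expect_true(is.na(part$parent[deep]))
})

test_that("a duplication-free tree delineates to a single top-level group", {
  gt <- readGeneTree("((sce_P1:1,kla_P2:1)90:1,(spo_P3:1,yli_P4:1)85:1)99;")
  gt@rooted <- TRUE
  part <- delineateOrthologGroups(gt, tax)
  expect_length(unique(part$membership), 1L)
  expect_true(all(is.na(part$parent)))
})

test_that("delineation recovers the simulated true partition", {
  stax <- simulateSpeciesTree(8, seed = 11)
  sim <- simulateFamilies(stax, 40, dupRate = 0.15, lossRate = 0, seed = 13)
  for (h in names(sim$truths)) {
    part <- delineateOrthologGroups(sim$trees[[h]], stax,
                                    curationConfig(supportThreshold = 0))
    truth <- sim$truths[[h]]@partition
    expect_identical(part$membership[names(truth)], truth,
                     label = paste("partition of", h))
  }
})

test_that("same-species expansions stay inside one ortholog group", {
  ## two sce in-paralogs under a speciation backbone are not split apart
  gt <- readGeneTree("(((sce_P1:1,sce_P2:1)99:1,kla_P3:1)95:1,spo_P4:1)99;")
  gt@rooted <- TRUE
  part <- delineateOrthologGroups(gt, tax)
  expect_length(unique(part$membership), 1L)
})

test_that("the merged hexokinase-style FOG is split with correct parentage", {
  fx <- hxkFixture(support = 79L)
  gt <- inferNodeEvents(fx$tree, curationConfig(70))
  prop <- detectOverclustering(fogOf(fx$catalog) |> names(), gt, tax,
                               curationConfig(70))
  expect_false(is.null(prop))
  expect_length(prop$groups, 2L)
  got <- lapply(prop$groups, sort)
  expect_true(any(vapply(got, identical, logical(1), sort(fx$hxk2))))
  expect_true(any(vapply(got, identical, logical(1), sort(fx$hxk3))))
  ## parentage: the ancestral (deep) copy is the parent group
  g2 <- names(prop$groups)[vapply(got, identical, logical(1), sort(fx$hxk2))]
  g3 <- names(prop$groups)[vapply(got, identical, logical(1), sort(fx$hxk3))]
  expect_identical(unname(prop$parent[g3]), g2)
})

test_that("no proposal without a supported duplication in the spanning clade", {
  gt <- readGeneTree("((sce_P1:1,kla_P2:1)90:1,spo_P3:1)99;")
  gt@rooted <- TRUE
  gt <- inferNodeEvents(gt, curationConfig(70))
  expect_null(detectOverclustering(c("sce_P1", "kla_P2", "spo_P3"), gt, tax,
                                   curationConfig(70)))

  ## below-threshold duplication support blocks the split
  fx <- hxkFixture(support = 45L)
  gt2 <- inferNodeEvents(fx$tree, curationConfig(70))
  expect_null(detectOverclustering(names(fogOf(fx$catalog)), gt2, tax,
                                   curationConfig(70)))

  expect_error(detectOverclustering("zzz_P9", gt, tax), "zzz_P9")
})

test_that("raising the support threshold never increases the split count", {
  fx <- hxkFixture(support = 79L)
  nGroups <- integer()
  for (thr in seq(0L, 100L, by = 5L)) {
    cfg <- curationConfig(supportThreshold = thr)
    gt <- inferNodeEvents(fx$tree, cfg)
    prop <- detectOverclustering(names(fogOf(fx$catalog)), gt, tax, cfg)
    nGroups <- c(nGroups, if (is.null(prop)) 1L else length(prop$groups))
  }
  expect_true(all(diff(nGroups) <= 0L))
  expect_identical(nGroups[1], 2L)  # threshold 0: split fires
  expect_identical(nGroups[length(nGroups)], 1L) # threshold 100: no split
  ## the documented default admits the 79-supported duplication
  expect_identical(nGroups[seq(0, 100, 5) == 70], 2L)
})

test_that("the copy-count merge rule follows the no-duplication condition", {
  ## Flo8-like: four FOGs, one HOG, every species once -> one FOG
  cat0 <- flo8Fixture()
  res <- mergeUnderclustered(cat0, "HOG00001")
  expect_true(res$merged)
  expect_identical(nFogs(res$catalog), 1L)
  expect_identical(unname(statusOf(res$catalog)), "electronically_modified")
  expect_setequal(names(fogOf(res$catalog)), names(fogOf(cat0)))

  ## single FOG -> untouched
  single <- toyCatalog()
  single@proteins$fog_id <- "FOG00001"
  single@fogs <- single@fogs[1, ]
  expect_false(mergeUnderclustered(single, "HOG00001")$merged)

  ## one species twice anywhere in the HOG blocks the merge
  dup <- flo8Fixture()
  dup@proteins$species_code[2] <- "sce"
  expect_false(mergeUnderclustered(dup, "HOG00001")$merged)
})

test_that("merge rule agrees with a brute-force oracle on all small configurations", {
  ## exhaustive: 2..5 proteins over <= 4 FOGs x all species assignments
  species <- c("aaa", "bbb", "ccc")
  for (n in 2:5) {
    partitions <- partitionsOfN(n)
    spGrid <- expand.grid(rep(list(species), n), stringsAsFactors = FALSE)
    ## subsample the species grid for n > 4 to keep the sweep quick
    rows <- if (nrow(spGrid) > 81) seq(1, nrow(spGrid), by = 3) else
      seq_len(nrow(spGrid))
    for (p in partitions) {
      if (length(p) > 4L) next
      for (r in rows) {
        sp <- unlist(spGrid[r, ])
        fogIds <- sprintf("FOG%05d", seq_along(p))
        assign <- character(n)
        for (i in seq_along(p)) assign[p[[i]]] <- fogIds[i]
        pr <- data.frame(protein_id = sprintf("%s_x%d", sp, seq_len(n)),
                         species_code = sp, length = 100L, fog_id = assign,
                         stringsAsFactors = FALSE)
        if (anyDuplicated(pr$protein_id)) next
        fg <- data.frame(fog_id = fogIds, hog_id = "HOG00001",
                         stringsAsFactors = FALSE)
        cat0 <- OrthologCatalog(pr, fg)
        expected <- mergeOracle(split(sp, assign))
        got <- mergeUnderclustered(cat0, "HOG00001")$merged
        expect_identical(got, expected,
                         label = sprintf("n=%d partition=%s species=%s", n,
                                         paste(assign, collapse = "/"),
                                         paste(sp, collapse = "/")))
      }
    }
  }
})

test_that("curation is a fixed point on the true partition and conserves proteins", {
  stax <- simulateSpeciesTree(9, seed = 21)
  sim <- simulateFamilies(stax, 25, dupRate = 0.12, lossRate = 0, seed = 23)
  res <- curateCatalog(sim$catalog, sim$trees, stax, curationConfig(70))
  expect_identical(sum(res$log$op %in% c("merge", "split")), 0L)
  expect_true(catalogIdentical(res$catalog, sim$catalog))
})

test_that("curation repairs perturbations, is idempotent, conserves proteins", {
  stax <- simulateSpeciesTree(10, seed = 31)
  sim <- simulateFamilies(stax, 40, dupRate = 0.1, lossRate = 0, seed = 33)
  pert <- perturbCatalog(sim$catalog, sim$truths, pSplit = 0.25,
                         pMerge = 0.25, pUnassign = 0, seed = 35)
  res <- curateCatalog(pert$catalog, sim$trees, stax, curationConfig(70))
  f0 <- fogOf(sim$catalog)
  f1 <- fogOf(res$catalog)[names(f0)]
  ## same partition up to group relabeling
  expect_identical(unname(tapply(names(f1), f1, function(x) paste(sort(x), collapse = ","))) |> sort(),
                   unname(tapply(names(f0), f0, function(x) paste(sort(x), collapse = ","))) |> sort())
  ## conservation: assigned multiset unchanged
  expect_identical(sort(names(f1)[!is.na(f1)]), sort(names(f0)[!is.na(f0)]))
  ## idempotence
  res2 <- curateCatalog(res$catalog, sim$trees, stax, curationConfig(70))
  expect_true(catalogIdentical(res2$catalog, res$catalog))
  expect_identical(sum(res2$log$op %in% c("merge", "split")), 0L)
})

test_that("HOGs without a tree are skipped and logged", {
  cat0 <- flo8Fixture()
  res <- curateCatalog(cat0, list(), tax, curationConfig(70))
  expect_true("skipped" %in% res$log$op)
  ## the copy-count merge still applies without a tree
  expect_identical(nFogs(res$catalog), 1L)
})

test_that("delineation never mixes species except in lineage expansions", {
  stax <- simulateSpeciesTree(8, seed = 41)
  sim <- simulateFamilies(stax, 40, dupRate = 0.2, lossRate = 0.05, seed = 43)
  for (h in names(sim$truths)) {
    gt <- sim$trees[[h]]
    part <- delineateOrthologGroups(gt, stax, curationConfig(0))
    phy <- gt@tree
    sp <- setNames(leafSpecies(gt), phy$tip.label)
    for (g in unique(part$membership)) {
      memb <- names(part$membership)[part$membership == g]
      dups <- table(sp[memb])
      dups <- names(dups)[dups >= 2]
      for (s in dups) {
        ## duplicated species within a group must form a same-species clade
        tips <- match(memb[sp[memb] == s], phy$tip.label)
        mrca <- ape::getMRCA(phy, tips)
        below <- phangorn::Descendants(phy, mrca, "tips")[[1]]
        expect_true(all(sp[phy$tip.label[below]] == s),
                    label = paste(h, g, s))
      }
    }
  }
})
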