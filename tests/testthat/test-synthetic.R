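test_that("species-tree simulation is deterministic with labelled groups", {
  t1 <- simulateSpeciesTree(3, seed = 1)
  t2 <- simulateSpeciesTree(3, seed = 1)
  expect_identical(ape::write.tree(speciesTree(t1)),
                   ape::write.tree(speciesTree(t2)))
  t10 <- simulateSpeciesTree(10, seed = 2)
  expect_length(speciesTree(t10)$tip.label, 10L)
  expect_identical(speciesTree(t10)$Nnode, 9L)
  expect_true(all(sort(unique(names(groupOf(t10)))) ==
                    sort(speciesTree(t10)$tip.label)))
  expect_error(simulateSpeciesTree(2), "at least 3")
})

test_that("the fixed yeast taxonomy has 33 species in six groups", {
  tax <- yeastTaxonomy()
  expect_length(speciesTree(tax)$tip.label, 33L)
  grp <- groupOf(tax)
  expect_length(grp, 33L)
  expect_length(unique(grp), 6L)
  expect_identical(sum(grp == "Pichiaceae"), 8L)
  expect_identical(sum(grp == "CTG clade"), 6L)
  expect_identical(unname(grp["sce"]), "Saccharomycetaceae")
  expect_identical(unname(tax@divergenceBand["Saccharomycotina outgroup"]),
                   "400-600")
})

test_that("a rate-free family is congruent with the species tree", {
  tax <- simulateSpeciesTree(7, seed = 5)
  truth <- simulateGeneFamily(tax, dupRate = 0, lossRate = 0, seed = 6)
  gt <- truth@geneTree
  expect_length(gt@tree$tip.label, 7L)
  expect_true(all(gt@event == "speciation"))
  expect_length(unique(truth@partition), 1L)
  expect_identical(truth@dupCount, 0L)
  expect_identical(truth@lossCount, 0L)
  ## topology matches the species tree
  sp <- leafSpecies(gt)
  phy <- gt@tree
  phy$tip.label <- sp
  expect_identical(phangorn::RF.dist(phy, speciesTree(tax)), 0L)
})

test_that("seeded family simulation is reproducible", {
  tax <- simulateSpeciesTree(8, seed = 7)
  a <- simulateGeneFamily(tax, 0.2, 0.1, seed = 8)
  b <- simulateGeneFamily(tax, 0.2, 0.1, seed = 8)
  expect_identical(writeGeneTree(a@geneTree), writeGeneTree(b@geneTree))
  expect_identical(a@partition, b@partition)
  expect_identical(a@dupCount, b@dupCount)
})

test_that("duplication counts match the branching-process expectation", {
  ## closed form for a pure-birth process seeded with one copy at the root:
  ## E[copies entering a branch] = prod(exp(lambda * t_anc)); births on a
  ## branch of length t with n_in entrants have mean n_in * (exp(lambda*t)-1)
  tax <- simulateSpeciesTree(6, seed = 9)
  phy <- speciesTree(tax)
  lambda <- 0.1
  ntip <- length(phy$tip.label)
  nIn <- numeric(ntip + phy$Nnode)
  nIn[ntip + 1L] <- 1
  expected <- 0
  for (i in order(phy$edge[, 1])) {
    par <- phy$edge[i, 1]; ch <- phy$edge[i, 2]; t <- phy$edge.length[i]
    expected <- expected + nIn[par] * (exp(lambda * t) - 1)
    nIn[ch] <- nIn[par] * exp(lambda * t)
  }
  sims <- vapply(seq_len(500), function(i)
    simulateGeneFamily(tax, lambda, 0, seed = 20000 + i)@dupCount,
    integer(1))
  se <- sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - expected), 3 * se + 1e-9)
})

test_that("perturbation at zero probabilities is the identity", {
  tax <- simulateSpeciesTree(8, seed = 11)
  sim <- simulateFamilies(tax, 10, dupRate = 0.1, lossRate = 0, seed = 12)
  pert <- perturbCatalog(sim$catalog, sim$truths, 0, 0, 0, seed = 13)
  expect_true(catalogIdentical(pert$catalog, sim$catalog))
  expect_identical(nrow(pert$log), 0L)
})

test_that("forced splits double the FOG count of a two-FOG HOG", {
  tax <- simulateSpeciesTree(8, seed = 15)
  sim <- simulateFamilies(tax, 30, dupRate = 0.15, lossRate = 0, seed = 16)
  twoFog <- names(Filter(function(h) {
    fogs <- fogTable(sim$catalog)
    sum(fogs$hog_id == h) == 2L
  }, setNames(nm = unique(fogTable(sim$catalog)$hog_id))))
  ## splittable = >= 2 members; count expected fragments per truth
  pert <- perturbCatalog(sim$catalog, sim$truths, pSplit = 1, pMerge = 0,
                         pUnassign = 0, seed = 17)
  h <- twoFog[1]
  fogsBefore <- fogTable(sim$catalog)
  fogsAfter <- fogTable(pert$catalog)
  before <- fogsBefore$fog_id[fogsBefore$hog_id == h]
  sizes <- table(fogOf(sim$catalog))[before]
  expectedAfter <- sum(ifelse(sizes >= 2L, 2L, 1L))
  expect_identical(sum(fogsAfter$hog_id == h), as.integer(expectedAfter))
})

test_that("replaying the perturbation log reproduces the perturbed catalog", {
  tax <- simulateSpeciesTree(9, seed = 18)
  sim <- simulateFamilies(tax, 25, dupRate = 0.12, lossRate = 0.02,
                          seed = 19)
  pert <- perturbCatalog(sim$catalog, sim$truths, 0.3, 0.3, 0.1, seed = 20)
  replayed <- replayPerturbations(sim$catalog, pert$log)
  expect_true(catalogIdentical(replayed, pert$catalog))
})

test_that("noise-free hits sit exactly on their group means", {
  tax <- simulateSpeciesTree(8, seed = 21, nGroups = 2L)
  sim <- simulateFamilies(tax, 10, dupRate = 0, lossRate = 0, seed = 22)
  focal <- leafSpecies(sim$trees[[1]])[1]
  means <- setNames(c(40, 58), sort(unique(groupOf(tax))))
  hits <- simulateHits(sim$catalog, tax, focal, means, noiseSd = 0,
                       seed = 23)
  grp <- groupOf(tax)[sub("_.*$", "", hits$subject_id)]
  expect_true(all(hits$pct_identity == means[grp]))
  ## seeded determinism with noise
  h1 <- simulateHits(sim$catalog, tax, focal, means, noiseSd = 3, seed = 24)
  h2 <- simulateHits(sim$catalog, tax, focal, means, noiseSd = 3, seed = 24)
  expect_identical(h1, h2)
})

test_that("support degradation can only lower supports", {
  tax <- simulateSpeciesTree(8, seed = 25)
  truth <- simulateGeneFamily(tax, 0.2, 0, seed = 26)
  deg <- degradeSupport(truth@geneTree, seed = 27)
  expect_true(all(deg@support <= truth@geneTree@support))
  expect_true(all(deg@support >= 0L))
})
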