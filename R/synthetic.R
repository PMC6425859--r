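## Ground-truth generator: gene families simulated on a species tree with
## birth-death duplications/losses, plus catalog perturbation with a
## replayable log, and synthetic similarity hits.  Every pipeline stage is
## testable against these truths without any external data.

#' Simulate a species tree with taxonomic groups
#'
#' A pure-birth (Yule) tree with `nSpecies` tips, deterministic under
#' `seed`.  Group labels are assigned by clade: the largest clade is split
#' until `nGroups` clades exist, each becoming one group.
#'
#' @param nSpecies integer >= 3.
#' @param seed integer seed.
#' @param nGroups number of taxonomic groups (capped at `nSpecies`).
#' @return a [SpeciesTaxonomy-class].
#' @export
simulateSpeciesTree <- function(nSpecies, seed = 1L, nGroups = 3L) {
  if (nSpecies < 3L) stop("need at least 3 species")
  set.seed(seed)
  phy <- ape::rphylo(nSpecies, birth = 1, death = 0)
  phy$tip.label <- sprintf("s%02d", seq_len(nSpecies))
  nGroups <- min(nGroups, nSpecies)
  ntip <- nSpecies
  children <- treeChildren(phy)
  tipsOf <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(children[[node]], tipsOf))
  }
  clades <- as.list(children[[ntip + 1L]])
  while (length(clades) < nGroups) {
    sizes <- vapply(clades, function(nd) length(tipsOf(nd[[1L]])), integer(1))
    big <- which.max(sizes)
    nd <- clades[[big]][[1L]]
    if (nd <= ntip) break
    clades <- c(clades[-big], as.list(children[[nd]]))
  }
  groupOf <- character(ntip)
  for (i in seq_along(clades))
    groupOf[vapply(tipsOf(clades[[i]][[1L]]), identity, integer(1))] <-
      sprintf("grp%d", i)
  names(groupOf) <- phy$tip.label
  speciesTaxonomy(phy, groupOf)
}

#' The 33-species yeast/fungus taxonomy fixture
#'
#' A fixed species tree over 33 fungal and yeast species (three-letter
#' codes), partitioned into the six taxonomic groups used for
#' divergence-banded analyses: the Saccharomycotina outgroup, basal
#' Saccharomycotina, Pichiaceae, the CTG clade, Phaffomycetaceae &
#' Saccharomycodaceae, and Saccharomycetaceae.  Branch lengths are in
#' units of 100 million years and encode the approximate divergence bands
#' with *S. cerevisiae* (0-100 My within Saccharomycetaceae out to 400-600
#' My for the outgroup).
#'
#' @return a [SpeciesTaxonomy-class].
#' @export
yeastTaxonomy <- function() {
  sacch <- "(kla:1.0,(lth:0.9,(zro:0.8,(vpo:0.6,sce:0.6):0.2):0.1):0.1)"
  phaff <- "(hva:1.1,(wan:0.9,cja:0.9):0.2)"
  ctg <- paste0("(bin:1.4,(mbi:1.2,((mgu:1.0,dha:1.0):0.1,",
                "(sst:0.9,spa:0.9):0.2):0.1):0.2)")
  pich <- paste0("(pta:1.5,((kph:0.8,kca:0.8):0.4,((oar:0.5,opa:0.5):0.3,",
                 "(dbr:0.6,(pme:0.3,pku:0.3):0.3):0.2):0.4):0.3)")
  basal <- "(lst:4.0,(yli:3.0,(bad:2.0,(nfu:1.0,aru:1.0):1.0):1.0):1.0)"
  outg <- paste0("(rgr:5.5,((spo:3.0,sco:3.0):1.0,((ani:1.5,tre:1.5):0.5,",
                 "ncr:2.0):2.0):1.5)")
  nwk <- sprintf("(((((%s:0.6,%s:0.4):0.2,%s:0.4):0.2,%s:0.5):2.0,%s:1.5):0.5,%s:0.5);",
                 sacch, phaff, ctg, pich, basal, outg)
  phy <- ape::read.tree(text = nwk)
  groups <- c(
    stats::setNames(rep("Saccharomycetaceae", 5),
                    c("kla", "lth", "zro", "vpo", "sce")),
    stats::setNames(rep("Phaffomycetaceae & Saccharomycodaceae", 3),
                    c("hva", "wan", "cja")),
    stats::setNames(rep("CTG clade", 6),
                    c("bin", "mbi", "mgu", "dha", "sst", "spa")),
    stats::setNames(rep("Pichiaceae", 8),
                    c("pta", "kph", "kca", "oar", "opa", "dbr", "pme", "pku")),
    stats::setNames(rep("basal Saccharomycotina", 5),
                    c("lst", "yli", "bad", "nfu", "aru")),
    stats::setNames(rep("Saccharomycotina outgroup", 6),
                    c("rgr", "spo", "sco", "ani", "tre", "ncr")))
  bands <- c("Saccharomycetaceae" = "0-100",
             "Phaffomycetaceae & Saccharomycodaceae" = "100-200",
             "CTG clade" = "200",
             "Pichiaceae" = "200",
             "basal Saccharomycotina" = "200-400",
             "Saccharomycotina outgroup" = "400-600")
  speciesTaxonomy(phy, groups, bands)
}

#' Simulate one gene family on a species tree
#'
#' One ancestral copy at the species-tree root evolves down every branch
#' under a birth-death process (`dupRate` duplications, `lossRate` losses
#' per copy per unit branch length).  Surviving copies become leaves named
#' `<species>_<familyId>_<copy>`; the true gene tree carries support 100 at
#' every node and the true speciation/duplication label from the process.
#' The true hierarchical ortholog partition is obtained by applying the
#' delineation convention ([delineateOrthologGroups()]) to the true
#' event-labelled tree, which it provably matches on loss-free trees.
#' Families whose copies all die are redrawn up to `maxRetry` times.
#'
#' @param taxonomy a [SpeciesTaxonomy-class].
#' @param dupRate,lossRate non-negative per-copy rates.
#' @param seed integer seed (deterministic output).
#' @param familyId identifier embedded in leaf names.
#' @param maxRetry resampling cap for all-extinct families.
#' @return a [FamilyTruth-class].
#' @export
simulateGeneFamily <- function(taxonomy, dupRate = 0.1, lossRate = 0,
                               seed = 1L, familyId = "fam", maxRetry = 100L) {
  stopifnot(dupRate >= 0, lossRate >= 0)
  set.seed(seed)
  phy <- taxonomy@tree
  if (is.null(phy$edge.length)) phy$edge.length <- rep(1, nrow(phy$edge))
  ntip <- length(phy$tip.label)
  children <- treeChildren(phy)
  elen <- numeric(ntip + phy$Nnode)
  elen[phy$edge[, 2L]] <- phy$edge.length
  rate <- dupRate + lossRate

  for (attempt in seq_len(maxRetry)) {
    nDup <- 0L; nLoss <- 0L

    atNode <- function(spNode) {
      if (spNode <= ntip)
        return(list(type = "leaf", species = phy$tip.label[spNode],
                    length = 0))
      kids <- lapply(children[[spNode]],
                     function(ch) evolveBranch(ch, elen[ch]))
      kids <- kids[!vapply(kids, is.null, logical(1))]
      if (!length(kids)) return(NULL)
      if (length(kids) == 1L) return(kids[[1L]])
      list(type = "spec", children = kids, length = 0)
    }
    evolveBranch <- function(spNode, t) {
      tev <- if (rate > 0) stats::rexp(1L, rate) else Inf
      if (tev < t) {
        if (stats::runif(1L) < dupRate / rate) {
          nDup <<- nDup + 1L
          a <- evolveBranch(spNode, t - tev)
          b <- evolveBranch(spNode, t - tev)
          if (is.null(a) && is.null(b)) return(NULL)
          if (is.null(a)) { b$length <- b$length + tev; return(b) }
          if (is.null(b)) { a$length <- a$length + tev; return(a) }
          return(list(type = "dup", children = list(a, b), length = tev))
        }
        nLoss <<- nLoss + 1L
        return(NULL)
      }
      sub <- atNode(spNode)
      if (is.null(sub)) return(NULL)
      sub$length <- sub$length + t
      sub
    }

    root <- atNode(ntip + 1L)
    if (is.null(root)) next
    if (root$type == "leaf") next # a single survivor is not a tree
    built <- buildGenePhylo(root, familyId)
    gt <- geneTree(built$phy,
                   support = rep(100L, built$phy$Nnode),
                   event = built$event, rooted = TRUE)
    part <- delineateOrthologGroups(gt, taxonomy,
                                    curationConfig(supportThreshold = 0L))
    return(new("FamilyTruth", geneTree = gt,
               partition = part$membership,
               parentGroup = part$parent,
               dupCount = nDup, lossCount = nLoss,
               seed = as.integer(seed)))
  }
  stop("gene family went extinct in every resampling attempt")
}

## Convert the recursive simulator output into a phylo with per-internal-node
## true event labels.  Tips are numbered in traversal order, internal nodes
## in preorder (root first), matching ape conventions.
buildGenePhylo <- function(root, familyId) {
  tips <- list(); internals <- list()
  collect <- function(node) {
    if (node$type == "leaf") {
      tips[[length(tips) + 1L]] <<- node
      return(list(kind = "tip", idx = length(tips)))
    }
    internals[[length(internals) + 1L]] <<- node
    my <- length(internals)
    kids <- lapply(node$children, collect)
    list(kind = "int", idx = my, kids = kids)
  }
  shape <- collect(root)
  ntip <- length(tips); nint <- length(internals)

  spCount <- integer(0)
  tipLabel <- character(ntip)
  for (i in seq_len(ntip)) {
    sp <- tips[[i]]$species
    k <- (if (sp %in% names(spCount)) spCount[[sp]] else 0L) + 1L
    spCount[sp] <- k
    tipLabel[i] <- sprintf("%s_%s_%d", sp, familyId, k)
  }

  edges <- matrix(0L, nrow = 0, ncol = 2)
  elen <- numeric(0)
  addEdges <- function(shape) {
    if (shape$kind == "tip") return(invisible(NULL))
    me <- ntip + shape$idx
    for (k in shape$kids) {
      child <- if (k$kind == "tip") k$idx else ntip + k$idx
      node <- if (k$kind == "tip") tips[[k$idx]] else internals[[k$idx]]
      edges <<- rbind(edges, c(me, child))
      elen <<- c(elen, node$length)
      addEdges(k)
    }
  }
  addEdges(shape)

  phy <- list(edge = edges, edge.length = elen, tip.label = tipLabel,
              Nnode = nint)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  event <- ifelse(vapply(internals, function(n) n$type, character(1)) == "dup",
                  "duplication", "speciation")
  list(phy = phy, event = event)
}

#' Simulate a set of families and assemble their true catalog
#'
#' Families are simulated with consecutive seeds derived from `seed`; each
#' family becomes one HOG, its true ortholog groups become FOGs with the
#' true parentage (abstract tie-parents are dropped to `NA`), and all
#' proteins enter with status `predicted`.
#'
#' @param taxonomy a [SpeciesTaxonomy-class].
#' @param nFamilies number of families.
#' @param dupRate,lossRate birth-death rates per unit branch length.
#' @param seed integer seed.
#' @param proteinLength length given to every simulated protein.
#' @return list with `catalog` ([OrthologCatalog-class]), `truths` and
#'   `trees` (both named by HOG id).
#' @export
simulateFamilies <- function(taxonomy, nFamilies, dupRate = 0.1,
                             lossRate = 0, seed = 1L, proteinLength = 400L) {
  truths <- list(); trees <- list()
  protRows <- list(); fogRows <- list()
  fogCounter <- 0L
  for (i in seq_len(nFamilies)) {
    famId <- sprintf("f%04d", i)
    hogId <- formatGroupId("HOG", i)
    famSeed <- as.integer((as.numeric(seed) * 7919 + i) %% 2147483647)
    truth <- simulateGeneFamily(taxonomy, dupRate, lossRate,
                                seed = famSeed, familyId = famId)
    truths[[hogId]] <- truth
    trees[[hogId]] <- truth@geneTree
    groups <- sort(unique(truth@partition))
    groups <- groups[order(as.integer(sub("^G", "", groups)))]
    fogIdOf <- stats::setNames(
      formatGroupId("FOG", fogCounter + seq_along(groups)), groups)
    fogCounter <- fogCounter + length(groups)
    parent <- truth@parentGroup[groups]
    parentFog <- ifelse(is.na(parent) | !parent %in% groups,
                        NA_character_, fogIdOf[parent])
    fogRows[[i]] <- data.frame(
      fog_id = unname(fogIdOf), hog_id = hogId,
      parent_fog = unname(parentFog), status = "predicted",
      stringsAsFactors = FALSE)
    ids <- names(truth@partition)
    protRows[[i]] <- data.frame(
      protein_id = ids,
      species_code = sub("^([^_]+)_.*$", "\\1", ids),
      length = as.integer(proteinLength),
      fog_id = unname(fogIdOf[truth@partition]),
      stringsAsFactors = FALSE)
  }
  catalog <- OrthologCatalog(do.call(rbind, protRows),
                             do.call(rbind, fogRows))
  list(catalog = catalog, truths = truths, trees = trees)
}

#' Perturb a catalog with known, replayable edits
#'
#' Creates the two clustering pathologies curation must repair: each
#' disjoint pair of FOGs within a HOG is merged with probability `pMerge`
#' (over-clustering) and each remaining FOG with at least two members is
#' split at a random tree-consistent bipartition with probability `pSplit`
#' (under-clustering); finally each assigned protein is unassigned with
#' probability `pUnassign`.  The log replays exactly
#' ([replayPerturbations()]).
#'
#' @param catalog an [OrthologCatalog-class] (typically the truth catalog).
#' @param truths named list of [FamilyTruth-class] by HOG id, supplying the
#'   trees for tree-consistent splits.
#' @param pSplit,pMerge,pUnassign probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @return list with `catalog` and `log` (data.frame `op`, `hog_id`, `old`,
#'   `new`, `members`).
#' @export
perturbCatalog <- function(catalog, truths, pSplit = 0.2, pMerge = 0.2,
                           pUnassign = 0, seed = 1L) {
  stopifnot(pSplit >= 0, pSplit <= 1, pMerge >= 0, pMerge <= 1,
            pUnassign >= 0, pUnassign <= 1)
  set.seed(seed)
  logs <- list()
  pushLog <- function(op, hog, old, new, members = NA_character_) {
    logs[[length(logs) + 1L]] <<- data.frame(
      op = op, hog_id = hog, old = old, new = new, members = members,
      stringsAsFactors = FALSE)
  }
  pr <- catalog@proteins
  fg <- catalog@fogs

  ## merges over disjoint within-HOG pairs
  for (hog in sort(unique(fg$hog_id))) {
    fogs <- sort(fg$fog_id[fg$hog_id == hog])
    if (length(fogs) < 2L) next
    nPairs <- length(fogs) %/% 2L
    for (p in seq_len(nPairs)) {
      pair <- fogs[c(2L * p - 1L, 2L * p)]
      if (stats::runif(1L) >= pMerge) next
      newId <- nextGroupIds(fg$fog_id, 1L, "FOG")
      pr$fog_id[!is.na(pr$fog_id) & pr$fog_id %in% pair] <- newId
      fg <- fg[!fg$fog_id %in% pair, , drop = FALSE]
      fg <- rbind(fg, data.frame(fog_id = newId, hog_id = hog,
                                 parent_fog = NA_character_,
                                 status = "predicted",
                                 stringsAsFactors = FALSE))
      pushLog("merge", hog, paste(pair, collapse = ","), newId)
    }
  }

  ## splits at tree-consistent bipartitions
  merged <- unlist(lapply(logs, function(x) x$new))
  for (fog in sort(setdiff(fg$fog_id, merged))) {
    members <- pr$protein_id[!is.na(pr$fog_id) & pr$fog_id == fog]
    if (length(members) < 2L) next
    if (stats::runif(1L) >= pSplit) next
    hog <- fg$hog_id[match(fog, fg$fog_id)]
    truth <- truths[[hog]]
    bip <- treeBipartitions(truth@geneTree, members)
    if (!length(bip)) next
    pick <- bip[[sample.int(length(bip), 1L)]]
    parts <- list(sort(pick), sort(setdiff(members, pick)))
    newIds <- nextGroupIds(fg$fog_id, 2L, "FOG")
    for (j in 1:2)
      pr$fog_id[pr$protein_id %in% parts[[j]]] <- newIds[j]
    fg <- fg[fg$fog_id != fog, , drop = FALSE]
    fg <- rbind(fg, data.frame(fog_id = newIds, hog_id = hog,
                               parent_fog = NA_character_,
                               status = "predicted",
                               stringsAsFactors = FALSE))
    pushLog("split", hog, fog, paste(newIds, collapse = ","),
            paste(vapply(parts, paste, character(1), collapse = ","),
                  collapse = "|"))
  }

  ## unassignments
  if (pUnassign > 0) {
    assigned <- which(!is.na(pr$fog_id))
    drop <- assigned[stats::runif(length(assigned)) < pUnassign]
    for (i in drop) {
      pushLog("unassign", NA_character_, pr$fog_id[i], NA_character_,
              pr$protein_id[i])
      pr$fog_id[i] <- NA_character_
    }
  }

  log <- if (length(logs)) do.call(rbind, logs)
  else data.frame(op = character(), hog_id = character(), old = character(),
                  new = character(), members = character(),
                  stringsAsFactors = FALSE)
  list(catalog = OrthologCatalog(pr, fg, catalog@metadata), log = log)
}

## All distinct bipartitions of `members` induced by clades of the tree.
treeBipartitions <- function(gtree, members) {
  phy <- gtree@tree
  ntip <- length(phy$tip.label)
  tips <- cladeTipList(phy)
  out <- list(); seen <- character()
  for (i in seq_along(tips)) {
    s <- intersect(phy$tip.label[tips[[i]]], members)
    if (!length(s) || length(s) == length(members)) next
    key <- paste(sort(s), collapse = ",")
    keyC <- paste(sort(setdiff(members, s)), collapse = ",")
    if (key %in% seen || keyC %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- s
  }
  out
}

#' Replay a perturbation log
#'
#' Applies the recorded edits in order; replaying the log of
#' [perturbCatalog()] on its input reproduces its output exactly.
#'
#' @param catalog the catalog the log was recorded against.
#' @param log the `log` data.frame from [perturbCatalog()].
#' @return the perturbed [OrthologCatalog-class].
#' @export
replayPerturbations <- function(catalog, log) {
  pr <- catalog@proteins
  fg <- catalog@fogs
  for (i in seq_len(nrow(log))) {
    row <- log[i, ]
    if (row$op == "merge") {
      old <- strsplit(row$old, ",", fixed = TRUE)[[1L]]
      pr$fog_id[!is.na(pr$fog_id) & pr$fog_id %in% old] <- row$new
      fg <- fg[!fg$fog_id %in% old, , drop = FALSE]
      fg <- rbind(fg, data.frame(fog_id = row$new, hog_id = row$hog_id,
                                 parent_fog = NA_character_,
                                 status = "predicted",
                                 stringsAsFactors = FALSE))
    } else if (row$op == "split") {
      newIds <- strsplit(row$new, ",", fixed = TRUE)[[1L]]
      parts <- strsplit(strsplit(row$members, "|", fixed = TRUE)[[1L]],
                        ",", fixed = TRUE)
      for (j in seq_along(parts))
        pr$fog_id[pr$protein_id %in% parts[[j]]] <- newIds[j]
      fg <- fg[fg$fog_id != row$old, , drop = FALSE]
      fg <- rbind(fg, data.frame(fog_id = newIds, hog_id = row$hog_id,
                                 parent_fog = NA_character_,
                                 status = "predicted",
                                 stringsAsFactors = FALSE))
    } else if (row$op == "unassign") {
      pr$fog_id[pr$protein_id == row$members] <- NA_character_
    }
  }
  OrthologCatalog(pr, fg, catalog@metadata)
}

#' Simulate similarity hits between co-orthologs
#'
#' One hit per (focal-species protein, co-ortholog) pair.  Percent identity
#' is drawn from a clipped normal around the subject species' group mean;
#' bit score and expect value are deterministic monotone transforms of
#' identity and subject length, so score distributions order by divergence
#' exactly as the identity means do.
#'
#' @param catalog an [OrthologCatalog-class].
#' @param taxonomy a [SpeciesTaxonomy-class].
#' @param focalSpecies query-side species code.
#' @param identityByGroup named numeric vector group -> mean percent
#'   identity in (0, 100).
#' @param noiseSd standard deviation of the identity noise.
#' @param seed integer seed.
#' @return data.frame of hit records ([readHitTable()] columns).
#' @export
simulateHits <- function(catalog, taxonomy, focalSpecies, identityByGroup,
                         noiseSd = 3, seed = 1L) {
  stopifnot(all(identityByGroup > 0), all(identityByGroup < 100))
  set.seed(seed)
  pr <- catalog@proteins
  assigned <- pr[!is.na(pr$fog_id), , drop = FALSE]
  rows <- list()
  for (fog in sort(unique(assigned$fog_id))) {
    memb <- assigned[assigned$fog_id == fog, , drop = FALSE]
    focal <- memb[memb$species_code == focalSpecies, , drop = FALSE]
    other <- memb[memb$species_code != focalSpecies, , drop = FALSE]
    if (!nrow(focal) || !nrow(other)) next
    for (i in seq_len(nrow(focal))) {
      grp <- taxonomy@groupOf[other$species_code]
      mu <- identityByGroup[grp]
      ident <- pmin(pmax(stats::rnorm(nrow(other), mu, noiseSd), 0.1), 100)
      bit <- round(2 * other$length * ident / 100, 2)
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = focal$protein_id[i], subject_id = other$protein_id,
        pct_identity = ident, bit_score = bit, evalue = 10^(-bit / 5),
        subject_length = other$length, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(query_id = character(), subject_id = character(),
                  pct_identity = numeric(), bit_score = numeric(),
                  evalue = numeric(), subject_length = integer(),
                  stringsAsFactors = FALSE)
}

#' Degrade the supports of a gene tree
#'
#' Multiplies every internal-node support by a Beta-distributed factor, to
#' exercise the unresolved-duplication path of event inference on otherwise
#' perfect simulated trees.
#'
#' @param gtree a [GeneTree-class].
#' @param shape1,shape2 Beta parameters of the degradation factor.
#' @param seed integer seed.
#' @return the gene tree with degraded supports.
#' @export
degradeSupport <- function(gtree, shape1 = 5, shape2 = 2, seed = 1L) {
  set.seed(seed)
  f <- stats::rbeta(length(gtree@support), shape1, shape2)
  gtree@support <- as.integer(round(gtree@support * f))
  gtree
}
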