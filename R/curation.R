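## Stage 2: root gene trees, infer duplication/speciation events by the
## species-overlap rule, delineate hierarchical ortholog groups, and apply
## the split (over-clustering) and merge (under-clustering) rules.

#' Curation configuration
#'
#' @param supportThreshold integer 0-100; a duplication node is only used
#'   for splitting when its bootstrap support reaches this value (default
#'   70, chosen so that the canonical 79%-supported paralog subtree
#'   qualifies while poorly resolved nodes do not).
#' @param outgroupSpecies ordered character vector of species codes used
#'   for rooting; empty means always midpoint-root.
#' @param minSpeciesOverlap integer >= 1; number of species the two child
#'   subtrees must share for a node to count as a duplication.
#' @return a list of class `CurationConfig`.
#' @export
curationConfig <- function(supportThreshold = 70L,
                           outgroupSpecies = character(),
                           minSpeciesOverlap = 1L) {
  supportThreshold <- as.integer(supportThreshold)
  minSpeciesOverlap <- as.integer(minSpeciesOverlap)
  stopifnot(supportThreshold >= 0L, supportThreshold <= 100L,
            minSpeciesOverlap >= 1L)
  structure(list(supportThreshold = supportThreshold,
                 outgroupSpecies = as.character(outgroupSpecies),
                 minSpeciesOverlap = minSpeciesOverlap),
            class = "CurationConfig")
}

## children of every node, as a list indexed by node number
treeChildren <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  out <- vector("list", n)
  for (i in seq_len(nrow(phy$edge)))
    out[[phy$edge[i, 1L]]] <- c(out[[phy$edge[i, 1L]]], phy$edge[i, 2L])
  out
}

## tip indices under every internal node
cladeTipList <- function(phy) {
  ntip <- length(phy$tip.label)
  phangorn::Descendants(phy, (ntip + 1L):(ntip + phy$Nnode), type = "tips")
}

## distance from the species-tree root to the MRCA of a species set;
## smaller = older stem.  Unit branch lengths are assumed when the tree
## carries none.
speciesDepths <- function(taxonomy) {
  phy <- taxonomy@tree
  if (is.null(phy$edge.length)) phy$edge.length <- rep(1, nrow(phy$edge))
  ape::node.depth.edgelength(phy)
}

cladeAge <- function(taxonomy, species, depths) {
  tipIdx <- match(unique(species), taxonomy@tree$tip.label)
  if (anyNA(tipIdx))
    stop("species absent from the species tree: ",
         unique(species)[which(is.na(tipIdx))[1L]])
  if (length(tipIdx) == 1L) return(depths[tipIdx])
  depths[ape::getMRCA(taxonomy@tree, tipIdx)]
}

#' Root a gene tree
#'
#' When leaves from the configured outgroup species exist and form a clade
#' on some rooting, the tree is rooted on the edge separating them from the
#' rest; otherwise it is midpoint-rooted (with a warning when an outgroup
#' was requested but is non-separable).
#'
#' @param gtree a [GeneTree-class] with at least three leaves.
#' @param taxonomy optional [SpeciesTaxonomy-class] (unused for rooting
#'   itself; accepted for interface symmetry).
#' @param config a [curationConfig()].
#' @return a rooted [GeneTree-class].
#' @export
rootGeneTree <- function(gtree, taxonomy = NULL, config = curationConfig()) {
  phy <- gtree@tree
  ntip <- length(phy$tip.label)
  if (ntip < 3L) stop("cannot root a tree with fewer than 3 leaves")
  phy$node.label <- ifelse(is.na(gtree@support), "",
                           as.character(gtree@support))
  if (is.null(phy$edge.length)) phy$edge.length <- rep(1, nrow(phy$edge))
  sp <- leafSpecies(gtree)
  og <- phy$tip.label[sp %in% config$outgroupSpecies]
  rooted <- NULL
  if (length(og) && length(og) < ntip) {
    rooted <- tryCatch(
      ape::root(phy, outgroup = og, resolve.root = TRUE),
      error = function(e) {
        warning("outgroup leaves are not separable; falling back to ",
                "midpoint rooting")
        NULL
      })
  }
  if (is.null(rooted)) rooted <- phangorn::midpoint(phy)
  lab <- rooted$node.label
  if (is.null(lab)) lab <- rep("", rooted$Nnode)
  lab[is.na(lab) | lab == ""] <- NA_character_
  support <- suppressWarnings(as.integer(lab))
  rooted$node.label <- NULL
  geneTree(rooted, support = support, rooted = TRUE,
           speciesMap = gtree@speciesMap)
}

#' Infer speciation/duplication events by species overlap
#'
#' An internal node is a duplication iff its child subtrees share at least
#' `minSpeciesOverlap` species; otherwise it is a speciation.  Duplications
#' whose bootstrap support falls below `supportThreshold` (missing support
#' counts as zero) are labelled `unresolved`: they are evidence too weak to
#' split a group on, though they still block nothing else.
#'
#' @param gtree a rooted [GeneTree-class].
#' @param config a [curationConfig()].
#' @return the gene tree with its `event` slot filled.
#' @export
inferNodeEvents <- function(gtree, config = curationConfig()) {
  if (!gtree@rooted) stop("event inference requires a rooted tree")
  phy <- gtree@tree
  ntip <- length(phy$tip.label)
  sp <- leafSpecies(gtree)
  children <- treeChildren(phy)
  tips <- cladeTipList(phy)
  cladeSp <- function(node) {
    if (node <= ntip) sp[node] else unique(sp[tips[[node - ntip]]])
  }
  event <- character(phy$Nnode)
  for (nd in (ntip + 1L):(ntip + phy$Nnode)) {
    kids <- children[[nd]]
    spSets <- lapply(kids, cladeSp)
    shared <- unique(unlist(lapply(seq_along(spSets), function(i)
      intersect(spSets[[i]], unlist(spSets[-i])))))
    if (length(shared) >= config$minSpeciesOverlap) {
      supp <- gtree@support[nd - ntip]
      if (is.na(supp)) supp <- 0L
      event[nd - ntip] <- if (supp >= config$supportThreshold) "duplication"
                          else "unresolved"
    } else {
      event[nd - ntip] <- "speciation"
    }
  }
  gtree@event <- event
  gtree
}

#' Delineate hierarchical ortholog groups from an event-labelled tree
#'
#' The tree is cut at every duplication node: the child clade whose
#' earliest-diverging species (stem of its species-tree MRCA) is younger is
#' cut off as a new child group, while the clade with the older stem
#' continues upward as the parent lineage, merging with earlier-diverged
#' leaves across speciation nodes.  When the two clades tie, all children
#' are cut and become children of a new abstract parent id.  Clades
#' containing a single species (species-lineage expansions, i.e.
#' in-paralogs) are never cut, so same-species duplicates below a
#' speciation backbone stay in one group.  `unresolved` duplications never
#' cut.
#'
#' @param gtree a rooted, event-labelled [GeneTree-class].
#' @param taxonomy a [SpeciesTaxonomy-class] covering all leaf species.
#' @param config a [curationConfig()].
#' @return list with `membership` (named character, tip label -> group id),
#'   `groups` (list group id -> tip labels), `parent` (named character,
#'   group id -> parent group id or `NA`) and `abstract` (character vector
#'   of abstract parent ids, which have no members).
#' @export
delineateOrthologGroups <- function(gtree, taxonomy,
                                    config = curationConfig()) {
  if (!gtree@rooted) stop("delineation requires a rooted tree")
  if (all(is.na(gtree@event))) gtree <- inferNodeEvents(gtree, config)
  phy <- gtree@tree
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  sp <- leafSpecies(gtree)
  children <- treeChildren(phy)
  tips <- cladeTipList(phy)
  depths <- speciesDepths(taxonomy)
  cladeSpOf <- function(node) {
    if (node <= ntip) sp[node] else unique(sp[tips[[node - ntip]]])
  }

  cut <- matrix(FALSE, nrow = 0, ncol = 2) # (parent, child) cut edges
  abstractAt <- integer()
  for (nd in (ntip + 1L):(ntip + nnode)) {
    if (gtree@event[nd - ntip] != "duplication") next
    if (length(cladeSpOf(nd)) == 1L) next # species-lineage expansion
    kids <- children[[nd]]
    ages <- vapply(kids, function(k) cladeAge(taxonomy, cladeSpOf(k), depths),
                   numeric(1))
    oldest <- which(ages == min(ages))
    if (length(oldest) == 1L) {
      toCut <- kids[-oldest]
    } else {
      toCut <- kids
      abstractAt <- c(abstractAt, nd)
    }
    cut <- rbind(cut, cbind(nd, toCut))
  }

  uf <- unionFind(ntip + nnode)
  cutKey <- paste(cut[, 1L], cut[, 2L])
  for (i in seq_len(nrow(phy$edge))) {
    if (!paste(phy$edge[i, 1L], phy$edge[i, 2L]) %in% cutKey)
      uf$union(phy$edge[i, 1L], phy$edge[i, 2L])
  }
  comp <- uf$components()

  tipComps <- unique(comp[seq_len(ntip)])
  ## deterministic group ids ordered by smallest tip index in each component
  firstTip <- vapply(tipComps, function(cc) min(which(comp[seq_len(ntip)] == cc)),
                     integer(1))
  tipComps <- tipComps[order(firstTip)]
  groupId <- stats::setNames(paste0("G", seq_along(tipComps)), tipComps)
  membership <- stats::setNames(unname(groupId[as.character(comp[seq_len(ntip)])]),
                                phy$tip.label)
  groups <- split(phy$tip.label, membership)
  groups <- groups[order(as.integer(sub("^G", "", names(groups))))]

  parent <- stats::setNames(rep(NA_character_, length(groups)), names(groups))
  abstract <- character()
  abstractIdOf <- stats::setNames(
    paste0("A", seq_along(abstractAt)), abstractAt)
  if (length(abstractAt)) {
    abstract <- unname(abstractIdOf)
    parent <- c(parent, stats::setNames(rep(NA_character_, length(abstract)),
                                        abstract))
  }
  groupOfComp <- function(cc) {
    id <- groupId[as.character(cc)]
    if (is.na(id)) NA_character_ else unname(id)
  }
  for (i in seq_len(nrow(cut))) {
    d <- cut[i, 1L]; ch <- cut[i, 2L]
    childGrp <- groupOfComp(comp[ch])
    if (is.na(childGrp)) next # leafless fragment (nested tie)
    parentGrp <- if (d %in% abstractAt) unname(abstractIdOf[as.character(d)])
                 else groupOfComp(comp[d])
    if (!is.na(parentGrp) && parentGrp != childGrp)
      parent[childGrp] <- parentGrp
  }
  for (d in abstractAt) {
    up <- groupOfComp(comp[d])
    if (!is.na(up)) parent[abstractIdOf[as.character(d)]] <- up
  }
  list(membership = membership, groups = groups, parent = parent,
       abstract = abstract)
}

#' Propose a split for an over-clustered group
#'
#' Returns a proposal iff the minimal clade spanning the group's members
#' contains a well-supported duplication separating them; the proposal is
#' the delineated sub-partition restricted to the members, with parentage.
#'
#' @param members character vector of protein ids, all leaves of the tree.
#' @param gtree a rooted [GeneTree-class] (events inferred on demand).
#' @param taxonomy a [SpeciesTaxonomy-class].
#' @param config a [curationConfig()].
#' @return `NULL` when no supported duplication separates the members;
#'   otherwise a list with `groups` (list of member subsets), `parent`
#'   (named character over the proposal's group ids) and `abstract`.
#' @export
detectOverclustering <- function(members, gtree, taxonomy,
                                 config = curationConfig()) {
  missing <- setdiff(members, gtree@tree$tip.label)
  if (length(missing))
    stop("group member not in the tree: ", missing[1L])
  part <- delineateOrthologGroups(gtree, taxonomy, config)
  mm <- part$membership[members]
  used <- unique(mm)
  if (length(used) < 2L) return(NULL)
  groups <- split(members, mm)
  groups <- groups[order(as.integer(sub("^G", "", names(groups))))]
  keep <- unique(c(names(groups), part$abstract))
  parent <- part$parent[names(part$parent) %in% keep]
  parent[!parent %in% keep] <- NA_character_
  list(groups = groups, parent = parent,
       abstract = intersect(part$abstract, keep))
}

#' Merge an under-clustered homolog group
#'
#' When a HOG holds two or more FOGs yet no organism contributes two or more
#' proteins anywhere in the HOG, there is no evidence of duplication and the
#' FOGs are collapsed into one new FOG with status
#' `electronically_modified`.  Otherwise the catalog is unchanged.
#'
#' @param catalog an [OrthologCatalog-class].
#' @param hogId HOG to examine.
#' @return list with `catalog`, `merged` (logical) and `log` (data.frame of
#'   applied edits, zero rows when nothing merged).
#' @export
mergeUnderclustered <- function(catalog, hogId) {
  fg <- catalog@fogs
  fogs <- sort(unique(fg$fog_id[fg$hog_id == hogId]))
  emptyLog <- data.frame(op = character(), hog_id = character(),
                         old = character(), new = character(),
                         stringsAsFactors = FALSE)
  if (length(fogs) < 2L)
    return(list(catalog = catalog, merged = FALSE, log = emptyLog))
  pr <- catalog@proteins
  members <- pr[!is.na(pr$fog_id) & pr$fog_id %in% fogs, , drop = FALSE]
  if (nrow(members) && max(table(members$species_code)) >= 2L)
    return(list(catalog = catalog, merged = FALSE, log = emptyLog))
  newId <- nextGroupIds(fg$fog_id, 1L, "FOG")
  pr$fog_id[pr$fog_id %in% fogs & !is.na(pr$fog_id)] <- newId
  fg <- fg[!fg$fog_id %in% fogs, , drop = FALSE]
  fg <- rbind(fg, data.frame(fog_id = newId, hog_id = hogId,
                             parent_fog = NA_character_,
                             status = "electronically_modified",
                             stringsAsFactors = FALSE))
  log <- data.frame(op = "merge", hog_id = hogId,
                    old = paste(fogs, collapse = ","), new = newId,
                    stringsAsFactors = FALSE)
  list(catalog = OrthologCatalog(pr, fg, catalog@metadata), merged = TRUE,
       log = log)
}

#' Curate a catalog against per-HOG gene trees
#'
#' Two passes, in ascending HOG order for determinism.  First the
#' copy-count merge rule ([mergeUnderclustered()]) runs on every HOG.  Then
#' every HOG that has a tree is reshaped to the tree's delineated partition:
#' FOGs spanning several delineated groups are split
#' ([detectOverclustering()] semantics) and FOGs that delineation places in
#' one group are merged, so under-clustering inside homolog families that
#' do contain duplications -- where the copy-count rule must stay silent --
#' is also repaired.  HOGs without a tree are logged as skipped.  Proteins
#' are only ever reassigned, never added or removed.
#'
#' @param catalog an [OrthologCatalog-class].
#' @param trees named list, HOG id -> rooted (or rootable)
#'   [GeneTree-class].
#' @param taxonomy a [SpeciesTaxonomy-class].
#' @param config a [curationConfig()].
#' @return list with `catalog` and `log`, a data.frame of edits with
#'   columns `op` (`merge`, `split`, `skipped`), `hog_id`, `old`, `new`.
#' @export
curateCatalog <- function(catalog, trees, taxonomy,
                          config = curationConfig()) {
  logs <- list()
  pushLog <- function(op, hog, old = NA_character_, new = NA_character_) {
    logs[[length(logs) + 1L]] <<- data.frame(
      op = op, hog_id = hog, old = old, new = new, stringsAsFactors = FALSE)
  }

  hogs <- sort(unique(catalog@fogs$hog_id))

  ## pass 1: copy-count merges
  for (hog in hogs) {
    res <- mergeUnderclustered(catalog, hog)
    catalog <- res$catalog
    if (res$merged) pushLog("merge", hog, res$log$old, res$log$new)
  }

  ## pass 2: tree-guided reshape
  for (hog in hogs) {
    if (!hog %in% names(trees)) {
      pushLog("skipped", hog)
      next
    }
    gt <- trees[[hog]]
    if (!gt@rooted) gt <- rootGeneTree(gt, taxonomy, config)
    if (all(is.na(gt@event))) gt <- inferNodeEvents(gt, config)
    part <- delineateOrthologGroups(gt, taxonomy, config)

    pr <- catalog@proteins
    fg <- catalog@fogs
    hogFogs <- sort(unique(fg$fog_id[fg$hog_id == hog]))
    inTree <- pr$protein_id %in% gt@tree$tip.label &
      !is.na(pr$fog_id) & pr$fog_id %in% hogFogs

    ## splits: a FOG whose tree members span >1 delineated group
    for (fog in hogFogs) {
      memb <- pr$protein_id[inTree & pr$fog_id == fog]
      if (length(memb) < 2L) next
      grp <- part$membership[memb]
      if (length(unique(grp)) < 2L) next
      frags <- split(memb, grp)
      frags <- frags[order(as.integer(sub("^G", "", names(frags))))]
      ## members of the FOG absent from the tree follow the largest fragment
      loose <- pr$protein_id[!inTree & !is.na(pr$fog_id) & pr$fog_id == fog]
      if (length(loose)) {
        big <- which.max(lengths(frags))
        frags[[big]] <- c(frags[[big]], loose)
      }
      newIds <- nextGroupIds(fg$fog_id, length(frags), "FOG")
      for (j in seq_along(frags))
        pr$fog_id[pr$protein_id %in% frags[[j]]] <- newIds[j]
      fg <- fg[fg$fog_id != fog, , drop = FALSE]
      fg <- rbind(fg, data.frame(fog_id = newIds, hog_id = hog,
                                 parent_fog = NA_character_,
                                 status = "electronically_modified",
                                 stringsAsFactors = FALSE))
      pushLog("split", hog, fog, paste(newIds, collapse = ","))
    }
    catalog <- OrthologCatalog(pr, fg, catalog@metadata)

    ## merges: several FOGs mapping into one delineated group
    pr <- catalog@proteins
    fg <- catalog@fogs
    hogFogs <- sort(unique(fg$fog_id[fg$hog_id == hog]))
    inTree <- pr$protein_id %in% gt@tree$tip.label &
      !is.na(pr$fog_id) & pr$fog_id %in% hogFogs
    fogGroup <- stats::setNames(rep(NA_character_, length(hogFogs)), hogFogs)
    for (fog in hogFogs) {
      memb <- pr$protein_id[inTree & pr$fog_id == fog]
      if (length(memb)) fogGroup[fog] <- part$membership[memb[1L]]
    }
    for (g in unique(stats::na.omit(fogGroup))) {
      fogsIn <- sort(names(fogGroup)[!is.na(fogGroup) & fogGroup == g])
      if (length(fogsIn) < 2L) next
      newId <- nextGroupIds(fg$fog_id, 1L, "FOG")
      pr$fog_id[!is.na(pr$fog_id) & pr$fog_id %in% fogsIn] <- newId
      fg <- fg[!fg$fog_id %in% fogsIn, , drop = FALSE]
      fg <- rbind(fg, data.frame(fog_id = newId, hog_id = hog,
                                 parent_fog = NA_character_,
                                 status = "electronically_modified",
                                 stringsAsFactors = FALSE))
      fogGroup <- fogGroup[!names(fogGroup) %in% fogsIn]
      fogGroup[newId] <- g
      pushLog("merge", hog, paste(fogsIn, collapse = ","), newId)
    }

    ## parentage from the delineated hierarchy (abstract parents -> NA)
    groupFog <- stats::setNames(names(fogGroup)[!is.na(fogGroup)],
                                fogGroup[!is.na(fogGroup)])
    for (g in names(groupFog)) {
      pg <- part$parent[g]
      if (is.na(pg) || !pg %in% names(groupFog)) next
      fg$parent_fog[fg$fog_id == groupFog[[g]]] <- groupFog[[pg]]
    }
    catalog <- OrthologCatalog(pr, fg, catalog@metadata)
  }

  log <- if (length(logs)) do.call(rbind, logs)
  else data.frame(op = character(), hog_id = character(),
                  old = character(), new = character(),
                  stringsAsFactors = FALSE)
  list(catalog = catalog, log = log)
}
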