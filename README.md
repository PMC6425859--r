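# OrthoCurator

Graph-based ortholog clustering (OrthoMCL-style Markov clustering, OrthoDB
homolog families) is fast but imperfect: it **over-clusters** — lumping
paralogs born of gene duplication into one "ortholog" group — and it
**under-clusters** — scattering true orthologs with low sequence similarity
across several groups. OrthoCurator is an R toolkit for building and
curating a *hierarchical* ortholog catalog for a pan-proteome (written for
yeasts and fungi, usable for any clade): fine-grained ortholog groups
(FOGs) nested inside homolog groups (HOGs), with parent → child links
between a duplication's ancestral and derived groups.

It is aimed at comparative genomicists and metabolic engineers who maintain
curated ortholog databases and need the curation steps to be explicit,
deterministic and testable rather than manual.

## What it does

1. **Grouping** — coalesce FOGs into HOGs by majority homolog-family label
   (ties to the lexicographically smallest label; conflicts reported, not
   lost), and seed singleton FOGs for labelled proteins the clustering
   missed.
2. **Tree curation** — for each HOG's consensus gene tree: root (outgroup,
   else midpoint), label every internal node *speciation* or *duplication*
   by the **species-overlap rule** (a node is a duplication iff its child
   subtrees share ≥ 1 species), and delineate ortholog groups by cutting
   the tree at duplications with bootstrap support ≥ 70 (configurable).
   At each cut the clade whose earliest-diverging species is older is the
   parent group; same-species expansions (in-paralogs) are never cut.
   Over-clustered FOGs are split along these cuts; FOGs in HOGs with no
   duplicated organism are merged.
3. **Rescue** — admit proteins missed by annotation or clustering from
   parsed similarity and phylogenetic-placement tables: expect-value
   pre-filter (1e-20), HOG by best BLASTP-style hit, FOG by maximum
   likelihood weight ratio (accepted at LWR ≥ 0.5), and a length filter
   discarding candidates shorter than 75 % of the group's mean length.
4. **QC** — flag localization-prediction outliers (group median ≥ 0.5 but
   a member ≥ 0.5 below it) and length outliers per group.
5. **Comparison** — classify every FOG against another ortholog database as
   congruent / over-clustered / under-clustered / both / no assignment,
   restricted to groups with species the other database covers; profile
   percent identity, log10 bit score and −log10 expect value by divergence
   group.
6. **Simulation** — a birth–death gene-family simulator on a species tree
   (including a fixed 33-species, six-group yeast taxonomy) with exact
   ground truth: true events, true partition, and a replayable perturbation
   log, so every stage above is validated against known answers.

I/O covers TSV, JSON, orthoXML (v0.3 layout), Newick (bootstrap node
labels) and FASTA, all round-trip faithful; gzip input is transparent.

## Worked example

Simulate 50 gene families on a 10-species tree, inject known over- and
under-clustering, then let curation repair it against the true trees:

```r
library(OrthoCurator)

tax <- simulateSpeciesTree(10, seed = 1)
sim <- simulateFamilies(tax, 50, dupRate = 0.1, lossRate = 0, seed = 1)
sim$catalog
#> OrthologCatalog with 544 proteins ( 544 assigned ), 74 FOGs, 50 HOGs
#>   status: predicted=74

pert <- perturbCatalog(sim$catalog, sim$truths, pSplit = 0.2, pMerge = 0.2,
                       seed = 2)
table(pert$log$op)
#> merge split
#>     3    11

cur <- curateCatalog(pert$catalog, sim$trees, tax,
                     curationConfig(supportThreshold = 70))
table(cur$log$op)
#> merge split
#>    11     3
cur$catalog
#> OrthologCatalog with 544 proteins ( 544 assigned ), 74 FOGs, 50 HOGs
#>   status: electronically_modified=17, predicted=57

f0 <- fogOf(sim$catalog); f1 <- fogOf(cur$catalog)[names(f0)]
mclust::adjustedRandIndex(factor(f0), factor(f1))
#> [1] 1
```

The 11 injected splits are undone by 11 merges and the 3 injected merges by
3 splits; the curated partition matches the simulated truth exactly
(adjusted Rand index 1), and every rebuilt group is stamped
`electronically_modified` so provenance survives.

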