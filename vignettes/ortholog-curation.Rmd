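---
title: "Tree-based curation of hierarchical ortholog groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-based curation of hierarchical ortholog groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OrthoCurator)
```

## The problem

Graph-based clustering assigns proteins to ortholog groups from pairwise
sequence similarity alone. Two systematic failure modes follow. When a
gene family duplicated recently, the paralogous copies are more similar to
each other than to anything else and get lumped into one group
(*over-clustering*): a group that claims to be "the" ortholog set actually
mixes two functional lineages. When true orthologs have drifted far apart
— short proteins, fast-evolving regulators — similarity falls below the
clustering threshold and one ortholog set is scattered over several groups
(*under-clustering*). Both pathologies are visible in a gene tree, which
is why tree review is the reference method for orthology even when
clustering produces the first draft.

OrthoCurator operationalises that review. The catalog it maintains is
hierarchical: fine-grained ortholog groups (FOGs) nest inside homolog
groups (HOGs), and a FOG born of a duplication points at its parent FOG,
so a query can be answered at either resolution.

## The curation model

### Event inference: the species-overlap rule

On a rooted gene tree, an internal node is labelled a **duplication** iff
its child subtrees share at least one species (`minSpeciesOverlap`,
default 1): a species can carry two descendants of a node only if the gene
doubled before the lineages split. Otherwise the node is a
**speciation**. This is the classical species-overlap heuristic; it
deliberately avoids full gene-tree/species-tree reconciliation, which
requires a fully resolved species tree and is sensitive to its errors.
The cost of the shortcut is known: a duplication followed by complete loss
of one copy in all overlapping species is invisible, and incomplete
lineage sorting can masquerade as duplication. On loss-free trees the
rule is exact — the simulator-backed tests exploit precisely this — and
with losses it errs on the conservative side (missed duplications, never
invented ones).

A duplication whose bootstrap support is below `supportThreshold` is
labelled **unresolved**: real enough to report, too weak to act on.
The default threshold is 70, a conventional "well-supported" bootstrap
bar; it is deliberately below the 79 % support of the canonical
acetyl-CoA-synthetase paralog subtree that motivates the hierarchy, so
that textbook case splits under defaults. Missing supports count as zero:
an unlabelled node never justifies a split.

### Delineation and parentage

Ortholog groups are obtained by cutting the tree at supported
duplications. At each such node one child clade — the one whose species
set has the *older* stem in the species tree (its MRCA sits closer to the
species-tree root) — continues the ancestral lineage upward and keeps
merging with earlier-diverged leaves across speciation nodes; the other
clade is cut off as a new group whose `parent_fog` is the continuing one.
The rationale is the acetyl-CoA-synthetase narrative: the derived copy is
recognisable because the deep-branching species lack it, so the clade
retaining deep species is the ancestral (parent) group.

Two deliberate refinements:

* **Species-lineage expansions are never cut.** A clade containing a
  single species (in-paralogs from a recent within-genome expansion) stays
  inside its parent group. Splitting here would manufacture one
  degenerate group per tandem duplicate, which no curator wants. This is
  also the only situation in which one group may legitimately contain two
  proteins of the same species, and the test suite asserts exactly that
  invariant.
* **Ties create an abstract parent.** When the two clades' species stems
  are equally old — the generic outcome on loss-free simulated trees,
  where both copies descend to identical species sets — there is no
  topological evidence for which copy is ancestral. Both clades become
  groups under a new abstract parent identifier. Abstract parents are
  reported by `delineateOrthologGroups()` but are not materialised as
  empty FOG rows in catalogs; the tie children simply carry no parent
  there. Inventing an orientation instead would be unfalsifiable from the
  data.

### Splitting and merging

`detectOverclustering()` proposes a split for a FOG exactly when the
delineated partition separates its members, i.e. when a supported
duplication lies inside their minimal spanning clade. Raising the support
threshold can only remove cut nodes, so the number of proposed groups is
monotone non-increasing in the threshold — a property the tests sweep over
the full 0–100 range.

`mergeUnderclustered()` implements the copy-count rule: if a HOG holds
two or more FOGs yet *no* organism contributes two proteins anywhere in
the HOG, there is no evidence any duplication ever happened, and the FOGs
collapse into one. This needs no tree at all, which is why it also runs
on HOGs for which no phylogeny is available.

`curateCatalog()` applies the copy-count merge to every HOG, then
reshapes every HOG that has a tree onto the tree's delineated partition —
splitting FOGs that span several delineated groups *and* merging FOGs
that delineation places in one group. The tree-guided merge is a
deliberate design decision: the copy-count rule is necessarily silent in
a HOG that genuinely contains duplications, yet scattered orthologs occur
there too, and the tree adjudicates those cases the same way a human
reviewer of the phylogeny would. Without it, an injected split inside a
duplication-bearing family would be unrepairable and recovery could not
be exact. All rebuilt groups get status `electronically_modified`;
curation is idempotent (a second run makes zero edits), conserves the
multiset of assigned proteins, and logs every edit replayably.

## Rescue, QC, comparison

The rescue chain admits proteins the annotation or the clustering missed:
hits are pre-filtered at expect ≤ 1e-20 (the search itself is external;
the filter is re-applied so the chain is self-contained), the HOG comes
from the best hit (bit score, then expect value, then subject id — a total
order, so ties cannot introduce nondeterminism), the FOG from the
placement with maximal likelihood weight ratio, accepted at LWR ≥ 0.5.
The 0.5 default demands a strict majority of placement mass; the
documented real-world acceptances (LWR 1.0 and 0.79) clear it, and it is
exposed as a parameter because reference placements vary in sharpness.
Candidates shorter than 75 % of the target group's mean length are
discarded as probable gene-model fragments; the boundary case is kept
(length exactly 75 % of the mean passes). The group mean is taken over
*all* current members of the placed FOG — the most reproducible choice;
a same-clade mean would depend on the candidate's placement inside the
group. The same relative-length rule doubles as a QC check over existing
groups.

Localization QC flags a protein when the group median probability is
≥ 0.5 (the group, as a whole, is confidently targeted) and the protein
falls ≥ 0.5 below that median. The median, not the mean, is the
reference: the outlier being hunted would drag a mean toward itself. The
cutoffs are calibrated so the motivating real case — one ortholog at
probability 0.0019 in a group otherwise above 0.80, caused by a truncated
N-terminus — flags, while a group that simply is not mitochondrial
(median below 0.5) never flags anyone. Fewer than three scored members
is declared underpowered rather than judged.

Congruence against another database is classified per FOG over *covered*
species only (species the other database annotates at all): no labelled
member → `none`; two or more distinct external labels → `under`; an
external group that also contains a covered protein from a different FOG
→ `over`; both → `over_and_under`. Defining `over` as "≥ 1 covered
protein from another FOG" (rather than requiring a second whole FOG) is
the stricter, simpler reading and is applied symmetrically to every
database compared. External-only proteins never create `over`, so a
broader database is not penalised for its breadth. Mixed
labelled/unlabelled groups are judged on the labelled members, with the
unlabelled count reported as a coverage note.

## The simulator and what passing its tests means

`simulateGeneFamily()` runs a birth–death process along the species tree:
one ancestral copy at the root, exponential waiting times, duplication
with probability `dupRate/(dupRate+lossRate)` at each event. Surviving
copies become leaves; the true event labels are recorded at every
surviving internal node, supports are set to 100, and the true partition
is the delineation of the true event-labelled tree (on loss-free trees
this is forced: any convention-independent truth would have to orient
duplications whose daughter clades are topologically exchangeable).
Branch lengths are abstract time units; **no sequences are simulated** —
similarity hits are generated separately with group-level identity means
and deterministic monotone score transforms.

The generator therefore emulates the *clustering pathologies* (known
splits/merges injected by `perturbCatalog()` with a replayable log) and
the *divergence ordering* of similarity scores, not: alignment error,
consensus-tree artefacts, rate variation across branches, horizontal
transfer, or annotation noise. Passing the recovery tests shows the
curation logic is exact when trees are correct and fully supported; it
does not show robustness to wrong trees, which is why `degradeSupport()`
exists to exercise the unresolved-event path, and why real curation keeps
bootstrap thresholds in the loop.

Default study sizes, chosen to estimate rates tightly while keeping the
whole suite interactive: 200 families on 10 species at `dupRate` 0.1
(loss-free) for event-inference and recovery checks; 500 groups for
congruence error rates (binomial SE ≈ 1.8 points at 20 %); 100 randomized
catalogs and trees for round-trip checks.

## Numerical and format choices

* Percentages print as integers, rounded half away from zero; the raw
  value is always retained alongside.
* FOG/HOG identifiers are `FOG`/`HOG` plus a zero-padded integer of at
  least five digits, widening when counts overflow.
* Expect values of exactly 0 map to a capped −log10 of 400 (configurable)
  for profiling only; the stored value remains 0.
* TSV output rows sort by (species, protein id) for deterministic diffs;
  JSON uses this package's documented schema (`proteins`, `fogs`,
  `metadata` arrays); orthoXML follows the 0.3 layout with the HOG id,
  parent FOG and status as group `<property>` tags (orthoXML has no
  native multi-level pairing) and protein length/annotation source as
  extra `<gene>` attributes so all formats round-trip bit-faithfully.
  Sequences travel in FASTA only.
* Species codes parse from tip labels as the token before the first
  underscore; an explicit tip → species map overrides this for accessions
  that themselves contain underscores.
* Rooting prefers the configured outgroup when its leaves are separable,
  else falls back to midpoint (with a warning if an outgroup was
  requested); two-leaf trees are rejected. Re-rooting can reattach the
  support of the edge adjacent to the new root, as is inherent to
  bootstrap labels under re-rooting.
* All randomness sits behind explicit integer seeds; per-family seeds are
  derived with a fixed affine map modulo 2^31 − 1.

## Known limitations

Species-overlap misses duplications erased by reciprocal loss; parent
orientation is undefined (abstract) without loss asymmetry; xenolog and
ohnolog annotation is carried as metadata, never inferred — horizontal
transfer and whole-genome-duplication calls need synteny or explicit
donor models outside this package's scope. Manual overrides (forced
protein → FOG assignments from alignment review) are applied verbatim and
not second-guessed. The congruence comparison classifies structure, not
correctness: a database disagreeing with the catalog is "incongruent",
which says nothing about which of the two is right.
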