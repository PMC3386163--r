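---
title: "Estimating and analysing protein phylogenetic ages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and analysing protein phylogenetic ages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylostrat)
```

## The model

`phylostrat` assigns each protein of a focal species a phylogenetic age:
the branch, on the path between the species' leaf and the root of a dated
species tree, on which the protein's family is inferred to have appeared.
Three inputs define an age database:

1. **A rooted, dated species tree.** Internal nodes carry taxon labels
   (the age strata used in reports) and ages in millions of years (mya).
   Only monotone nesting is required — a parent must not be younger than a
   child — not ultrametricity. Polytomies are allowed and handled natively
   by all algorithms. The tree is used as rooted, as written; ages are
   meaningful only relative to the given root, so no rerooting is ever
   performed.
2. **A protein family database.** A partition of all proteins of all
   species into families; copy number is collapsed to presence/absence per
   species, because the reconstruction models gain and loss of the family,
   not changes in copy number.
3. **A reconstruction algorithm.** Either Dollo parsimony or asymmetric
   Wagner parsimony (below).

The age attached to a protein is the age of its origin taxon, and it is a
*lower bound*: the family may have appeared anywhere along the origin
branch. All numerical analyses use the mya values; reports additionally
use the taxon labels as discrete strata.

### Dollo parsimony

Dollo parsimony assumes a family is gained exactly once — a reasonable
assumption for complex sequence features, and the reason a single false
positive in a family database can pull an origin far rootward. The origin
is then necessarily the MRCA of the species possessing the family. Among
the minimal-loss labelings we fix a canonical one: a node is present iff
it lies on a path from the origin to a present leaf, which places one loss
on the highest absent branch of each maximal absent subtree inside the
origin clade. Any minimal-loss convention would give the same origins;
fixing one makes event lists reproducible.

### Asymmetric Wagner parsimony

Wagner parsimony allows multiple gains, trading them against losses via a
cost scheme: a loss costs 1 (the fixed reference) and a gain costs the
*relative gain penalty* `g` (default 1). A minimum-cost 0/1 labeling is
found by Sankoff dynamic programming: a post-order pass computes, for each
node and state, the minimal cost of its subtree; the root adds `g` if
present (origination on the stem); a pre-order traceback then selects
states. Summation over children handles multifurcations directly, with no
binarization.

**Tie-break.** When both states of a node are optimal during traceback we
choose absence. This is deterministic, and it biases ambiguous families
toward multiple recent gains rather than one ancient gain — the direction
in which Wagner estimates are expected to differ from Dollo. With this
convention a protein's Wagner age never exceeds its Dollo age on
loss-only simulated histories (verified exhaustively in the test suite),
and the package's Wagner oracle-equivalence tests check the DP cost
against `brute_force_reconstruct()`, an exhaustive enumeration over all
internal labelings. Other tools that implement Wagner parsimony may break
ties differently; on ambiguous families their event lists (not their
costs) can differ from ours.

**"First appeared" under multiple gains.** A multi-gain labeling has no
single family origin. For a given protein we date the top of the
contiguous present segment of its species' leaf-to-root path: the unique
gain event that explains *this* protein's presence. Under Dollo this
reduces to the family MRCA for every member; under Wagner members in
different species may receive different origins.

### Domain-based ages

As an alternative definition of age, each protein may be dated by its
annotated domains: the age of its oldest domain (conservative, dominated
by the most ancient module) or of its youngest (dominated by the most
recent acquisition). Oldest-domain ages are never younger than
youngest-domain ages, with equality exactly when a protein has at most one
distinct domain age. Ties in age are resolved toward the more leafward
taxon, and proteins with no predicted domains are treated as specific to
their species (age 0, flagged `no_domains`). Domain taxa must be ancestors
of the focal species, since a reported origin must lie on the species'
root path.

## Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| `gain_penalty` | 1 | multiples of the loss cost | larger values force fewer gains; at `g >=` the leaf count the optimum has a single gain at the Dollo origin |
| `loss_penalty` | 1 | reference | exposed for completeness; only the ratio matters |
| `restrict_to_tree` | `FALSE` | — | species present in the family table but absent from the tree abort the run by default, because silently restricting the species set changes ages; the flag opts into dropping them |
| `exclude_oldest` | 0 | strata | number of most ancient strata excluded from the linear trend fit (ancient proteins often do not maintain trends seen among younger ones); the correlation always uses all pairs |
| `bh` | off | — | Benjamini–Hochberg q-values per stratum; raw p-values remain the primary report since the strata are few and strongly dependent |

Node ages may come from a label/age table or from branch lengths (leaves
at 0, internal age = maximum child age + branch length). When both are
available the table is authoritative and any disagreement above 1e-6 mya
is an error rather than a silent preference: literature consensus dates
and inferred branch lengths should not be mixed unknowingly.

## Statistical conventions

* **Mann-Whitney U**: U from midranks; exact two-sided p (null
  distribution of U) when `n1 + n2 <= 12` with no ties, otherwise the
  normal approximation with tie correction and continuity correction.
  Degenerate samples (all values identical) give p = 1. Age data are
  heavily tied — every protein of a stratum shares one value — so the
  approximate branch is the common case; its calibration on a discrete
  age null is checked empirically (5,000 replicates of two n = 200
  samples) in the acceptance tests.
* **Fisher's exact test**: two-sided p sums hypergeometric probabilities
  of all tables (margins fixed) no more probable than the observed one,
  with 1e-12 relative slack for floating-point ties; the reported odds
  ratio is the sample `ad/bc` (with `Inf`/0/`NaN` for zero cells), not a
  conditional MLE. Verified against exhaustive enumeration for every
  table with total at most 40.
* **Spearman correlation**: rho is the Pearson correlation of midranks.
  For `n <= 10` the two-sided p is exact over the full permutation null,
  computed by a subset-sum dynamic program (ranks doubled to integers, so
  midrank ties are exact); above that, the usual t approximation on
  `n - 2` degrees of freedom.
* **Box summaries**: Tukey hinges (median-of-halves, as in `fivenum()`),
  with whiskers at the extreme observations within 1.5 IQR of the hinges.
  Quartile conventions differ across software; box summaries from other
  tools may differ slightly.
* **Set comparisons**: when one input set contains the other (including
  the default proteome background), the background is disjointified
  (`set2 \ set1`) before both tests, keeping the per-stratum 2x2 margins
  valid. Partially overlapping sets are rejected rather than guessed at.
  Missing IDs are always reported alongside the results. Significance
  stars (`*`, `**`, `***` at 0.05, 0.01, 0.001) are a reporting
  convention only.

## The simulator: what it does and does not emulate

`simulate_tree()` joins random lineages under strictly decreasing ages
(uniform 20–150 mya increments per join, leaves at 0), optionally with one
polytomy. `simulate_families()` samples an origin node per family
(uniform by default), then loses each branch below the origin
independently with probability `loss_prob`; extinct families are
regenerated. Seeds are mandatory and recorded, and the caller's RNG state
is left untouched.

Because loss is the only source of homoplasy and there is no regain, the
true history is always Dollo-consistent: Dollo reconstruction recovers
every origin exactly at `loss_prob = 0`, and its error at positive loss
rates is a clean measure of how patchy profiles mislead the MRCA rule.
The simulator does **not** emulate: family databases built from sequence
similarity (no false merges/splits between families), horizontal
transfer or regain, copy-number dynamics, correlated loss across related
branches, or non-uniform origin preferences. Passing tests on these
fixtures therefore validate the algorithms and their implementations, not
the biological accuracy of any particular family database.

The test and acceptance problem sizes — 500 random instances for the
Wagner/brute-force equivalence on trees of up to 8 leaves, 1,000 families
on 16-leaf trees for ordering and recovery properties, 5,000 replicates
for null calibration, every 2x2 table up to total 40 for the Fisher
oracle — were chosen so the full suite exercises each property at scales
where the exhaustive oracles are still cheap.

## Degenerate inputs and edge cases

Single-leaf trees parse (the analysis step rejects them with a clear
message, since there is no internal structure to date). All-absent
presence rows, empty protein lists, constant inputs to the correlation,
and a background that disjointifies to nothing are all structured errors,
never silent results. Proteins absent from the family database are dated
to their own leaf (age 0) and flagged `no_family`, mirroring the
convention for proteins without predicted domains, so downstream analyses
can exclude them explicitly.

## Limitations

* Ages are only as good as the tree and the family partition; both are
  inputs, not inferences. Different family databases encode different
  notions of relatedness and will shift age distributions.
* Origin ages are lower bounds attached to the child node of the origin
  branch; tools that attach the parent node's date instead will report
  means offset by a per-stratum constant.
* The pipeline targets clades where horizontal transfer is rare;
  transfer-aware reconstruction is out of scope.
* No explicit ancestral genome content is reported — labelings exist
  internally, but the supported outputs are per-protein ages, profiles,
  and the analyses built on them.
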