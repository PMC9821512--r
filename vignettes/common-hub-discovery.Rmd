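---
title: "Common-hub discovery in disease PPI networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Common-hub discovery in disease PPI networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hubseeker` asks a specific network question: given six curated sets of
disease-associated proteins and a quantitative readout of how a perturbation
shifts the neuronal proteome, is there a small set of *intermediate* proteins
— not themselves disease genes — that connect unusually many members of all
six sets in the protein–protein interaction network? This vignette documents
the models behind each stage, the parameters that matter, and the choices we
made where the design was genuinely open.

## The proteomics model

The quant table holds one row per protein: a peptide-evidence count and four
control plus four treated replicate intensities. Two filters define the
high-quality subset:

* **Peptide evidence** (`min_peptides`, default 2): the standard two-peptide
  identification rule.
* **Replicate presence** (`min_present`, default 3 of `n_replicates` = 4):
  a protein must be quantified in at least three of four replicates. The rule
  as usually stated is ambiguous about whether it applies per condition or
  pooled; we apply it **per condition**, the stricter reading, because a
  protein quantified 4/4 in control but 1/4 in treated has no trustworthy
  fold change. Both knobs are configurable.

Both filters only remove rows, are idempotent, and commute — properties the
test suite asserts rather than assumes.

The ranked score is `log2(mean treated / mean control)` over present
replicates: **ratio of means**, not mean of ratios, because with up to one
missing replicate per condition the ratio of means uses every observed cell
without pairing assumptions. Missing intensities (recorded as empty or zero
cells) are excluded from means and never imputed; imputation would be an
additional modelling commitment the data do not force. Ties in the ranked
list break lexicographically by ID so that output is a pure function of
input.

## Cutoff-free enrichment

All quantified proteins contribute to enrichment — no fold-change or p-value
gate. For a set of size $N_S$ in a ranked universe of size $N$, walking down
the list the running sum gains $|s_i|^p / \sum_{hits} |s_j|^p$ at members and
loses $1/(N - N_S)$ at non-members; the enrichment score is the extremum by
absolute value. `weight_exponent` $p$ defaults to 1 (the weighted statistic);
$p = 0$ reduces to the classical Kolmogorov–Smirnov form, which is what our
hand oracles and the two-sample KS identity test exercise.

Because no sample-level data survive to this stage (the ranked list is the
interface), the only available null is **gene-label permutation**: random
member sets of matched size. With `n_perm` permutations the p-value is
$(1 + \#\{|ES_{null}| \ge |ES_{obs}|\})/(1 + n_perm)$ — the +1 pseudocount
keeps p in $(0, 1]$ and makes $1/(n_{perm}+1)$ the smallest attainable value.
The normalised score divides by the mean $|ES_{null}|$ of the same sign.
Per-set permutation seeds are derived by hashing the set ID with the run
seed, so results are independent of collection order. Sets are clipped to
the ranked universe and kept only within `min_set_size` 5 to `max_set_size`
500 — standard enrichment hygiene; a set equal to the whole universe has no
defined score and is rejected. Multiplicity is controlled with
Benjamini–Hochberg across the scored sets.

The enrichment map places significant sets (q ≤ `q_cutoff`, default 0.1) as
nodes and connects pairs whose overlap coefficient
$|A \cap B| / \min(|A|, |B|)$ reaches `overlap_cutoff` (default 0.25),
storing the shared-member count that a drawing encodes as edge thickness.
The overlap coefficient (rather than Jaccard) is the convention for
enrichment maps because it keeps nested set pairs visible.

## Subnetwork expansion and hub ranking

A disorder subnetwork is the induced subgraph on all nodes within
shortest-path distance ≤ `depth` (default 2) of the seed set, with roles
recording exact distances. We read "expand by up to two neighbors" as a
distance-≤2 ball; iterating first-neighbor expansion twice yields the same
node set, so the two readings coincide for nodes (the tests check distances
explicitly). Combining subnetworks re-induces the node union on the
reference, which restores interactions bridging two disorder neighborhoods —
exactly the edges a common hub needs.

Candidates for common hubs must (a) be non-seed ("intermediate") nodes and
(b) appear in at least `min_disorders` subnetworks — default all six, since a
"common" hub shared by only some disorders is a weaker claim; the knob is
exposed. Ranking is by **degree in the combined network** (the most connected
node), with normalized betweenness and then ID as tie-breaks; betweenness is
also reported because connector nodes that bridge communities can be
betweenness-prominent before they are degree-prominent. A `rank_key` option
allows betweenness-first ranking; per-disorder rank aggregation can be built
from the per-disorder `centrality_stats()` tables. Betweenness is the
normalized shortest-path count ($2B/((n-1)(n-2))$ in the scoped graph) and is
checked against an exhaustive path-enumeration oracle on small random graphs.

## The random-seed specificity null

The control re-runs the identical expansion with `n_random_seeds` = 80
proteins drawn uniformly from the network minus the disease seeds,
`n_iterations` times. The default statistic per iteration is the **maximum
within-subnetwork degree** (`top1_degree`), compared with the observed hub's
combined-network degree: it asks *"does a random seed selection ever produce
a hub as strongly connected as the one we observed?"*, which is the question
the random control answers.

We also implement the hub's degree-rank percentile (`rank_percentile`) but do
not default to it, for a power reason worth recording. The hub's rank within
a subnetwork is driven by its induced degree, and under reseeding every
node's induced degree scales by roughly the same ball-coverage factor — so a
node that ranks first in the real analysis tends to rank first under any
reseeding, and the percentile statistic barely moves. The top-1 degree
statistic does not have this defect: under random seeds only a coverage
fraction of the hub's partners is included, so the null maximum sits well
below the observed value unless a random seed happens to fall adjacent to
the hub.

That adjacency event also sets the null's floor: its per-iteration
probability is about $n_{seeds} \cdot d_{base}/|pool|$, where $d_{base}$ is
the hub's degree outside the disease sets. This is why the synthetic
reference defaults to 10,000 nodes — the scale of a curated mammalian
interactome — rather than something smaller: with a pool of only ~1,500
proteins the floor is ~0.15 and no implementation could call the hub
specific, while at interactome scale the floor is ~0.03. Inside the null
loop, the distance-≤2 ball and within-ball degrees are computed with sparse
adjacency mat-vec products; a test verifies this path against
`expand_subnetwork()` node-for-node and degree-for-degree.

## What the generators emulate — and what they do not

`generate_ppi()` offers preferential attachment (default, scale-free like
curated interactomes), Erdős–Rényi, and a duplication–divergence model.
`plant_hub()` samples six disjoint seed sets (default sizes
78/118/46/39/124/60; a pairwise-overlap parameter, default 0, allows shared
disease genes), picks a low-degree node as the connector so that its signal
comes from the planted wiring alone, and adds `links_per_set` = 50 edges into
each set — a connectivity comparable to well-connected chromatin regulators,
and safely above the ~180 maximum background degree of a 10,000-node
preferential-attachment graph. Decoy hubs (40 links into a single set) are
planted so that common-hub detection is distinguishable from plain degree
ranking. Edges are only added, never removed.

Quant intensities are log-normal around a per-protein baseline with a CV
parameter; missingness is completely at random; peptide counts are
1 + Poisson. Real label-based proteomics has intensity-dependent missingness,
batch structure, and shared-peptide ambiguity — none of which the generator
reproduces, so passing tests demonstrate the *logic* of the filters and
ranking, not robustness to those artifacts. Likewise the multi-omic
generators plant exact concordant/bivalent/responsive fractions with draws
strictly on the correct side of each threshold; they validate rule
application, not biology. No spectra, reads or ChIP peaks are simulated.

## Numerical and interface choices

* All threshold comparisons are **strict** (`FPKM > 1.2`, `p < 0.05`,
  `|log2FC| > 0.25`), matching how such rules are printed; boundary cases are
  pinned in tests.
* Hypergeometric overlap p-values use the exact upper tail (`phyper`); the
  default universe for an overlap test is the intersection of the two
  assays' gene universes, since counting genes unmeasurable in one assay
  inflates significance.
* Gene IDs match by exact string; no ortholog mapping.
* Every stochastic function takes an explicit `rng_seed` and is a pure
  function of it; the pipeline writes a manifest (config echo, config hash,
  MD5 of every input and output) and reruns byte-identically.
* Degenerate inputs have defined behaviour: empty enrichment maps are empty
  results, an all-seed network yields an empty hub report with a warning,
  zero mapped seeds or an all-missing condition are hard errors.

## Problem sizes

The shipped demo and the acceptance checks run at the study's operating
conditions: 10,000-node reference networks, the full 465-protein seed
complement, 1,000-protein quant tables, 1,000 null iterations and 1,000
permutations; hub-recovery properties are established over 50 independently
generated networks, enrichment calibration over 500 null sets at 200
permutations, and oracle equivalences over hundreds of exhaustive small
cases.

## Known limitations

Edges are unweighted — confidence-scored interactomes are reduced to
presence/absence. The gene-label permutation null ignores inter-gene
correlation, which in real data inflates enrichment significance; sample
permutation would require replicate-level data that the ranked-list
interface deliberately abstracts away. The specificity null redraws seeds
uniformly; degree-matched redrawing would be stricter and is not
implemented. And the synthetic truth is a single connector — overlapping or
competing multi-hub architectures are outside what the recovery guarantees
cover.
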