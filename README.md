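# hubseeker

Neurological disorders such as Alzheimer's, Parkinson's, Huntington's, ALS,
autism-spectrum disorder and epilepsy each come with a curated set of
disease-associated proteins. A recurring question in systems biology is
whether a perturbation — here, the ketone body 3-hydroxybutyrate acting on
neuronal cells — converges on a small number of *common hub* regulators that
sit between several of those disease protein sets in the protein–protein
interaction (PPI) network. `hubseeker` implements that integrative analysis
as a tested, reusable R pipeline, together with a synthetic-data module that
plants a known connector so every stage can be validated end to end.

## What it computes

**Proteomics quantification.** A two-condition (4 + 4 replicate) protein
quant table is filtered to proteins with ≥ 2 peptides and quantification in
≥ 3 of 4 replicates in both conditions, then summarised into a ranked list
scored by `log2(mean treated / mean control)` — no significance cutoff, so
every quantified protein contributes to enrichment.

**Cutoff-free gene-set enrichment.** For a gene set *S* in a ranked universe
of *N* genes, the weighted Kolmogorov–Smirnov running sum increments at hits
by `|score|^p / Σ_hits |score|^p` and decrements at misses by `1/(N − N_S)`;
the enrichment score ES is the extremum by absolute value. Significance is a
gene-label permutation null (`p = (1 + #{|ES_null| ≥ |ES_obs|}) / (1 +
n_perm)`), with BH control across sets, and significant sets are arranged in
an enrichment map whose edges carry shared-member counts and overlap
coefficients `|A∩B| / min(|A|,|B|)`.

**PPI hub discovery.** Each disorder seed set is mapped onto a reference
interactome and expanded to all nodes within shortest-path distance ≤ 2
(induced subgraph). Subnetworks are ranked by degree and normalized
betweenness, combined by re-inducing the union on the reference, and
candidate common hubs are *intermediate* (non-seed) nodes present in all six
subnetworks, ranked by combined-network degree. Specificity of the top hub is
tested by an empirical null: redraw 80 random seed proteins, re-expand with
identical parameters, and ask how often the random subnetwork contains a hub
as strongly connected as the observed one
(`p = (1 + #{null ≥ observed}) / (1 + n_iterations)`).

**Multi-omic integration.** Sign-concordant genes across RNA and protein fold
changes; bivalent-chromatin calls (H3K4me3 *and* H3K27me3 FPKM > 1.2, strict);
transcriptionally responsive calls (p < 0.05, strict); the volcano-style DE
filter (p < 0.05 and |log2FC| > 0.25); and upper-tail hypergeometric overlap
tests between any two calls.

## Worked example

```r
library(hubseeker)

demo <- make_demo("demo", rng_seed = 1)      # synthetic inputs + config.yaml
res  <- run_pipeline(demo$config_path, "results")
glance(res$hub_report)
```

```
# A tibble: 1 × 4
  n_candidates top_hub top_degree empirical_p
         <int> <chr>        <int>       <dbl>
1           20 P7198          287      0.0260
```

`P7198` is exactly the planted connector (`demo$truth$hub_id`): it links 50
members of each of the six disorder seed sets (sizes 78/118/46/39/124/60),
tops the combined-network degree ranking at 287, and only ~2.6% of random
80-seed networks produce any hub that strongly connected. The ranked
candidates show how sharply it separates from the scale-free background:

```
  id    n_disorders_present combined_degree combined_betweenness
1 P7198                   6             287               0.246
2 P0006                   6             123               0.0812
3 P0005                   6             116               0.0740
```

The run log audits every retention decision, e.g.

```
quant: peptide filter (>= 2) 1000 -> 853
quant: replicate filter (>= 3/4 both conditions) 853 -> 829
enrich: scored 15 of 15 sets; 3 at q <= 0.1
network: combined subnetwork 6817 nodes / 13228 edges
integrate: 77 up / 73 down concordant; 100 bivalent, 100 responsive, overlap 20 (p = 0.5489)
```

and the two planted signal gene sets lead the enrichment table (`LOADED_1`,
`LOADED_2`, q ≈ 0.0075). Every result type has `tidy()` / `glance()` methods
and an `autoplot()` view (`plot_running_sum()` for single sets, circular
enrichment-map layout, degree-vs-betweenness hub scatter, null histogram).

A thin command-line wrapper lives at `inst/scripts/hubseeker.R`
(`demo` and `run-all` subcommands).

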