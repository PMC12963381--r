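# scResilience

Tools for asking whether specific cortical neuron subtypes are
*resilient* to advancing neurodegenerative pathology: preserved in
relative abundance across donors staged as low / intermediate / high
pathology, and corroborated in their transcriptomic response by several
independent statistical engines. The package re-implements, as tested
and reusable functions, the analysis core of such a study:

* **Compositional testing** — Bayesian Dirichlet-multinomial regression
  of donor-level cell-type counts,
  `counts ~ group + sex + APOE + assay + age`, with an automatically
  selected stable reference type, a spike-and-slab prior yielding a
  posterior inclusion probability (PIP) per effect, the credibility rule
  *PIP > 0.95 and |log2FC| > 0.1*, a loss-only stress-test variant with
  a half-normal prior on β ≤ 0, and an independent beta-regression
  (logit link) check per cell type.
* **Consensus differential expression** — a hurdle (two-part) mixed
  model with donor random intercepts, a 100-iteration half-sample
  bootstrap requiring the same significant direction in ≥ 20/100
  iterations, and a pseudobulk negative-binomial Wald test on donor sums
  (≥ 20 expressing nuclei, median-of-ratios offsets). "High-confidence"
  genes are mixed-model hits corroborated by the bootstrap, the
  pseudobulk test, or top-50 kME co-expression hub membership.
* **Co-expression modules** — metacell aggregation (k = 25, minimum 50
  cells per group), soft-thresholded unsigned adjacency, topological
  overlap, constant-height tree cut with eigengene merging, kME hub
  ranking (top 10 / top 50), and bootstrap module stability.
* **Spatial ensemble annotation** — heuristic marker scoring, graph
  (Leiden) clustering with marker labeling, and kNN label transfer in a
  reference PCA space (15 PCs, k = 20), combined by plurality voting
  with a strict consensus-confidence gate of 0.5; neuronal subtypes are
  transferred only to cells with more than 50 transcripts.
* **Calcium events** — dF/F0 with a rolling 10th-percentile 10-s
  baseline, strict 0.2 threshold-crossing detection with debounce, and
  events/min averaged at the well level.
* **Synthetic cohorts** — `simulate_cohort()`, `simulate_spatial()` and
  `simulate_calcium()` generate donor-structured negative-binomial
  counts with dropout, Dirichlet-multinomial compositional shifts,
  planted DE genes and co-expression modules, layered spatial sections,
  and event-bearing fluorescence traces — with full ground truth, so
  every stage is validated by calibration and recovery experiments
  rather than fixtures.

## Worked example

Simulate a 60-donor cohort in which cell type Ex1 loses 1.5 log2 units
of relative abundance between the low and high pathology groups, then
test composition:

```r
library(scResilience)

cfg <- cohort_config(n_donors_per_group = 20, n_celltypes = 8,
                     n_cells_per_donor = 2000,
                     comp_log2fc = c(-1.5, rep(0, 7)), seed = 4)
ct <- simulate_composition(cfg)

post <- fit_dirichlet_multinomial(ct, reference = "auto",
                                  mcmc = list(chains = 4, warmup = 1000,
                                              samples = 1000, seed = 2))
credible_effects(post)
#>   type                   covariate     pip     log2FC credible
#> 1  Ex1 pathology_groupintermediate 0.97675 -0.7741021     TRUE
#> 2  Ex1         pathology_grouphigh 1.00000 -1.6010412     TRUE
```

The planted type — and only the planted type — is flagged credible, at
both stages: the intermediate group sits at about half the planted shift
(−0.77 vs −0.75 true) and the high group at the full shift (−1.60 vs
−1.50 true, PIP 1.0). The loss-only variant
(`constrain_nonpositive = TRUE`) fits the same design with every
coefficient restricted to β ≤ 0 and, by construction, never reports an
expansion.

Downstream, `fit_hurdle_mixed()`, `bootstrap_de()` and
`pseudobulk_de()` feed `consensus_high_confidence()`;
`build_metacells()`, `detect_modules()` and `compute_kme()` produce hub
lists; `heuristic_classify()`, `cluster_annotate()`,
`knn_label_transfer()` and `ensemble_vote()` annotate spatial sections;
`compute_dff()`, `detect_events()` and `summarize_rates()` quantify
calcium traces. The methods vignette
(`vignettes/resilience-pipeline.Rmd`) documents every model, default and
deliberate design choice.

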