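# metasort

Statistical and annotation pipeline for untargeted LC-MS metabolomics of
**rare, flow-sorted cell populations** — experiments in which a few thousand
cells (hematopoietic stem cells, circulating tumor cells, ...) are sorted
directly into extraction solvent, so that peak intensities are low, many
metabolites sit near the detection limit, and every sorted cell carries a
droplet of saline sheath fluid that contributes background signal.

The package is for analysts who already have per-metabolite peak areas
(integrated from a curated metabolite library) and need the downstream
statistics: deciding what is real signal versus sheath-fluid background,
normalizing and testing small paired/batched designs, and interpreting the
hits at the pathway level.

## What it computes

For a metabolite × sample intensity matrix with zeros encoding
"not detected":

* **Above-background detection.** Each metabolite's cell samples are
  compared against blank (sheath fluid) samples with a Gaussian GLM on
  `log2(x + 1)`-transformed, non-normalized data. With BH-adjusted
  FDR `q_m` and fold change `FC_m = 2^(beta_m)` (the fitted group
  coefficient), a metabolite is above background iff `FC_m > 2` and
  `q_m < 0.05` (both strict).
* **Differential abundance.** Cell-vs-cell comparisons use half-minimum
  imputation (zeros replaced by half the metabolite's minimum nonzero
  value), relative log expression (RLE, median-of-ratios) size-factor
  normalization, a log2 transform, then a per-metabolite Gaussian GLM
  `log2 y ~ group (+ pair) (+ batch)` with pairing (same animal) and batch
  (independent experiment) as fixed-effect covariates. Significance uses the
  same strict `FC > 2`, `FDR < 0.05` rule over the universe of metabolites
  above background.
* **Pathway enrichment.** One-sided hypergeometric over-representation of
  the significant set within each GMT pathway, BH-adjusted, enriched at
  `FDR < 0.01`.
* **Library matching.** Observed features are matched to a metabolite
  library by mass accuracy (`|ppm| <= 5`, where
  `ppm = 1e6 (m_obs - m_theo)/m_theo`), retention time (±0.5 min), and
  agreement of the observed M/M+1/M+2 isotopologue envelope with the
  pattern predicted from the elemental formula (cosine ≥ 0.95). Candidate
  library features must also pass an inclusion test: retention times
  aligned across samples and intensity increasing with cell number
  (Spearman ρ ≥ 0.8).
* **Protocol concordance.** PCA of samples, Spearman + OLS regression of
  log2 fold changes between two analyses, overlap of significant sets, and
  per-group above-background counts (mean ± SD over replicate runs).
* **Simulation.** A generator that emulates sorted-cell data — lognormal
  baselines spanning 1e4–1e9 counts, blank background on a subset of
  metabolites, logistic intensity-dependent dropout, planted fold changes,
  batch and pairing effects — so every stage is testable against known
  truth.

## Worked example

```r
library(metasort)

sim   <- simulate_experiment(sim_config(seed = 42))   # 200 metabolites, 2 groups x 5, 5 blanks
calls <- above_background(sim$matrix, sim$meta)
sum(calls$above_background)
#> [1] 184

res <- differential_abundance(sim$matrix, sim$meta, ref = "A", test = "B",
                              universe = calls$metabolite_id[calls$above_background])
head(res[order(res$fdr), c("metabolite_id", "log2_fc", "fold_change",
                           "fdr", "significant", "direction")], 3)
#>     metabolite_id log2_fc fold_change      fdr significant direction
#> 171       met_185    3.77      13.623 2.72e-05        TRUE        up
#> 113       met_124   -2.80       0.143 4.90e-05        TRUE      down
#> 24        met_025    4.12      17.397 5.71e-05        TRUE        up

count_significant(res, 2)    # FC > 2,   FDR < 0.05
#> [1] 16
count_significant(res, 2.5)  # FC > 2.5, FDR < 0.05
#> [1] 14
```

Of 200 simulated metabolites, 184 clear the sheath-fluid background; the
comparison of groups B vs A then finds 16 significant metabolites (14 beyond
2.5-fold), recovering 16 of the 20 planted effects — the misses are planted
fold changes near the detection threshold. `log2_fc` is the fitted group
coefficient (a log2 ratio of geometric means), `fold_change = 2^log2_fc`,
and `direction` reads off its sign for significant metabolites.

A command-line wrapper over the same functions ships in
`inst/cli/metasort.R` with `detect`, `diff`, `enrich`, `match` and
`simulate` subcommands; every run writes a JSON manifest (inputs + MD5,
parameters, seed, package version) sufficient to reproduce it.

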