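---
title: "Statistical methods for sorted-cell metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for sorted-cell metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metasort)
```

# The measurement problem

Metabolomic profiling of rare cell populations works at the edge of what an
LC-MS instrument can see. A sorted sample of 10,000 cells yields peak areas
spanning roughly four orders of magnitude (1e4–1e9 ion counts), and three
features of the data dominate the statistics:

1. **Background signal.** Each sorted cell arrives with 1–3 nl of saline
   sheath fluid; its salts and contaminants produce peaks of their own. A
   metabolite is only interpretable if its cell-sample signal clearly
   exceeds the signal in blank sheath-fluid samples.
2. **Dropout.** Low-intensity peaks fall below the integration limit and
   are recorded as 0. Zeros are censored values, not true absences.
3. **Small, structured designs.** Typical experiments have 3–8 replicates
   per condition, often paired (cells and comparator sorted from the same
   animal) and spread over independent experiments (batches).

`metasort` implements the full decision chain for such data. This vignette
records the model, the parameter choices, and the design decisions taken
where more than one reasonable convention exists.

# Above-background detection

Cell samples are compared to blank samples per metabolite on
$\log_2(x + c)$-transformed, **non-normalized** data (default pseudo-count
$c = 1$, which maps zeros to 0 on the log scale). Normalization is
deliberately skipped here: size factors estimated from blanks would be
dominated by background chemistry, and the contrast of interest is exactly
the raw signal difference. No imputation is applied either — zeros in
blanks are evidence of absence of background, which is what the test should
see.

The test is a Gaussian generalized linear model (an ordinary linear model)
of the transformed intensity on a cell-vs-blank indicator; the two-sided
p value uses the t distribution at the residual degrees of freedom. The
fitted coefficient $\beta$ is a log2 ratio of (pseudo-counted) geometric
means, and the fold over blank is $2^\beta$. After Benjamini–Hochberg
adjustment across metabolites, a metabolite is **above background** iff

$$\mathrm{FC} > 2 \quad\text{and}\quad \mathrm{FDR} < 0.05,$$

with both inequalities strict: a fold change of exactly 2.000 does not
qualify. The thresholds are the field's reporting convention and are
configurable in `analysis_config()`.

# Differential abundance between cell populations

Cell-vs-cell comparisons run the pipeline

*half-minimum imputation → RLE normalization → log2 → per-metabolite GLM →
BH*.

**Half-minimum imputation** replaces each metabolite's zeros with half of
its minimum nonzero value, computed across **all** samples in the
comparison rather than per group — a per-group minimum would manufacture
fold changes for metabolites detected in only one group. Rows observed in
no sample cannot be imputed; they are flagged and excluded.

**Ordering.** Imputation precedes normalization. RLE's median-of-ratios
estimator needs a positive reference row set; imputing first keeps every
metabolite usable instead of silently dropping any row with a zero. The two
operations nearly commute for the well-detected majority of metabolites
that drive the median, so the order matters little in practice, but a fixed
convention is needed and this one maximizes the information entering the
size factors.

**RLE normalization** computes, per sample, the median over metabolites of
the ratio to the across-sample geometric mean, then rescales the factors to
geometric mean 1 so the data keep their original intensity scale. The
estimator assumes the majority of metabolites are not differential — the
standard assumption behind median-of-ratios normalization. An alternative
normalizer, `mean_equalize()`, scales samples so their average intensity
over the above-background metabolites is equal; it is provided for
workflows stated in those terms, with RLE as the default throughout.

**The test** is again a Gaussian GLM on the log2 scale,
`log2 y ~ group + pair + batch`, with pairing and batch as fixed-effect
indicator covariates when requested. With no covariates this is exactly the
pooled-variance two-sample t-test; with a complete pair covariate it is
exactly the paired t-test (both identities are verified in the test suite
to 1e-10). Random-effect formulations were deliberately not used: with 3–8
replicates per group there is too little replication to estimate variance
components, and fixed effects keep the model identical to its classical
special cases.

**Fold change** is defined as $2^{\hat\beta}$ where $\hat\beta$ is the
fitted group coefficient — a ratio of geometric means, self-consistent with
the model actually fitted, rather than a ratio of arithmetic means computed
off-model.

**The FDR universe** is the set of metabolites above background in at least
one of the two conditions (`detection_universe()`). Testing metabolites
that are indistinguishable from blank everywhere would only dilute the BH
correction with uninformative tests.

**Degenerate fits.** When the residual variance is numerically zero the t
statistic is undefined. The package resolves this by convention: zero
effect with zero residual variance gives $p = 1$ (identical groups are no
evidence of change), nonzero effect gives $p = 0$; both are flagged
`degenerate`. Rank-deficient designs (e.g. batch confounded with group)
are an error naming the collinear term, not a silent drop.

# Pathway enrichment

Over-representation uses the one-sided hypergeometric tail (Fisher exact
upper tail): with `n_path` of the `n_universe` tested metabolites in a
pathway and `n_sig` significant, the p value is $P(X \ge \text{overlap})$.
The universe is the tested universe, not the whole library — a metabolite
that never cleared background had no chance to be called significant and
must not inflate the null. Pathways with fewer than 2 universe members are
skipped (configurable); a one-member "set" cannot be meaningfully enriched.
BH adjustment runs across the tested pathways, with enrichment called at
FDR < 0.01. Pathway collections are plain GMT files, so results are pinned
to an editable, versionable artifact rather than a live database query.

# Library matching

A library entry carries a formula, adduct, polarity, theoretical m/z and
retention time. Matching criteria, all configurable via `analysis_config()`:

* **Mass accuracy:** $|\mathrm{ppm}| \le 5$, inclusive at the boundary
  ("within 5 ppm" is read as $\le$). Ion m/z is the neutral monoisotopic
  mass ± one **proton** (1.007276 Da) for [M+H]+/[M−H]−; using the hydrogen
  atom mass instead is a classic 0.55 mDa error the package avoids.
* **Retention time:** within 0.5 min. No inter-run RT drift correction is
  applied; the tolerance absorbs ordinary drift on a stable gradient.
* **Isotope pattern:** cosine similarity ≥ 0.95 between the observed
  M/M+1/M+2 envelope and the pattern predicted from the formula. The
  prediction convolves each element's natural isotope distribution
  (embedded IUPAC 2021 table; C, H, N, O, P, S, Cl, Na, K) over its atom
  count, aggregates by nominal mass shift, and normalizes to the
  monoisotopic peak. The implementation uses exponentiation-by-squaring in
  the truncated convolution algebra; tests verify it against an exhaustive
  atom-by-atom convolution to 1e-6.

`match_feature()` reports every candidate within **twice** the tolerances
so near-misses are visible with their rejection reasons ("mass",
"retention_time", "isotope_pattern"), sorts by $|\mathrm{ppm}|$ with
$|\Delta RT|$ as tie-break, and accepts only candidates inside all windows.

**Inclusion testing** operationalizes two qualitative library-building
rules. "Peaks align in all samples" becomes max–min RT spread ≤ the RT
tolerance over samples where the feature is detected. "Intensity increases
with cell number" becomes Spearman $\rho \ge 0.8$ between cell count and
intensity — rank-based, hence robust to the lognormal intensity scale and
invariant to rescaling; 0.8 tolerates a single rank inversion in a 5-point
titration while rejecting flat contaminant profiles. Both cutoffs are
configurable. `restrict_library()` then narrows a high-abundance library to
the subset actually detectable in low-abundance samples; it is
count-agnostic and order-preserving.

# Concordance analytics

For comparing two protocols analysed with the same contrast:
`fc_concordance()` reports the Spearman correlation and an OLS regression
of B's log2 fold changes on A's over their common metabolites (optionally
restricted to metabolites significant in A), plus significant-set overlaps
in both directions; `direction_agreement()` counts matching fold-change
signs among a chosen id set; `pca_scores()` runs PCA on per-metabolite
mean-centered data (intended input: imputed, normalized, log2 data);
`count_above_background_by_group()` aggregates detection counts as
mean ± sample SD across replicate runs. OLS (rather than orthogonal
regression) matches the convention of regressing one protocol's estimates
on the other as plotted; the Spearman r is symmetric regardless.

# The simulator

`simulate_experiment()` generates data with the structure the pipeline
assumes:

| parameter | default | meaning |
|---|---|---|
| `n_metabolites` | 200 | detected features in a typical run |
| `n_per_group`, `n_blanks` | 5, 5 | replicates per condition / blanks |
| `baseline_log10_mean_range` | [4, 9] | per-metabolite baseline span |
| `biological_cv` | 0.25 | replicate CV; lognormal noise with $\sigma_{\log_2} = \sqrt{\ln(1+CV^2)}/\ln 2$ |
| `blank_fraction`, `blank_level` | 0.3, 0.05 | share of metabolites with background signal, at 5 % of cell level |
| `dropout_midpoint`, `dropout_steepness` | 1e4, 2 | logistic detection curve in log10 intensity |
| `frac_differential` | 0.1 | planted differential share |
| `effect_fold_range` | [2, 16] | planted fold changes (random sign) |
| `batch_sd_log2`, `pair_sd_log2` | 0, 0 | additive log2-scale effects when enabled |

Dropout is modeled as a logistic detection probability in log10 intensity —
the simplest mechanism that reproduces the empirical fact that zeros
concentrate at low intensity. Blank background is per-metabolite (a
contaminated subset) rather than a global additive floor, matching how
sheath-fluid chromatograms actually look. Batch and pair effects are
additive on the log2 scale, i.e. multiplicative on raw intensities,
consistent with the fixed-effect covariates in the GLM. All randomness
derives from R's default Mersenne-Twister generator under a single
configuration seed, so outputs are bit-reproducible.

`simulate_titration()` produces cell-number series (default 10k–100k cells)
with intensity proportional to cell count, plus optional flat contaminant
features for exercising the inclusion test. `simulate_blank_contamination()`
produces blank-only matrices with increasing background for testing that
detection counts shrink as background grows.

**What the simulator does not emulate:** correlated metabolites (pathway
co-regulation), heavy-tailed or intensity-dependent variance beyond the
lognormal, retention-time drift, ion suppression as a function of
co-eluting load, and integration errors. Passing tests therefore
demonstrate the statistical machinery is correct under the stated
generative model, not that real data satisfy that model.

# Numerical conventions

* Zeros encode "not detected" throughout; file readers map empty cells to 0
  with a warning and reject negative, NaN or infinite intensities with the
  offending cell named.
* Canonical orientation is metabolites × samples; transposed files load via
  an orientation flag and the two reads are verified identical.
* Significance inequalities are strict exactly as printed: FC > 2,
  FDR < 0.05, enrichment FDR < 0.01; the mass window is inclusive
  ($\le 5$ ppm).
* BH adjustment is the step-up procedure (via `stats::p.adjust`), verified
  in tests against a from-scratch implementation of the definition.
* Result tables are written at full precision (17 significant digits) so
  read-back equals written values to better than 1e-9 relative.
* I/O is delimited text (CSV/TSV sniffed from extension), GMT for pathway
  sets and JSON for configuration and run manifests.

# Problem sizes in the test suite

The suite exercises the pipeline at desk scale, chosen to keep the
statistics meaningful while the whole suite runs in well under a minute:
200 metabolites × 10 samples for operating-characteristic checks, 20
simulation seeds for the null false-call rate, 5 seeds × 20 planted 8-fold
effects for sensitivity and fold-change accuracy, 1000 random p-vectors for
the BH oracle, and exhaustive enumeration for hypergeometric universes up
to 15. `scripts/acceptance.R` recomputes the same quantities end-to-end at
an arbitrary seed.

# Known limitations

* The GLM assumes approximately lognormal intensities; count-model
  alternatives (e.g. compound-Poisson) are out of scope.
* No variance shrinkage across metabolites: with n = 3 per group, per-
  metabolite variance estimates are noisy and power is limited.
* Pathway enrichment ignores pathway topology and metabolite-set overlap.
* Library matching does not score MS2 spectra; identification confidence
  beyond mass/RT/isotope agreement must come from upstream curation.
* Metabolite identifiers are taken at face value; no HMDB/KEGG/ChEBI
  cross-mapping is performed.
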