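#' Simulation configuration for sorted-cell LC-MS intensity data
#'
#' Defaults describe a typical sorted-cell metabolomics experiment: ~200
#' detected metabolites, 5 replicates per condition and 5 sheath-fluid
#' blanks, lognormal peak intensities with per-metabolite baselines spanning
#' 1e4-1e9 counts, biological coefficient of variation 0.25, a subset of
#' metabolites carrying blank (background) signal, intensity-dependent
#' dropout near the detection limit, and an optional batch/pairing
#' structure. A tenth of the metabolites are differential with fold changes
#' between 2 and 16.
#'
#' @param n_metabolites,n_per_group,n_blanks Counts (all >= 1).
#' @param groups Two group labels (reference first).
#' @param baseline_log10_mean_range Range of per-metabolite baseline
#'   log10-intensities.
#' @param biological_cv Coefficient of variation of replicate intensities.
#' @param blank_fraction Fraction of metabolites with nonzero blank signal.
#' @param blank_level Blank signal level relative to the cell baseline.
#' @param dropout_midpoint Intensity (counts) at which detection probability
#'   is 0.5.
#' @param dropout_steepness Logistic slope per log10 decade of intensity.
#' @param frac_differential Fraction of metabolites with a planted effect.
#' @param effect_fold_range Range of planted fold changes (> 1; the sign of
#'   the log2 effect is randomized).
#' @param n_batches Number of independent experiments; samples are split
#'   evenly across them.
#' @param batch_sd_log2 SD of the per-batch additive shift on the log2 scale.
#' @param paired Whether samples are paired across groups (same animal).
#' @param pair_sd_log2 SD of the per-pair additive shift on the log2 scale.
#' @param seed Integer seed; all outputs are reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_metabolites = 200L,
                       n_per_group = 5L,
                       n_blanks = 5L,
                       groups = c("A", "B"),
                       baseline_log10_mean_range = c(4, 9),
                       biological_cv = 0.25,
                       blank_fraction = 0.3,
                       blank_level = 0.05,
                       dropout_midpoint = 1e4,
                       dropout_steepness = 2,
                       frac_differential = 0.1,
                       effect_fold_range = c(2, 16),
                       n_batches = 1L,
                       batch_sd_log2 = 0,
                       paired = FALSE,
                       pair_sd_log2 = 0,
                       seed = 1L) {
  stopifnot(
    n_metabolites >= 1L, n_per_group >= 1L, n_blanks >= 0L,
    length(groups) == 2L, !anyDuplicated(groups),
    length(baseline_log10_mean_range) == 2L,
    diff(baseline_log10_mean_range) >= 0,
    biological_cv > 0,
    blank_fraction >= 0, blank_fraction <= 1, blank_level >= 0,
    dropout_midpoint > 0, dropout_steepness > 0,
    frac_differential >= 0, frac_differential <= 1,
    length(effect_fold_range) == 2L, all(effect_fold_range > 1),
    n_batches >= 1L, batch_sd_log2 >= 0, pair_sd_log2 >= 0
  )
  structure(mget(names(formals(sim_config))), class = "sim_config")
}

# lognormal SD on the log2 scale implied by a coefficient of variation
cv_to_sdlog2 <- function(cv) sqrt(log(1 + cv^2)) / log(2)

#' Simulate a sorted-cell metabolomics experiment
#'
#' Draws a metabolite x sample intensity matrix with the structure of a
#' sorted-cell LC-MS run: per-metabolite lognormal baselines, planted
#' differential effects in the test group, additive batch and pair effects
#' on the log2 scale, blank samples carrying background signal for a subset
#' of metabolites, and a logistic detection curve that zeroes intensities
#' near the detection limit.
#'
#' @param config A [sim_config()].
#' @return List with `matrix` (an [intensity_matrix()]), `meta` (a
#'   [sample_meta()]), and `truth` - a list with `differential` (data.frame
#'   of planted ids and true log2 effects), `blank_signal_ids`,
#'   `baseline_log10`, and `n_dropout` (count of zeroed cells).
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nm <- config$n_metabolites
  met_ids <- sprintf("met_%03d", seq_len(nm))
  baseline_log10 <- stats::runif(nm, config$baseline_log10_mean_range[1L],
                                 config$baseline_log10_mean_range[2L])
  n_diff <- round(config$frac_differential * nm)
  diff_idx <- if (n_diff > 0) sample.int(nm, n_diff) else integer(0)
  effect_log2 <- numeric(nm)
  if (n_diff > 0) {
    folds <- stats::runif(n_diff, config$effect_fold_range[1L],
                          config$effect_fold_range[2L])
    effect_log2[diff_idx] <- log2(folds) * sample(c(-1, 1), n_diff,
                                                  replace = TRUE)
  }
  blank_ids <- met_ids[stats::runif(nm) < config$blank_fraction]

  n_cells <- 2L * config$n_per_group
  cell_ids <- sprintf("cell_%02d", seq_len(n_cells))
  blank_sample_ids <- if (config$n_blanks > 0) {
    sprintf("blank_%02d", seq_len(config$n_blanks))
  } else character(0)
  group <- rep(config$groups, each = config$n_per_group)
  batch <- rep_len(sprintf("batch%d", seq_len(config$n_batches)),
                   config$n_per_group)
  batch <- rep(batch, 2L) # matched batch layout across the two groups
  pair <- if (config$paired) rep(sprintf("animal%02d",
                                         seq_len(config$n_per_group)), 2L)
          else rep(NA_character_, n_cells)

  sdlog2 <- cv_to_sdlog2(config$biological_cv)
  batch_shift <- stats::rnorm(config$n_batches, 0, config$batch_sd_log2)
  names(batch_shift) <- sprintf("batch%d", seq_len(config$n_batches))
  pair_shift <- stats::rnorm(config$n_per_group, 0, config$pair_sd_log2)
  names(pair_shift) <- sprintf("animal%02d", seq_len(config$n_per_group))

  log2_base <- baseline_log10 * log2(10)
  m <- matrix(0, nm, n_cells, dimnames = list(met_ids, cell_ids))
  for (j in seq_len(n_cells)) {
    mu <- log2_base +
      (if (group[j] == config$groups[2L]) effect_log2 else 0) +
      batch_shift[[batch[j]]] +
      (if (config$paired) pair_shift[[pair[j]]] else 0)
    m[, j] <- 2^(mu + stats::rnorm(nm, 0, sdlog2))
  }
  blanks <- matrix(0, nm, length(blank_sample_ids),
                   dimnames = list(met_ids, blank_sample_ids))
  if (length(blank_sample_ids) > 0 && length(blank_ids) > 0) {
    bi <- match(blank_ids, met_ids)
    for (j in seq_along(blank_sample_ids)) {
      blanks[bi, j] <- 2^(log2_base[bi] + log2(config$blank_level) +
                            stats::rnorm(length(bi), 0, sdlog2))
    }
  }
  full <- cbind(m, blanks)
  # logistic detection: P(detect) rises with log10 intensity
  p_detect <- stats::plogis(config$dropout_steepness *
                              (log10(pmax(full, .Machine$double.xmin)) -
                                 log10(config$dropout_midpoint)))
  dropped <- stats::runif(length(full)) > p_detect
  full[dropped] <- 0

  meta <- sample_meta(data.frame(
    sample_id = c(cell_ids, blank_sample_ids),
    role = c(rep("cell", n_cells), rep("blank", length(blank_sample_ids))),
    group = c(group, rep("blank", length(blank_sample_ids))),
    batch = c(batch, rep(batch[1L], length(blank_sample_ids))),
    pair = c(pair, rep(NA_character_, length(blank_sample_ids))),
    stringsAsFactors = FALSE
  ))
  truth <- list(
    differential = data.frame(
      metabolite_id = met_ids[diff_idx],
      log2_effect = effect_log2[diff_idx],
      stringsAsFactors = FALSE
    ),
    blank_signal_ids = blank_ids,
    baseline_log10 = stats::setNames(baseline_log10, met_ids),
    n_dropout = sum(dropped)
  )
  list(matrix = intensity_matrix(full), meta = meta, truth = truth)
}

#' Simulate a cell-number titration series
#'
#' Per-feature intensities proportional to the number of cells in the
#' sample, with multiplicative lognormal noise and the same logistic
#' detection limit as [simulate_experiment()]. Optionally plants flat
#' "contaminant" features whose intensity does not scale with cell number -
#' these should fail the library [inclusion_test()].
#'
#' @param config A [sim_config()]; `n_metabolites`, `biological_cv`,
#'   dropout parameters and `seed` are used.
#' @param cell_numbers At least 3 cell counts (one sample per count).
#' @param n_flat Number of planted flat contaminant features.
#' @param rt_jitter_sd SD (minutes) of per-sample retention-time jitter.
#' @return List with `intensity` (features x samples), `retention_time`
#'   (same shape), `cell_numbers` (named by sample), and `truth` (a
#'   data.frame flagging flat features).
#' @export
simulate_titration <- function(config = sim_config(),
                               cell_numbers = c(10000, 20000, 30000,
                                                50000, 100000),
                               n_flat = 0L,
                               rt_jitter_sd = 0.02) {
  if (length(cell_numbers) < 3L) stop("need >= 3 cell numbers")
  set.seed(config$seed + 1L)
  nf <- config$n_metabolites
  ids <- c(sprintf("feat_%03d", seq_len(nf)),
           if (n_flat > 0) sprintf("flat_%02d", seq_len(n_flat)))
  n_all <- nf + n_flat
  samples <- sprintf("cells_%d", cell_numbers)
  # per-cell signal spans the configured baseline range at 10k cells
  per_cell_log10 <- stats::runif(n_all,
                                 config$baseline_log10_mean_range[1L],
                                 config$baseline_log10_mean_range[2L]) -
    log10(10000)
  sdlog2 <- cv_to_sdlog2(config$biological_cv)
  rt0 <- stats::runif(n_all, 1, 15)
  m <- matrix(0, n_all, length(cell_numbers),
              dimnames = list(ids, samples))
  rt <- matrix(NA_real_, n_all, length(cell_numbers),
               dimnames = list(ids, samples))
  flat <- grepl("^flat_", ids)
  for (j in seq_along(cell_numbers)) {
    scale_log10 <- ifelse(flat, log10(mean(cell_numbers)),
                          log10(cell_numbers[j]))
    mu <- (per_cell_log10 + scale_log10) * log2(10)
    m[, j] <- 2^(mu + stats::rnorm(n_all, 0, sdlog2))
    rt[, j] <- rt0 + stats::rnorm(n_all, 0, rt_jitter_sd)
  }
  p_detect <- stats::plogis(config$dropout_steepness *
                              (log10(pmax(m, .Machine$double.xmin)) -
                                 log10(config$dropout_midpoint)))
  dropped <- stats::runif(length(m)) > p_detect
  m[dropped] <- 0
  rt[m == 0] <- NA_real_
  list(intensity = m, retention_time = rt,
       cell_numbers = stats::setNames(cell_numbers, samples),
       truth = data.frame(feature_id = ids, flat = flat,
                          stringsAsFactors = FALSE))
}

#' Simulate blank matrices at increasing contamination levels
#'
#' Blank-only intensity matrices whose total background signal grows across
#' ordered contamination levels (e.g. drying protocols that concentrate
#' airborne contaminants). Useful for testing that above-background calls
#' shrink as background grows: the same cell signal cleared against a
#' noisier blank yields fewer calls.
#'
#' @param config A [sim_config()].
#' @param levels Multipliers (>= 0) applied to the blank signal, one matrix
#'   per level; at least 2 and ordered as supplied.
#' @return Named list of `intensity_matrix` objects, one per level.
#' @export
simulate_blank_contamination <- function(config = sim_config(),
                                         levels = c(0, 1, 4)) {
  if (length(levels) < 2L) stop("need >= 2 contamination levels")
  set.seed(config$seed + 2L)
  nm <- config$n_metabolites
  met_ids <- sprintf("met_%03d", seq_len(nm))
  blank_sample_ids <- sprintf("blank_%02d", seq_len(max(config$n_blanks, 2L)))
  baseline_log10 <- stats::runif(nm, config$baseline_log10_mean_range[1L],
                                 config$baseline_log10_mean_range[2L])
  contaminated <- stats::runif(nm) < config$blank_fraction
  sdlog2 <- cv_to_sdlog2(config$biological_cv)
  out <- lapply(levels, function(lev) {
    m <- matrix(0, nm, length(blank_sample_ids),
                dimnames = list(met_ids, blank_sample_ids))
    if (lev > 0) {
      bi <- which(contaminated)
      for (j in seq_along(blank_sample_ids)) {
        m[bi, j] <- 2^(baseline_log10[bi] * log2(10) +
                         log2(config$blank_level * lev) +
                         stats::rnorm(length(bi), 0, sdlog2))
      }
    }
    intensity_matrix(m)
  })
  names(out) <- paste0("level_", levels)
  out
}

#' Write a simulated experiment to disk
#'
#' Writes the intensity table, sample metadata and planted-truth table in
#' the same delimited formats the readers consume.
#'
#' @param sim Output of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    intensity = file.path(dir, "intensity.csv"),
    meta = file.path(dir, "samples.csv"),
    truth = file.path(dir, "truth.csv")
  )
  write_intensity_table(sim$matrix, paths[["intensity"]])
  write_sample_meta(sim$meta, paths[["meta"]])
  utils::write.table(sim$truth$differential, paths[["truth"]], sep = ",",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
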