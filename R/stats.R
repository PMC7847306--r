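#' Log2 transform with pseudo-count
#'
#' Elementwise `log2(x + pseudo_count)` of a raw intensity matrix. Used for
#' background comparisons, where zeros (not detected) are kept and the
#' pseudo-count maps them to 0 on the log scale.
#'
#' @param matrix A raw-scale `intensity_matrix`.
#' @param pseudo_count Nonnegative constant added before the log.
#' @return An `intensity_matrix` with `log_scale = TRUE`.
#' @export
log2p1 <- function(matrix, pseudo_count = 1) {
  if (pseudo_count < 0) stop("pseudo_count must be >= 0")
  if (is_log_scale(matrix)) stop("matrix is already on the log scale")
  im_like(log2(unclass(matrix) + pseudo_count), matrix, log_scale = TRUE)
}

#' Half-minimum imputation of undetected values
#'
#' Replaces zeros in each metabolite row by half of that metabolite's
#' minimum nonzero value across all samples in the matrix. Rows with no
#' nonzero value at all cannot be imputed; they are left unchanged and their
#' ids are recorded in the `undetected` attribute of the result.
#'
#' @param matrix A raw-scale `intensity_matrix`.
#' @return The imputed matrix; `attr(, "undetected")` lists all-zero rows.
#' @export
half_min_impute <- function(matrix) {
  if (is_log_scale(matrix)) stop("impute on the raw scale, before any log transform")
  m <- unclass(matrix)
  undetected <- character(0)
  for (i in seq_len(nrow(m))) {
    nz <- m[i, ] > 0
    if (!any(nz)) {
      undetected <- c(undetected, rownames(m)[i])
    } else if (!all(nz)) {
      m[i, !nz] <- min(m[i, nz]) / 2
    }
  }
  out <- im_like(m, matrix)
  attr(out, "undetected") <- undetected
  out
}

#' Relative log expression (RLE) size factors
#'
#' Median-of-ratios size factors: for each sample, the median over usable
#' metabolites of the ratio of the sample's intensity to that metabolite's
#' geometric mean across samples. Metabolites with any zero are excluded
#' from factor computation (impute first to use all rows). Factors are
#' rescaled to have geometric mean 1, so normalization preserves the overall
#' intensity scale.
#'
#' @param matrix A raw-scale `intensity_matrix`.
#' @return Named numeric vector of positive per-sample factors.
#' @export
rle_size_factors <- function(matrix) {
  if (is_log_scale(matrix)) stop("RLE factors are computed on the raw scale")
  m <- unclass(matrix)
  usable <- rowSums(m <= 0) == 0L
  if (!any(usable)) {
    stop("no metabolite is nonzero in every sample; run half_min_impute() first")
  }
  lm_ <- log(m[usable, , drop = FALSE])
  ref <- rowMeans(lm_) # log geometric mean across samples
  factors <- exp(apply(lm_ - ref, 2L, stats::median))
  factors <- factors / exp(mean(log(factors)))
  stats::setNames(factors, colnames(m))
}

#' RLE normalization
#'
#' Divides each sample column by its [rle_size_factors()] factor and sets
#' the `normalized` flag. Idempotent up to numerical precision: factors of
#' an already-normalized matrix are all 1.
#'
#' @param matrix A raw-scale `intensity_matrix`.
#' @return The normalized matrix; factors in `attr(, "size_factors")`.
#' @export
rle_normalize <- function(matrix) {
  factors <- rle_size_factors(matrix)
  out <- im_like(sweep(unclass(matrix), 2L, factors, "/"), matrix,
                 normalized = TRUE)
  attr(out, "size_factors") <- factors
  out
}

#' Mean-equalizing normalization over above-background metabolites
#'
#' Scales each sample so that its average intensity over the metabolites
#' detected above background equals the grand mean of those per-sample
#' averages. An alternative to RLE when the goal is stated directly as equal
#' average signal in the samples being compared.
#'
#' @param matrix A raw-scale `intensity_matrix`.
#' @param above_background_ids Nonempty character vector of metabolite ids.
#' @return The scaled matrix with `normalized = TRUE`.
#' @export
mean_equalize <- function(matrix, above_background_ids) {
  above_background_ids <- intersect(above_background_ids, rownames(matrix))
  if (length(above_background_ids) == 0L) {
    stop("above_background_ids shares no metabolites with the matrix")
  }
  m <- unclass(matrix)
  sample_means <- colMeans(m[above_background_ids, , drop = FALSE])
  if (any(sample_means <= 0)) stop("a sample has zero mean signal over the id set")
  scale <- mean(sample_means) / sample_means
  im_like(sweep(m, 2L, scale, "*"), matrix, normalized = TRUE)
}

#' Per-metabolite Gaussian GLM group test
#'
#' Fits a Gaussian generalized linear model of a metabolite's log-scale
#' values on a two-level group indicator, optionally adjusting for pairing
#' (samples from the same animal) and/or batch (independent experiment) as
#' fixed-effect covariates. The group coefficient is the log2 fold change of
#' test over reference; the two-sided p value comes from the t distribution
#' at the residual degrees of freedom. Without covariates this reproduces
#' the pooled-variance two-sample t-test; with a complete pair covariate it
#' reproduces the paired t-test.
#'
#' Degenerate fits are resolved by convention: when the residual variance is
#' (numerically) zero, a zero group effect gives p = 1 (no evidence) and a
#' nonzero effect gives p = 0; both are flagged via the `degenerate` field.
#'
#' @param y Numeric response on the log2 scale, one value per sample.
#' @param group Factor-coercible with exactly two levels; the first level is
#'   the reference.
#' @param pair,batch Optional covariate labels per sample.
#' @return List with `coefficient`, `se`, `p_value`, `df`, `degenerate`.
#' @export
fit_group_test <- function(y, group, pair = NULL, batch = NULL) {
  group <- if (is.factor(group)) droplevels(group) else factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  if (any(table(group) < 2L)) stop("need >= 2 samples per group")
  df <- data.frame(y = as.numeric(y), group = group)
  terms <- "group"
  if (!is.null(pair)) {
    df$pair <- as.factor(as.character(pair))
    terms <- c(terms, "pair")
  }
  if (!is.null(batch)) {
    df$batch <- as.factor(as.character(batch))
    terms <- c(terms, "batch")
  }
  fit <- stats::glm(stats::reformulate(terms, response = "y"),
                    family = stats::gaussian(), data = df)
  coefs <- stats::coef(fit)
  if (anyNA(coefs)) {
    bad <- names(coefs)[is.na(coefs)]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  est <- coefs[[2L]] # group indicator is the first non-intercept term
  rdf <- stats::df.residual(fit)
  rss <- sum(stats::residuals(fit)^2)
  scale_ref <- max(mean(df$y^2), .Machine$double.eps)
  degenerate <- rdf <= 0 || rss / scale_ref < 1e-20
  if (degenerate) {
    p <- if (abs(est) < 1e-10 * max(1, sqrt(scale_ref))) 1 else 0
    return(list(coefficient = est, se = 0, p_value = p, df = rdf,
                degenerate = TRUE))
  }
  s <- summary(fit)$coefficients
  list(coefficient = est, se = s[2L, "Std. Error"],
       p_value = s[2L, 4L], df = rdf, degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values controlling the false discovery rate, returned
#' in the input order and clipped to 1.
#'
#' @param p_values Numeric vector of p values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

# shared significance rule: strict fold change AND strict FDR inequalities
is_significant <- function(fold_change, fdr, config) {
  beyond <- fold_change > config$fc_threshold |
    fold_change < 1 / config$fc_threshold
  beyond & fdr < config$fdr_threshold
}

#' Above-background detection against blank samples
#'
#' Calls each metabolite detected above background by comparing cell
#' samples to blank (sheath fluid) samples on `log2(x + pseudo_count)`
#' transformed, non-normalized, non-imputed data with a Gaussian GLM. The
#' fitted group coefficient gives the fold change of cells over blanks;
#' p values are BH-adjusted across metabolites, and a metabolite is above
#' background when fold change exceeds `fc_threshold` (strictly) at
#' `fdr < fdr_threshold`.
#'
#' @param matrix Raw, non-normalized `intensity_matrix`.
#' @param meta [sample_meta()] covering the matrix samples; needs >= 2
#'   blanks and >= 2 cell samples.
#' @param config An [analysis_config()].
#' @param group Optional cell group label; by default all cell samples are
#'   compared against the blanks.
#' @param batch Set TRUE to include the metadata batch column as a covariate.
#' @return Data.frame: `metabolite_id`, `fold_over_blank`, `log2_fc`,
#'   `p_value`, `fdr`, `above_background`.
#' @export
above_background <- function(matrix, meta, config = analysis_config(),
                             group = NULL, batch = FALSE) {
  if (is_normalized(matrix) || is_log_scale(matrix)) {
    stop("background calls use the raw, non-normalized matrix")
  }
  meta <- check_meta_match(matrix, meta)
  cell_keep <- meta$role == "cell"
  if (!is.null(group)) cell_keep <- cell_keep & meta$group %in% group
  meta <- meta[meta$role == "blank" | cell_keep, , drop = FALSE]
  sub <- matrix[, meta$sample_id, drop = FALSE]
  n_blank <- sum(meta$role == "blank")
  n_cell <- sum(meta$role == "cell")
  if (n_blank < 2L) stop("need >= 2 blank (sheath fluid) samples")
  if (n_cell < 2L) stop("need >= 2 cell samples")
  lg <- log2(unclass(sub) + config$pseudo_count)
  role <- factor(meta$role, levels = c("blank", "cell"))
  batch_v <- if (isTRUE(batch)) meta$batch else NULL
  fits <- apply(lg, 1L, function(y) fit_group_test(y, role, batch = batch_v))
  log2_fc <- vapply(fits, `[[`, 0, "coefficient")
  p <- vapply(fits, `[[`, 0, "p_value")
  fdr <- benjamini_hochberg(p)
  fold <- 2^log2_fc
  data.frame(
    metabolite_id = rownames(sub),
    fold_over_blank = fold, log2_fc = log2_fc,
    p_value = p, fdr = fdr,
    above_background = fold > config$fc_threshold & fdr < config$fdr_threshold,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Differential abundance between two cell groups
#'
#' The cell-vs-cell pipeline: half-minimum imputation, RLE normalization,
#' log2 transform, then a per-metabolite Gaussian GLM of the test group
#' against the reference with optional pairing/batch covariates, BH
#' adjustment across the tested universe, and the strict
#' fold change > `fc_threshold` / `fdr < fdr_threshold` significance rule.
#'
#' @param matrix Raw, non-normalized `intensity_matrix` (cell samples may be
#'   a superset of the two groups; blanks are ignored).
#' @param meta [sample_meta()] covering the matrix samples.
#' @param ref,test Group labels; the fitted log2 fold change is test over
#'   reference.
#' @param covariates Character subset of `c("pair", "batch")`.
#' @param config An [analysis_config()].
#' @param universe Metabolite ids to test (typically those above background
#'   in at least one of the two groups); defaults to all rows.
#' @return Data.frame of class `diff_result`: `metabolite_id`, `mean_ref`,
#'   `mean_test` (log2 scale), `log2_fc`, `fold_change`, `p_value`, `fdr`,
#'   `significant`, `direction`.
#' @export
differential_abundance <- function(matrix, meta, ref, test,
                                   covariates = character(0),
                                   config = analysis_config(),
                                   universe = NULL) {
  stopifnot(all(covariates %in% c("pair", "batch")))
  if (is_log_scale(matrix)) stop("supply the raw-scale matrix")
  meta <- check_meta_match(matrix, meta)
  meta <- meta[meta$role == "cell" & meta$group %in% c(ref, test), ,
               drop = FALSE]
  if (!ref %in% meta$group) stop("reference group '", ref, "' has no samples")
  if (!test %in% meta$group) stop("test group '", test, "' has no samples")
  if (is.null(universe)) universe <- rownames(matrix)
  universe <- intersect(rownames(matrix), universe)
  if (length(universe) == 0L) stop("empty metabolite universe")
  sub <- matrix[universe, meta$sample_id, drop = FALSE]
  if ("pair" %in% covariates) {
    tab <- table(meta$pair, meta$group)
    if (any(is.na(meta$pair)) || any(tab == 0L)) {
      stop("pair covariate requires every pair label in both groups")
    }
  }
  imputed <- half_min_impute(sub)
  dropped <- attr(imputed, "undetected")
  if (length(dropped) > 0L) {
    warning(length(dropped), " metabolite(s) undetected in all samples ",
            "removed from the universe")
    imputed <- imputed[setdiff(rownames(imputed), dropped), , drop = FALSE]
    imputed <- im_like(unclass(imputed), imputed)
  }
  normalized <- rle_normalize(imputed)
  lg <- log2(unclass(normalized))
  grp <- factor(meta$group, levels = c(ref, test))
  pair_v <- if ("pair" %in% covariates) meta$pair else NULL
  batch_v <- if ("batch" %in% covariates) meta$batch else NULL
  fits <- apply(lg, 1L, function(y) {
    fit_group_test(y, grp, pair = pair_v, batch = batch_v)
  })
  log2_fc <- vapply(fits, `[[`, 0, "coefficient")
  p <- vapply(fits, `[[`, 0, "p_value")
  fdr <- benjamini_hochberg(p)
  fold <- 2^log2_fc
  sig <- is_significant(fold, fdr, config)
  out <- data.frame(
    metabolite_id = rownames(lg),
    mean_ref = rowMeans(lg[, grp == ref, drop = FALSE]),
    mean_test = rowMeans(lg[, grp == test, drop = FALSE]),
    log2_fc = log2_fc, fold_change = fold,
    p_value = p, fdr = fdr, significant = sig,
    direction = ifelse(!sig, "none", ifelse(log2_fc > 0, "up", "down")),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("diff_result", "data.frame")
  out
}

#' Count significant results at a fold-change cutoff
#'
#' Direction-agnostic count of results with `fdr < fdr_threshold` and fold
#' change strictly beyond the cutoff in either direction. Used to re-count
#' a result set at a stronger effect size (e.g. 2.5-fold).
#'
#' @param results A `diff_result` data.frame.
#' @param fc_threshold Fold-change cutoff (> 1).
#' @param fdr_threshold FDR cutoff.
#' @return Integer count.
#' @export
count_significant <- function(results, fc_threshold = 2,
                              fdr_threshold = 0.05) {
  if (is.null(results) || nrow(results) == 0L) return(0L)
  beyond <- results$fold_change > fc_threshold |
    results$fold_change < 1 / fc_threshold
  sum(beyond & results$fdr < fdr_threshold)
}
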