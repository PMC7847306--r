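#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked data (ties receive their average
#' rank). A constant input has no ranking information; NA is returned with
#' a warning rather than an error so vectorized callers can proceed.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return Correlation in `[-1, 1]`, or NA for a constant input.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need >= 3 observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(rank(x), rank(y), method = "pearson")
}

#' Fold-change concordance between two analyses
#'
#' Compares two differential-abundance result tables over their common
#' metabolites (the two protocols being compared, e.g. sorted vs pipetted
#' samples analysed with the same contrast): Spearman correlation of the
#' log2 fold changes, an ordinary least squares regression of B's log2 fold
#' change on A's, and the overlap of the significant sets in both
#' directions.
#'
#' @param results_a,results_b `diff_result` tables sharing >= 3 metabolites.
#' @param restrict_to `"all"` (default) or `"significant_in_a"` to restrict
#'   the correlation/regression to metabolites significant in A.
#' @return List of class `concordance_summary`: `n_common`, `spearman_r`,
#'   `slope`, `intercept`, `n_sig_a`, `n_sig_b`, `n_sig_both`, `pct_a_in_b`,
#'   `pct_b_in_a`.
#' @export
fc_concordance <- function(results_a, results_b,
                           restrict_to = c("all", "significant_in_a")) {
  restrict_to <- match.arg(restrict_to)
  common <- merge(
    results_a[, c("metabolite_id", "log2_fc", "significant")],
    results_b[, c("metabolite_id", "log2_fc", "significant")],
    by = "metabolite_id", suffixes = c("_a", "_b")
  )
  sig_a <- results_a$metabolite_id[results_a$significant]
  sig_b <- results_b$metabolite_id[results_b$significant]
  use <- common
  if (restrict_to == "significant_in_a") {
    use <- common[common$significant_a, , drop = FALSE]
  }
  if (nrow(use) < 3L) stop("fewer than 3 common metabolites to compare")
  fit <- stats::lm(log2_fc_b ~ log2_fc_a, data = use)
  both <- intersect(sig_a, sig_b)
  structure(list(
    n_common = nrow(use),
    spearman_r = spearman_cor(use$log2_fc_a, use$log2_fc_b),
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    n_sig_a = length(sig_a), n_sig_b = length(sig_b),
    n_sig_both = length(both),
    pct_a_in_b = if (length(sig_a) > 0) 100 * length(both) / length(sig_a) else NA_real_,
    pct_b_in_a = if (length(sig_b) > 0) 100 * length(both) / length(sig_b) else NA_real_
  ), class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf(
    paste0("concordance over %d metabolites: Spearman r = %.3f, ",
           "y = %.2fx %+.2f\nsignificant: %d (A), %d (B), %d shared ",
           "(%.0f%% of A, %.0f%% of B)\n"),
    x$n_common, x$spearman_r, x$slope, x$intercept,
    x$n_sig_a, x$n_sig_b, x$n_sig_both, x$pct_a_in_b, x$pct_b_in_a))
  invisible(x)
}

#' Principal component analysis of samples
#'
#' PCA of samples in metabolite space: each metabolite is mean-centered
#' across samples, components are ordered by decreasing variance. Intended
#' for log2-transformed, normalized, imputed data.
#'
#' @param matrix A log-scale `intensity_matrix` with >= 3 samples.
#' @param n_components Number of components to return (default 2).
#' @return List with `scores` (samples x components), `explained` (variance
#'   fractions, one per returned component), and `loadings`.
#' @export
pca_scores <- function(matrix, n_components = 2L) {
  if (ncol(matrix) < 3L) stop("PCA needs >= 3 samples")
  max_comp <- min(ncol(matrix) - 1L, nrow(matrix))
  if (n_components > max_comp) {
    stop("requested ", n_components, " components but at most ", max_comp,
         " are available")
  }
  fit <- stats::prcomp(t(unclass(matrix)), center = TRUE, scale. = FALSE)
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x[, seq_len(n_components), drop = FALSE],
       explained = explained[seq_len(n_components)],
       loadings = fit$rotation[, seq_len(n_components), drop = FALSE])
}

#' Above-background counts per group across replicate analyses
#'
#' Aggregates [above_background()] call tables into per-group counts,
#' reported as mean and sample (n-1) standard deviation when a group was
#' analysed in several replicate runs (e.g. independent experiments).
#'
#' @param calls Named list: group label -> list of call data.frames (or a
#'   single data.frame) from [above_background()].
#' @return Data.frame: `group`, `n_runs`, `mean_count`, `sd_count`.
#' @export
count_above_background_by_group <- function(calls) {
  stopifnot(length(calls) >= 1L, !is.null(names(calls)))
  rows <- lapply(names(calls), function(g) {
    runs <- calls[[g]]
    if (is.data.frame(runs)) runs <- list(runs)
    counts <- vapply(runs, function(df) sum(df$above_background), 0)
    data.frame(group = g, n_runs = length(counts),
               mean_count = mean(counts),
               sd_count = if (length(counts) > 1L) stats::sd(counts) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of metabolites trending in the same direction
#'
#' For a set of metabolites, the share whose log2 fold changes have the
#' same sign in both result tables (an exact zero agrees only with zero).
#' Used to ask whether changes called in one protocol but not the other at
#' least trend the same way.
#'
#' @param results_a,results_b `diff_result` tables.
#' @param ids Nonempty metabolite ids present in both tables.
#' @return Fraction in `[0, 1]`.
#' @export
direction_agreement <- function(results_a, results_b, ids) {
  ids <- unique(as.character(ids))
  if (length(ids) == 0L) stop("empty id set")
  missing <- setdiff(ids, intersect(results_a$metabolite_id,
                                    results_b$metabolite_id))
  if (length(missing) > 0L) {
    stop("id(s) absent from one of the result tables: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  fa <- results_a$log2_fc[match(ids, results_a$metabolite_id)]
  fb <- results_b$log2_fc[match(ids, results_b$metabolite_id)]
  mean(sign(fa) == sign(fb))
}
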