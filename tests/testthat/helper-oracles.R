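# Independent oracles used across the suite. Each re-derives a quantity by
# a different route than the package implementation.

# Benjamini-Hochberg step-up, straight from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Exhaustive isotopologue convolution: full (untruncated) polynomial
# product taken one atom at a time, with its own formula parser and a
# duplicated natural-abundance table.
oracle_abundance <- list(
  C = c(0.9893, 0.0107), H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364), O = c(0.99757, 0.00038, 0.00205),
  P = c(1), S = c(0.9499, 0.0075, 0.0425, 0, 0.0001),
  Cl = c(0.7576, 0, 0.2424), Na = c(1),
  K = c(0.932581, 0.000117, 0.067302)
)

iso_oracle <- function(formula, max_shift = 2L) {
  conv_full <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(a)) {
      idx <- i + seq_along(b) - 1L
      out[idx] <- out[idx] + a[i] * b
    }
    out
  }
  dist <- 1
  if (nzchar(formula)) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1L]]
    tokens <- regmatches(formula, list(m))[[1L]]
    for (tok in tokens) {
      el <- sub("[0-9]*$", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.integer(n) else 1L
      for (k in seq_len(n)) dist <- conv_full(dist, oracle_abundance[[el]])
    }
  }
  dist <- c(dist, numeric(max_shift + 1L))[seq_len(max_shift + 1L)]
  dist / dist[1L]
}

# Hypergeometric upper tail by exhaustive enumeration of all draws.
hyper_oracle <- function(overlap, n_sig, n_path, n_universe) {
  if (n_sig == 0L) return(as.numeric(overlap <= 0))
  draws <- utils::combn(n_universe, n_sig)
  marked <- seq_len(n_path)
  mean(apply(draws, 2L, function(d) sum(d %in% marked) >= overlap))
}

# Small deterministic experiment fixtures -----------------------------------

toy_matrix <- function(values, met = NULL, smp = NULL) {
  values <- as.matrix(values)
  if (is.null(met)) met <- sprintf("m%d", seq_len(nrow(values)))
  if (is.null(smp)) smp <- sprintf("s%d", seq_len(ncol(values)))
  intensity_matrix(values, metabolite_ids = met, sample_ids = smp)
}

toy_meta <- function(sample_ids, roles, groups, batch = NULL, pair = NULL) {
  sample_meta(data.frame(
    sample_id = sample_ids, role = roles, group = groups,
    batch = if (is.null(batch)) NA_character_ else batch,
    pair = if (is.null(pair)) NA_character_ else pair,
    stringsAsFactors = FALSE
  ))
}

# Two-group cell matrix with blanks: k metabolites x (blanks + 2 groups).
toy_experiment <- function(n_met = 6L, n_per_group = 3L, n_blanks = 3L,
                           seed = 42L) {
  set.seed(seed)
  smp <- c(sprintf("bl%d", seq_len(n_blanks)),
           sprintf("a%d", seq_len(n_per_group)),
           sprintf("b%d", seq_len(n_per_group)))
  m <- matrix(2^(rnorm(n_met * length(smp), 16, 0.3)), n_met, length(smp))
  m[, seq_len(n_blanks)] <- m[, seq_len(n_blanks)] / 100
  mat <- toy_matrix(m, smp = smp)
  meta <- toy_meta(smp,
                   c(rep("blank", n_blanks), rep("cell", 2L * n_per_group)),
                   c(rep("blank", n_blanks), rep("A", n_per_group),
                     rep("B", n_per_group)))
  list(matrix = mat, meta = meta)
}
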