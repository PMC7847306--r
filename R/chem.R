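# Embedded natural-abundance and monoisotopic-mass tables (IUPAC 2021).
# Abundance vectors are indexed by nominal mass shift relative to the
# monoisotopic isotope (position 1 = shift 0).
.isotope_abundance <- list(
  C  = c(0.9893, 0.0107),
  H  = c(0.999885, 0.000115),
  N  = c(0.99636, 0.00364),
  O  = c(0.99757, 0.00038, 0.00205),
  P  = c(1),
  S  = c(0.9499, 0.0075, 0.0425, 0, 0.0001),
  Cl = c(0.7576, 0, 0.2424),
  Na = c(1),
  K  = c(0.932581, 0.000117, 0.067302)
)

.monoisotopic_mass <- c(
  C = 12.0, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
  P = 30.97376163, S = 31.97207100, Cl = 34.96885268,
  Na = 22.9897692809, K = 38.96370668
)

.proton_mass <- 1.007276

#' Parse an elemental formula
#'
#' Parses a Hill-order formula string such as `"C6H12O6"` into element
#' counts. Supported elements: C, H, N, O, P, S, Cl, Na, K.
#'
#' @param formula Formula string; `""` parses to an empty composition.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  formula <- trimws(formula)
  if (formula == "") return(stats::setNames(integer(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1L]]
  tokens <- regmatches(formula, list(m))[[1L]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula: '", formula, "'")
  }
  elems <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(elems, names(.isotope_abundance))
  if (length(unknown) > 0L) {
    stop("unsupported element(s) in '", formula, "': ",
         paste(unknown, collapse = ", "))
  }
  tapply(counts, factor(elems, levels = unique(elems)), sum)[unique(elems)]
}

#' Monoisotopic mass of a formula
#'
#' @param formula Formula string (see [parse_formula()]).
#' @return Monoisotopic neutral mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(.monoisotopic_mass[names(counts)] * counts)
}

#' Theoretical m/z of an adduct
#'
#' Protonated/deprotonated ion masses from a neutral formula:
#' `[M+H]+` adds and `[M-H]-` subtracts one proton (1.007276 Da); `"M"`
#' returns the neutral monoisotopic mass.
#'
#' @param formula Formula string (nonempty).
#' @param adduct One of `"[M+H]+"`, `"[M-H]-"`, `"M"`.
#' @return Theoretical m/z in Da.
#' @export
#' @examples
#' adduct_mz("H2O", "[M+H]+") # 19.017841
adduct_mz <- function(formula, adduct = c("[M+H]+", "[M-H]-", "M")) {
  adduct <- match.arg(adduct)
  if (trimws(formula) == "") stop("empty formula has no adduct m/z")
  m <- monoisotopic_mass(formula)
  switch(adduct,
         "[M+H]+" = m + .proton_mass,
         "[M-H]-" = m - .proton_mass,
         "M" = m)
}

#' Mass error in parts per million
#'
#' `1e6 * (observed - theoretical) / theoretical`; the sign records the
#' direction of the deviation.
#'
#' @param observed_mz,theoretical_mz Masses in Da, both > 0.
#' @return Signed ppm error (vectorized).
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  if (any(observed_mz <= 0) || any(theoretical_mz <= 0)) {
    stop("masses must be positive")
  }
  1e6 * (observed_mz - theoretical_mz) / theoretical_mz
}

#' Predicted isotopologue envelope of a formula
#'
#' Relative abundances of the M, M+1, ..., M+`max_shift` isotopologue peaks
#' predicted from natural isotope abundances, aggregated by nominal mass
#' shift. Computed as the convolution product, over elements, of each
#' element's single-atom isotope distribution raised to its atom count, then
#' normalized so the monoisotopic peak M equals 1.
#'
#' @param formula Formula string; the empty formula yields `c(1)`.
#' @param max_shift Largest nominal shift to report (default 2, the
#'   M/M+1/M+2 envelope used in library matching).
#' @return Numeric vector of length `max_shift + 1` with M normalized to 1.
#' @export
#' @examples
#' isotope_pattern("C6H12O6")
isotope_pattern <- function(formula, max_shift = 2L) {
  stopifnot(max_shift >= 0L)
  counts <- parse_formula(formula)
  len <- max_shift + 1L
  dist <- c(1, numeric(max_shift))
  for (el in names(counts)) {
    single <- .isotope_abundance[[el]]
    single <- c(single, numeric(max(0L, len - length(single))))[seq_len(len)]
    # exponentiation by squaring in the truncated convolution algebra
    pow <- conv_power(single, counts[[el]], len)
    dist <- conv_trunc(dist, pow, len)
  }
  dist / dist[1L]
}

conv_trunc <- function(a, b, len) {
  out <- numeric(len)
  for (k in seq_len(len)) {
    i <- seq_len(k)
    out[k] <- sum(a[i] * b[k - i + 1L])
  }
  out
}

conv_power <- function(x, n, len) {
  result <- c(1, numeric(len - 1L))
  base <- x
  while (n > 0L) {
    if (n %% 2L == 1L) result <- conv_trunc(result, base, len)
    base <- conv_trunc(base, base, len)
    n <- n %/% 2L
  }
  result
}

#' Cosine similarity between two isotope envelopes
#'
#' @param a,b Nonnegative numeric vectors; shorter one is zero-padded.
#' @return Cosine similarity in `[0, 1]`, or NA if either vector is all zero.
#' @export
envelope_cosine <- function(a, b) {
  len <- max(length(a), length(b))
  a <- c(a, numeric(len - length(a)))
  b <- c(b, numeric(len - length(b)))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}
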