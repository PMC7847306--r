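#' Read / write a metabolite library table
#'
#' A library row identifies a metabolite by name, elemental formula, adduct,
#' polarity, theoretical m/z and chromatographic retention time, with flags
#' recording whether the identity was confirmed by MS2 spectra and by a
#' chemical standard. When a formula is present, `theoretical_mz` is checked
#' against the formula + adduct mass to within 1e-3 Da (and filled in when
#' absent).
#'
#' @param path CSV/TSV with columns `metabolite_id`, `name`, `formula`,
#'   `adduct`, `polarity`, `theoretical_mz`, `retention_time` and optional
#'   `ms2_confirmed`, `standard_confirmed`, `pathway_ids`
#'   (semicolon-separated).
#' @return A data.frame of class `metabolite_library`.
#' @export
read_library <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  metabolite_library(df)
}

#' @rdname read_library
#' @param library A `metabolite_library` data.frame.
#' @export
write_library <- function(library, path) {
  utils::write.table(as.data.frame(library), path, sep = sniff_sep(path),
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_library
#' @param df Data.frame with the library columns.
#' @export
metabolite_library <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("metabolite_id", "name", "adduct", "polarity", "retention_time")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    stop("library lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$metabolite_id)) stop("duplicate metabolite_id in library")
  if (!"formula" %in% names(df)) df$formula <- NA_character_
  if (!"theoretical_mz" %in% names(df)) df$theoretical_mz <- NA_real_
  bad_add <- setdiff(unique(df$adduct), c("[M+H]+", "[M-H]-", "M"))
  if (length(bad_add) > 0L) {
    stop("unsupported adduct(s): ", paste(bad_add, collapse = ", "))
  }
  bad_pol <- setdiff(unique(df$polarity), c("+", "-"))
  if (length(bad_pol) > 0L) {
    stop("polarity must be '+' or '-', got: ", paste(bad_pol, collapse = ", "))
  }
  if (any(df$retention_time < 0, na.rm = TRUE)) {
    stop("retention times must be >= 0")
  }
  for (flag in c("ms2_confirmed", "standard_confirmed")) {
    if (!flag %in% names(df)) df[[flag]] <- FALSE
    df[[flag]] <- as.logical(df[[flag]])
  }
  if (!"pathway_ids" %in% names(df)) df$pathway_ids <- ""
  has_formula <- !is.na(df$formula) & nzchar(trimws(df$formula))
  for (i in which(has_formula)) {
    mz <- adduct_mz(df$formula[i], df$adduct[i])
    if (is.na(df$theoretical_mz[i])) {
      df$theoretical_mz[i] <- mz
    } else if (abs(df$theoretical_mz[i] - mz) > 1e-3) {
      stop(sprintf(
        "library entry '%s': theoretical_mz %.6f inconsistent with %s %s (%.6f)",
        df$metabolite_id[i], df$theoretical_mz[i], df$formula[i],
        df$adduct[i], mz))
    }
  }
  if (any(is.na(df$theoretical_mz) | df$theoretical_mz <= 0)) {
    stop("every library entry needs a positive theoretical_mz or a formula")
  }
  rownames(df) <- NULL
  class(df) <- c("metabolite_library", "data.frame")
  df
}

#' Match an observed LC-MS feature against a metabolite library
#'
#' Compares a feature's m/z and retention time against every library entry
#' of the same polarity. Candidates within twice the configured tolerances
#' are reported (so near-misses appear with their rejection reasons);
#' acceptance requires mass accuracy within `ppm_tolerance` (inclusive),
#' retention time within `rt_tolerance`, and - when the feature carries an
#' isotope envelope and the entry a formula - envelope cosine similarity of
#' at least `isotope_cosine_min`. Results are ordered by `|ppm_error|`, ties
#' broken by `|rt_delta|`.
#'
#' @param feature A list with `feature_id`, `mz`, `retention_time`,
#'   `polarity` and optionally `isotope_envelope` (relative abundances of
#'   M, M+1, M+2 with M = 1).
#' @param library A `metabolite_library`.
#' @param config An [analysis_config()].
#' @return Data.frame with one row per candidate: `feature_id`,
#'   `metabolite_id`, `ppm_error`, `rt_delta`, `isotope_cosine`, `accepted`,
#'   `rejection_reasons` (comma-separated, empty when accepted).
#' @export
match_feature <- function(feature, library, config = analysis_config()) {
  stopifnot(is.list(feature), !is.null(feature$mz), feature$mz > 0)
  empty <- data.frame(feature_id = character(0), metabolite_id = character(0),
                      ppm_error = numeric(0), rt_delta = numeric(0),
                      isotope_cosine = numeric(0), accepted = logical(0),
                      rejection_reasons = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(library) == 0L) return(empty)
  lib <- library[library$polarity == feature$polarity, , drop = FALSE]
  if (nrow(lib) == 0L) return(empty)
  ppm <- ppm_error(feature$mz, lib$theoretical_mz)
  rtd <- feature$retention_time - lib$retention_time
  cand <- abs(ppm) <= 2 * config$ppm_tolerance &
    abs(rtd) <= 2 * config$rt_tolerance
  if (!any(cand)) return(empty)
  lib <- lib[cand, , drop = FALSE]
  ppm <- ppm[cand]; rtd <- rtd[cand]
  cosine <- rep(NA_real_, nrow(lib))
  if (!is.null(feature$isotope_envelope)) {
    has_f <- !is.na(lib$formula) & nzchar(trimws(lib$formula))
    for (i in which(has_f)) {
      cosine[i] <- envelope_cosine(
        feature$isotope_envelope,
        isotope_pattern(lib$formula[i],
                        max_shift = length(feature$isotope_envelope) - 1L))
    }
  }
  reasons <- vapply(seq_len(nrow(lib)), function(i) {
    r <- character(0)
    if (abs(ppm[i]) > config$ppm_tolerance) r <- c(r, "mass")
    if (abs(rtd[i]) > config$rt_tolerance) r <- c(r, "retention_time")
    if (!is.na(cosine[i]) && cosine[i] < config$isotope_cosine_min) {
      r <- c(r, "isotope_pattern")
    }
    paste(r, collapse = ",")
  }, "")
  out <- data.frame(
    feature_id = if (is.null(feature$feature_id)) NA_character_ else feature$feature_id,
    metabolite_id = lib$metabolite_id,
    ppm_error = ppm, rt_delta = rtd, isotope_cosine = cosine,
    accepted = reasons == "", rejection_reasons = reasons,
    stringsAsFactors = FALSE
  )
  out[order(abs(out$ppm_error), abs(out$rt_delta)), , drop = FALSE]
}

#' Library inclusion test: alignment and cell-number monotonicity
#'
#' A candidate feature enters the library only if (i) its chromatographic
#' peak aligns across all samples in which it is detected - the max-min
#' retention-time spread must not exceed `rt_tolerance` - and (ii) its peak
#' intensity increases with the number of cells in the sample, assessed as a
#' Spearman rank correlation of at least `spearman_min` (default 0.8)
#' between cell number and intensity. The rank-based criterion is invariant
#' to uniform intensity rescaling.
#'
#' @param intensity Nonnegative per-sample intensities (0 = not detected).
#' @param cell_number Cell counts for the same samples; at least 3 distinct
#'   values are required.
#' @param retention_time Optional per-sample apex retention times (NA where
#'   the feature is undetected).
#' @param config An [analysis_config()].
#' @return List with `pass` (logical), `reasons` (character vector, empty on
#'   pass), `spearman` and `rt_spread`.
#' @export
inclusion_test <- function(intensity, cell_number, retention_time = NULL,
                           config = analysis_config()) {
  stopifnot(length(intensity) == length(cell_number))
  if (length(unique(cell_number)) < 3L) {
    stop("inclusion test needs >= 3 samples with distinct cell numbers")
  }
  reasons <- character(0)
  rt_spread <- NA_real_
  if (!is.null(retention_time)) {
    rt <- retention_time[intensity > 0 & !is.na(retention_time)]
    if (length(rt) >= 2L) {
      rt_spread <- max(rt) - min(rt)
      if (rt_spread > config$rt_tolerance) reasons <- c(reasons, "not aligned")
    }
  }
  # a constant intensity vector has no rank information: treated as failing
  rho <- suppressWarnings(spearman_cor(cell_number, intensity))
  if (is.na(rho) || rho < config$spearman_min) {
    reasons <- c(reasons, "not increasing")
  }
  list(pass = length(reasons) == 0L, reasons = reasons,
       spearman = rho, rt_spread = rt_spread)
}

#' Restrict a high-abundance library to the detected subset
#'
#' Narrows a library built from high-abundance samples to the metabolites
#' actually detected in a low-abundance screen, preserving order. Detected
#' ids not present in the library are reported as a warning, not an error.
#'
#' @param library A `metabolite_library`.
#' @param detected_ids Character vector of detected metabolite ids.
#' @return The sub-library containing exactly the detected entries.
#' @export
restrict_library <- function(library, detected_ids) {
  detected_ids <- unique(as.character(detected_ids))
  unknown <- setdiff(detected_ids, library$metabolite_id)
  if (length(unknown) > 0L) {
    warning(length(unknown), " detected id(s) not in the library: ",
            paste(utils::head(unknown, 5L), collapse = ", "),
            if (length(unknown) > 5L) ", ..." else "")
  }
  out <- library[library$metabolite_id %in% detected_ids, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(library)
  out
}
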