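#' Analysis configuration
#'
#' Bundles the thresholds and tolerances used throughout the pipeline.
#' Defaults reflect the conventions of sorted-cell metabolomics: a metabolite
#' is called significant (or above background) when its fold change exceeds 2
#' (strictly) at a Benjamini-Hochberg FDR below 0.05, library matches must be
#' within 5 ppm of theoretical mass and 0.5 min of the library retention
#' time, and pathway enrichment is called at FDR < 0.01.
#'
#' @param fc_threshold Fold-change cutoff for significance; strict
#'   (`fold_change > fc_threshold` or `< 1/fc_threshold`). Must be > 1.
#' @param fdr_threshold FDR cutoff for significance, strict (`fdr <`). In (0,1).
#' @param fc_threshold_secondary Secondary fold-change cutoff used when
#'   re-counting results at a stronger effect size (default 2.5).
#' @param enrichment_fdr FDR cutoff for calling a pathway enriched.
#' @param pseudo_count Pseudo-count added before the log2 transform of raw
#'   (non-normalized) data in background comparisons.
#' @param ppm_tolerance Mass accuracy window in parts per million, inclusive.
#' @param rt_tolerance Retention-time window in minutes, inclusive.
#' @param isotope_cosine_min Minimum cosine similarity between an observed
#'   and predicted M..M+2 isotopologue envelope for a match to be accepted.
#' @param spearman_min Minimum Spearman correlation between cell number and
#'   intensity for a feature to pass the library inclusion test.
#' @param min_pathway_size Pathways with fewer universe members than this are
#'   skipped during enrichment.
#' @param seed Integer seed recorded with the configuration.
#'
#' @return A list of class `metasort_config`.
#' @export
#' @examples
#' cfg <- analysis_config(fc_threshold = 2, fdr_threshold = 0.05)
#' cfg$ppm_tolerance
analysis_config <- function(fc_threshold = 2,
                            fdr_threshold = 0.05,
                            fc_threshold_secondary = 2.5,
                            enrichment_fdr = 0.01,
                            pseudo_count = 1,
                            ppm_tolerance = 5,
                            rt_tolerance = 0.5,
                            isotope_cosine_min = 0.95,
                            spearman_min = 0.8,
                            min_pathway_size = 2,
                            seed = 1L) {
  stopifnot(
    is.numeric(fc_threshold), length(fc_threshold) == 1L, fc_threshold > 1,
    is.numeric(fdr_threshold), fdr_threshold > 0, fdr_threshold < 1,
    is.numeric(fc_threshold_secondary), fc_threshold_secondary > 1,
    is.numeric(enrichment_fdr), enrichment_fdr > 0, enrichment_fdr < 1,
    is.numeric(pseudo_count), pseudo_count >= 0,
    is.numeric(ppm_tolerance), ppm_tolerance > 0,
    is.numeric(rt_tolerance), rt_tolerance > 0,
    is.numeric(isotope_cosine_min), isotope_cosine_min > 0,
    isotope_cosine_min <= 1,
    is.numeric(spearman_min), spearman_min > 0, spearman_min <= 1,
    is.numeric(min_pathway_size), min_pathway_size >= 0
  )
  structure(
    list(
      fc_threshold = fc_threshold,
      fdr_threshold = fdr_threshold,
      fc_threshold_secondary = fc_threshold_secondary,
      enrichment_fdr = enrichment_fdr,
      pseudo_count = pseudo_count,
      ppm_tolerance = ppm_tolerance,
      rt_tolerance = rt_tolerance,
      isotope_cosine_min = isotope_cosine_min,
      spearman_min = spearman_min,
      min_pathway_size = min_pathway_size,
      seed = as.integer(seed)
    ),
    class = "metasort_config"
  )
}

#' Read / write an analysis configuration as JSON
#'
#' @param path File path of a JSON object whose fields match the arguments of
#'   [analysis_config()]; unknown fields are rejected.
#' @return `read_config()` returns a `metasort_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L) {
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  }
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @param config A `metasort_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "metasort_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
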