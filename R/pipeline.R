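# Pipeline orchestration: each run_* command reads standard input files,
# executes one stage, writes delimited outputs plus a JSON run manifest
# sufficient to re-run the command bit-identically.

write_manifest <- function(command, inputs, outputs, params, seed, out_dir) {
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("metasort")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    params = params,
    outputs = outputs
  )
  path <- file.path(out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run the above-background detection stage
#'
#' Reads an intensity table and sample metadata, calls metabolites above
#' the sheath-fluid background, and writes the call table, a per-group
#' count summary, and a run manifest.
#'
#' @param intensity_path,meta_path Input file paths (CSV/TSV).
#' @param out_dir Output directory (created if needed).
#' @param config An [analysis_config()].
#' @return The call data.frame, invisibly; files are the primary output.
#' @export
run_detect <- function(intensity_path, meta_path, out_dir,
                       config = analysis_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mat <- read_intensity_table(intensity_path)
  meta <- read_sample_meta(meta_path)
  calls <- above_background(mat, meta, config)
  out <- file.path(out_dir, "background_calls.csv")
  write_results(calls, out)
  groups <- unique(meta$group[meta$role == "cell"])
  summary_df <- count_above_background_by_group(
    stats::setNames(lapply(groups, function(g) {
      above_background(mat, meta, config, group = g)
    }), groups)
  )
  sum_path <- file.path(out_dir, "background_counts.csv")
  utils::write.table(summary_df, sum_path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  write_manifest("detect", list(intensity_path, meta_path),
                 list(out, sum_path),
                 params = unclass(config), seed = config$seed, out_dir)
  invisible(calls)
}

#' Run the differential-abundance stage
#'
#' Full cell-vs-cell pipeline (impute, RLE-normalize, log2, Gaussian GLM,
#' BH) between two groups, with the test universe restricted to metabolites
#' above background in at least one of the two groups.
#'
#' @param intensity_path,meta_path Input file paths.
#' @param ref,test Group labels (log2 fold change is test over reference).
#' @param covariates Character subset of `c("pair", "batch")`.
#' @param out_dir Output directory.
#' @param config An [analysis_config()].
#' @return The `diff_result` data.frame, invisibly.
#' @export
run_diff <- function(intensity_path, meta_path, ref, test,
                     covariates = character(0), out_dir,
                     config = analysis_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mat <- read_intensity_table(intensity_path)
  meta <- read_sample_meta(meta_path)
  for (g in c(ref, test)) {
    if (!g %in% meta$group[meta$role == "cell"]) {
      stop("group '", g, "' has no samples in the metadata")
    }
  }
  universe <- detection_universe(mat, meta, c(ref, test), config)
  res <- differential_abundance(mat, meta, ref, test,
                                covariates = covariates, config = config,
                                universe = universe)
  out <- file.path(out_dir, "diff_results.csv")
  write_results(res, out)
  write_manifest("diff", list(intensity_path, meta_path), list(out),
                 params = c(unclass(config),
                            list(ref = ref, test = test,
                                 covariates = as.list(covariates))),
                 seed = config$seed, out_dir)
  invisible(res)
}

#' Universe of metabolites above background in at least one group
#'
#' @param matrix Raw `intensity_matrix`.
#' @param meta [sample_meta()]; must contain blanks if any group is to be
#'   cleared against background (without blanks the whole matrix is used).
#' @param groups Cell group labels to clear.
#' @param config An [analysis_config()].
#' @return Character vector of metabolite ids.
#' @export
detection_universe <- function(matrix, meta, groups,
                               config = analysis_config()) {
  meta2 <- check_meta_match(matrix, meta)
  if (sum(meta2$role == "blank") < 2L) return(rownames(matrix))
  above <- lapply(groups, function(g) {
    calls <- above_background(matrix, meta, config, group = g)
    calls$metabolite_id[calls$above_background]
  })
  sort(unique(unlist(above)))
}

#' Run the pathway-enrichment stage
#'
#' @param results_path A written `diff_result` table (from [run_diff()]).
#' @param gmt_path Pathway sets in GMT format.
#' @param out_dir Output directory.
#' @param config An [analysis_config()].
#' @return The enrichment data.frame, invisibly.
#' @export
run_enrich <- function(results_path, gmt_path, out_dir,
                       config = analysis_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- read_results(results_path)
  pathways <- read_gmt(gmt_path)
  er <- enrich(res$metabolite_id[res$significant], res$metabolite_id,
               pathways, config)
  out <- file.path(out_dir, "enrichment.csv")
  utils::write.table(er, out, sep = ",", quote = FALSE, row.names = FALSE)
  write_manifest("enrich", list(results_path, gmt_path), list(out),
                 params = unclass(config), seed = config$seed, out_dir)
  invisible(er)
}

#' Run the library-matching stage
#'
#' Matches a table of observed features (columns `feature_id`, `mz`,
#' `retention_time`, `polarity`) against a metabolite library.
#'
#' @param features_path,library_path Input file paths.
#' @param out_dir Output directory.
#' @param config An [analysis_config()].
#' @return The combined match data.frame, invisibly.
#' @export
run_match <- function(features_path, library_path, out_dir,
                      config = analysis_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  feats <- utils::read.table(features_path, header = TRUE,
                             sep = sniff_sep(features_path),
                             stringsAsFactors = FALSE)
  library <- read_library(library_path)
  matches <- do.call(rbind, lapply(seq_len(nrow(feats)), function(i) {
    match_feature(as.list(feats[i, , drop = FALSE]), library, config)
  }))
  if (is.null(matches)) matches <- match_feature(
    list(feature_id = "none", mz = 1, retention_time = 0, polarity = "+"),
    library[0L, , drop = FALSE], config)
  out <- file.path(out_dir, "matches.csv")
  utils::write.table(matches, out, sep = ",", quote = FALSE,
                     row.names = FALSE)
  write_manifest("match", list(features_path, library_path), list(out),
                 params = unclass(config), seed = config$seed, out_dir)
  invisible(matches)
}

#' Run the simulation stage
#'
#' Generates a synthetic experiment and writes intensity, metadata and
#' truth tables plus a manifest.
#'
#' @param out_dir Output directory.
#' @param config A [sim_config()].
#' @return The simulation list, invisibly.
#' @export
run_simulate <- function(out_dir, config = sim_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_experiment(config)
  paths <- write_simulation(sim, out_dir)
  write_manifest("simulate", list(), as.list(unname(paths)),
                 params = lapply(unclass(config), function(x) {
                   if (length(x) > 1L) as.list(x) else x
                 }),
                 seed = config$seed, out_dir)
  invisible(sim)
}
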