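#' Read a metabolite intensity table
#'
#' Reads a delimited (CSV or TSV, sniffed from the extension or the header
#' line) peak-intensity table into an [intensity_matrix()]. The first column
#' (or row, see `orientation`) holds ids; the body must be numeric. Empty
#' cells are read as 0 (not detected) with a warning; negative, NaN or
#' infinite values are rejected with the offending cell named.
#'
#' @param path File path.
#' @param orientation `"metabolites"` if rows are metabolites (default, the
#'   LC-MS convention), `"samples"` if rows are samples (the table is
#'   transposed after reading, so both orientations yield the same matrix).
#' @return An `intensity_matrix` (raw scale, not normalized).
#' @export
read_intensity_table <- function(path,
                                 orientation = c("metabolites", "samples")) {
  orientation <- match.arg(orientation)
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "")
  if (ncol(df) < 2L) stop("intensity table needs an id column plus data")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate row ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  body <- df[, -1L, drop = FALSE]
  n_empty <- sum(body == "" | is.na(body))
  if (n_empty > 0L) {
    warning(n_empty, " empty cell(s) read as 0 (not detected)")
    body[body == "" | is.na(body)] <- "0"
  }
  num <- suppressWarnings(
    vapply(body, as.numeric, numeric(nrow(body)), USE.NAMES = TRUE)
  )
  if (nrow(body) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, names(body)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                 body[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]],
                 colnames(num)[bad[1L, 2L]]))
  }
  neg <- which(num < 0 | !is.finite(num), arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    stop(sprintf("invalid intensity %s at row '%s', column '%s'",
                 format(num[neg[1L, , drop = FALSE]]), ids[neg[1L, 1L]],
                 colnames(num)[neg[1L, 2L]]))
  }
  rownames(num) <- ids
  if (orientation == "samples") num <- t(num)
  intensity_matrix(num)
}

#' Write an intensity matrix as delimited text
#'
#' @param matrix An `intensity_matrix`.
#' @param path Output path; `.tsv` extension selects tab separation.
#' @param orientation As in [read_intensity_table()].
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(matrix, path,
                                  orientation = c("metabolites", "samples")) {
  orientation <- match.arg(orientation)
  m <- unclass(matrix)
  if (orientation == "samples") m <- t(m)
  id_name <- if (orientation == "metabolites") "metabolite_id" else "sample_id"
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  utils::write.table(df, path, sep = sniff_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

sniff_sep <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) return("\t")
  if (grepl("\\.csv$", path, ignore.case = TRUE)) return(",")
  # fall back to inspecting the first line
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 1L && grepl("\t", first)) "\t" else ","
}

#' Read sample metadata
#'
#' Delimited table with required columns `sample_id`, `role` (blank/cell) and
#' `group`; optional `batch`, `pair`, `cell_number`, `notes`. A pair label
#' seen in only one sample triggers a warning but the load succeeds.
#'
#' @param path File path (CSV or TSV).
#' @return A validated [sample_meta()] data.frame.
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          quote = "\"", stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "")
  sample_meta(df)
}

#' @rdname read_sample_meta
#' @param meta A `sample_meta` data.frame.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = sniff_sep(path),
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read pathway sets in GMT format
#'
#' One tab-separated line per set: id, description, then one field per
#' member. Lines with fewer than three fields (no members) are rejected with
#' their line number.
#'
#' @param path GMT file path.
#' @return A [pathway_sets()] collection.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short) > 0L) {
    stop("GMT line ", short[1L], " has fewer than 3 fields (no members)")
  }
  ids <- vapply(fields, `[[`, "", 1L)
  descs <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) f[-c(1L, 2L)])
  names(members) <- ids
  pathway_sets(members, names_ = descs)
}

#' @rdname read_gmt
#' @param pathways A `pathway_sets` collection.
#' @export
write_gmt <- function(pathways, path) {
  stopifnot(inherits(pathways, "pathway_sets"))
  lines <- vapply(pathways, function(p) {
    paste(c(p$pathway_id, p$name, p$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a differential-abundance result table
#'
#' Columns: `metabolite_id`, `mean_ref`, `mean_test`, `log2_fc`,
#' `fold_change`, `p_value`, `fdr`, `significant`, `direction`. Values
#' round-trip to within 1e-9 relative (full precision is written).
#'
#' @param results Nonempty data.frame as returned by
#'   [differential_abundance()].
#' @param path Output path (CSV or TSV).
#' @return `path` invisibly; `read_results()` returns the data.frame.
#' @export
write_results <- function(results, path) {
  results <- as.data.frame(results)
  if (nrow(results) == 0L) stop("refusing to write an empty result table")
  num <- vapply(results, is.numeric, TRUE)
  results[num] <- lapply(results[num], function(x) {
    formatC(x, digits = 17, format = "g")
  })
  utils::write.table(results, path, sep = sniff_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  if ("significant" %in% names(df)) df$significant <- as.logical(df$significant)
  df
}
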