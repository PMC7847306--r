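#' Intensity matrix constructor
#'
#' The central container: a metabolite x sample matrix of nonnegative LC-MS
#' peak intensities in which a value of exactly 0 encodes "not detected".
#' Metabolites are rows and samples are columns, the usual LC-MS layout.
#' Two provenance flags travel with the matrix: `normalized` (size-factor
#' scaling has been applied) and `log_scale` (values are log2 intensities).
#'
#' @param values Numeric matrix, metabolites in rows, samples in columns.
#'   All values must be finite and >= 0 (on the raw scale).
#' @param metabolite_ids,sample_ids Unique character ids; default to existing
#'   dimnames.
#' @param normalized,log_scale Provenance flags.
#' @return A numeric matrix of class `intensity_matrix` with dimnames set and
#'   `normalized` / `log_scale` attributes.
#' @export
intensity_matrix <- function(values,
                             metabolite_ids = rownames(values),
                             sample_ids = colnames(values),
                             normalized = FALSE,
                             log_scale = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("intensity values must be numeric")
  if (is.null(metabolite_ids) || is.null(sample_ids)) {
    stop("metabolite and sample ids are required (set dimnames or pass them)")
  }
  metabolite_ids <- as.character(metabolite_ids)
  sample_ids <- as.character(sample_ids)
  if (length(metabolite_ids) != nrow(values) ||
      length(sample_ids) != ncol(values)) {
    stop("id lengths do not match matrix dimensions")
  }
  if (anyDuplicated(metabolite_ids)) {
    stop("duplicate metabolite ids: ",
         paste(unique(metabolite_ids[duplicated(metabolite_ids)]),
               collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  dimnames(values) <- list(metabolite_ids, sample_ids)
  bad <- which(!is.finite(values) | (!log_scale & values < 0), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "invalid intensity at [%s, %s]: %s (values must be finite and >= 0)",
      metabolite_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]],
      format(values[bad[1L, , drop = FALSE]])
    ))
  }
  structure(values,
            normalized = isTRUE(normalized),
            log_scale = isTRUE(log_scale),
            class = c("intensity_matrix", "matrix", "array"))
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf(
    "intensity_matrix: %d metabolites x %d samples (%s scale%s)\n",
    nrow(x), ncol(x),
    if (isTRUE(attr(x, "log_scale"))) "log2" else "raw",
    if (isTRUE(attr(x, "normalized"))) ", normalized" else ""
  ))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE]))
  invisible(x)
}

is_log_scale <- function(m) isTRUE(attr(m, "log_scale"))
is_normalized <- function(m) isTRUE(attr(m, "normalized"))

# rebuild an intensity_matrix after elementwise transformation
im_like <- function(values, template, normalized = is_normalized(template),
                    log_scale = is_log_scale(template)) {
  intensity_matrix(values,
                   metabolite_ids = rownames(template),
                   sample_ids = colnames(template),
                   normalized = normalized, log_scale = log_scale)
}

#' Sample metadata constructor / validator
#'
#' Per-sample annotations tying samples to their experimental role. Blank
#' samples are sheath-fluid (or solvent) background injections; cell samples
#' carry a group label (cell type or condition). `batch` identifies the
#' independent experiment, `pair` links samples derived from the same animal
#' (used as a fixed-effect covariate), and `cell_number` records how many
#' cells were sorted or pipetted into the sample.
#'
#' @param df A data.frame with columns `sample_id`, `role`
#'   (`"blank"`/`"cell"`), `group`, and optional `batch`, `pair`,
#'   `cell_number`, `notes`.
#' @return The validated data.frame with class `sample_meta`, optional
#'   columns present (NA where absent).
#' @export
sample_meta <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("sample_id", "role", "group")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    stop("metadata lacks required column(s): ", paste(miss, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  df$role <- as.character(df$role)
  bad_role <- setdiff(unique(df$role), c("blank", "cell"))
  if (length(bad_role) > 0L) {
    stop("unknown role value(s): ", paste(bad_role, collapse = ", "),
         " (expected 'blank' or 'cell')")
  }
  df$group <- as.character(df$group)
  no_group <- df$role == "cell" & (is.na(df$group) | df$group == "")
  if (any(no_group)) {
    stop("cell sample(s) without a group: ",
         paste(df$sample_id[no_group], collapse = ", "))
  }
  for (opt in c("batch", "pair", "notes")) {
    if (!opt %in% names(df)) df[[opt]] <- NA_character_
    df[[opt]] <- as.character(df[[opt]])
    df[[opt]][!is.na(df[[opt]]) & df[[opt]] == ""] <- NA_character_
  }
  if (!"cell_number" %in% names(df)) df$cell_number <- NA_real_
  df$cell_number <- as.numeric(df$cell_number)
  if (any(!is.na(df$cell_number) & df$cell_number < 0)) {
    stop("cell_number must be nonnegative")
  }
  if (any(df$role == "blank" & !is.na(df$pair))) {
    stop("blank samples cannot carry a pair label")
  }
  pr <- df$pair[!is.na(df$pair)]
  singletons <- names(which(table(pr) < 2L))
  if (length(singletons) > 0L) {
    warning("pair label(s) occurring in a single sample: ",
            paste(singletons, collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("sample_meta", "data.frame")
  df
}

#' Pathway set collection constructor
#'
#' @param pathways Named list: `pathway_id` -> character vector of metabolite
#'   ids (nonempty).
#' @param names_ Optional human-readable names, same length.
#' @return A list of class `pathway_sets`; each element has `pathway_id`,
#'   `name` and `members`.
#' @export
pathway_sets <- function(pathways, names_ = NULL) {
  ids <- names(pathways)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("pathways must be a uniquely named list")
  }
  if (is.null(names_)) names_ <- ids
  out <- Map(function(id, nm, mem) {
    mem <- unique(as.character(mem))
    if (length(mem) == 0L) stop("pathway '", id, "' has no members")
    list(pathway_id = id, name = nm, members = mem)
  }, ids, names_, pathways)
  names(out) <- ids
  structure(out, class = "pathway_sets")
}

# align an intensity matrix with metadata: sample sets must be consistent
check_meta_match <- function(matrix, meta) {
  stopifnot(inherits(meta, "sample_meta"))
  missing <- setdiff(colnames(matrix), meta$sample_id)
  if (length(missing) > 0L) {
    stop("samples present in the matrix but absent from metadata: ",
         paste(missing, collapse = ", "))
  }
  meta[match(colnames(matrix), meta$sample_id), , drop = FALSE]
}
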