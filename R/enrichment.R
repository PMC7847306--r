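#' Upper-tail hypergeometric probability
#'
#' `P(X >= overlap)` where X counts pathway members among `n_sig` draws
#' without replacement from a universe of `n_universe` metabolites of which
#' `n_path` belong to the pathway. The over-representation p value of a
#' pathway given a significant set.
#'
#' @param overlap Observed members of the pathway among the significant set.
#' @param n_sig Size of the significant set.
#' @param n_path Pathway members present in the universe.
#' @param n_universe Universe size.
#' @return p value in (0, 1].
#' @export
hypergeom_tail <- function(overlap, n_sig, n_path, n_universe) {
  stopifnot(overlap >= 0, n_sig >= 0, n_path >= 0, n_universe >= 0)
  if (overlap > n_sig || overlap > n_path || n_path > n_universe ||
      n_sig > n_universe) {
    stop("inconsistent counts: need overlap <= n_sig, overlap <= n_path, ",
         "n_path <= n_universe, n_sig <= n_universe")
  }
  stats::phyper(overlap - 1, n_path, n_universe - n_path, n_sig,
                lower.tail = FALSE)
}

#' Pathway over-representation analysis
#'
#' One-sided hypergeometric (Fisher exact upper tail) test of each pathway's
#' overlap with the significant metabolite set, against the universe of
#' metabolites that were eligible for testing (typically those detected
#' above background). Pathways are intersected with the universe first;
#' those with fewer than `min_pathway_size` universe members are skipped.
#' p values are BH-adjusted across the tested pathways and a pathway is
#' called enriched at `fdr < enrichment_fdr` (default 0.01).
#'
#' @param significant_ids Metabolite ids called significant (must be a
#'   subset of the universe).
#' @param universe_ids Nonempty universe of tested metabolite ids.
#' @param pathways A [pathway_sets()] collection.
#' @param config An [analysis_config()].
#' @return Data.frame: `pathway_id`, `name`, `n_universe`,
#'   `n_pathway_in_universe`, `n_significant`, `n_overlap`, `p_value`,
#'   `fdr`, `enriched`.
#' @export
enrich <- function(significant_ids, universe_ids, pathways,
                   config = analysis_config()) {
  stopifnot(inherits(pathways, "pathway_sets"))
  universe_ids <- unique(as.character(universe_ids))
  if (length(universe_ids) == 0L) stop("empty metabolite universe")
  significant_ids <- unique(as.character(significant_ids))
  stray <- setdiff(significant_ids, universe_ids)
  if (length(stray) > 0L) {
    stop("significant ids outside the universe: ",
         paste(utils::head(stray, 5L), collapse = ", "))
  }
  rows <- lapply(pathways, function(p) {
    members <- intersect(p$members, universe_ids)
    if (length(members) < config$min_pathway_size) return(NULL)
    overlap <- length(intersect(members, significant_ids))
    data.frame(
      pathway_id = p$pathway_id, name = p$name,
      n_universe = length(universe_ids),
      n_pathway_in_universe = length(members),
      n_significant = length(significant_ids),
      n_overlap = overlap,
      p_value = hypergeom_tail(overlap, length(significant_ids),
                               length(members), length(universe_ids)),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    return(data.frame(pathway_id = character(0), name = character(0),
                      n_universe = integer(0),
                      n_pathway_in_universe = integer(0),
                      n_significant = integer(0), n_overlap = integer(0),
                      p_value = numeric(0), fdr = numeric(0),
                      enriched = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- benjamini_hochberg(out$p_value)
  out$enriched <- out$fdr < config$enrichment_fdr
  out[order(out$p_value), , drop = FALSE]
}
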