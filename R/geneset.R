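#' Normalize gene symbols
#'
#' Uppercases and strips surrounding whitespace so that, e.g., chicken-style
#' (all-caps) and mouse-style (title-case) symbols compare equal. Idempotent.
#'
#' @param x Character vector of gene symbols.
#' @return Normalized character vector.
#' @export
normalize_symbols <- function(x) {
  toupper(trimws(x))
}

#' Overlap of a query gene list with a curated gene set
#'
#' Computes the overlap count `k = |query intersect reference|`, the query
#' size `n`, the in-universe reference size `K`, the universe size `N`, the
#' overlap percentage `round(100 * k / n, 2)` and the upper-tail
#' hypergeometric p-value. Symbols are matched case-insensitively
#' (see [normalize_symbols()]); the reference is intersected with the
#' universe before counting; query genes outside the universe are dropped
#' with a message.
#'
#' @param query Character vector of query gene ids.
#' @param reference A gene set (list with `set_id`, `members`; see
#'   [read_gmt()]) or a plain character vector.
#' @param universe Character vector of universe gene ids (non-empty).
#' @param query_id Identifier recorded in the report.
#' @return A one-row data.frame with columns `query_id`, `set_id`, `k`, `n`,
#'   `K`, `N`, `percent`, `p`.
#' @export
overlap_report <- function(query, reference, universe, query_id = "query") {
  set_id <- "reference"
  if (is.list(reference)) {
    set_id <- reference$set_id
    reference <- reference$members
  }
  universe <- unique(normalize_symbols(universe))
  .check(length(universe) > 0L, "universe must be non-empty")
  query <- unique(normalize_symbols(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    message(length(outside), " query genes outside the universe dropped")
    query <- intersect(query, universe)
  }
  reference <- intersect(unique(normalize_symbols(reference)), universe)
  k <- length(intersect(query, reference))
  n <- length(query)
  K <- length(reference)
  N <- length(universe)
  p <- if (n == 0L || K == 0L) 1 else hypergeometric_tail(k, K, n, N)
  data.frame(query_id = query_id, set_id = set_id, k = k, n = n, K = K,
             N = N, percent = if (n == 0L) NA_real_ else round(100 * k / n, 2),
             p = p, stringsAsFactors = FALSE)
}

#' Over-representation analysis against a gene-set collection
#'
#' Runs [overlap_report()] for every set, adjusts p-values across sets with
#' Benjamini-Hochberg and sorts ascending by `q` then `p`.
#'
#' @param query Character vector of query gene ids.
#' @param sets A list of gene sets (see [read_gmt()]).
#' @param universe Character vector of universe gene ids.
#' @param alpha Significance level recorded for convenience; reports with
#'   `q <= alpha` are flagged in the `significant` column.
#' @param query_id Identifier recorded in the reports.
#' @return A data.frame of reports with added `q` and `significant` columns,
#'   one row per set, sorted by `q` then `p`.
#' @export
ora <- function(query, sets, universe, alpha = 0.05, query_id = "query") {
  .check(length(sets) >= 1L, "need at least one gene set")
  reports <- do.call(rbind, lapply(sets, overlap_report, query = query,
                                   universe = universe, query_id = query_id))
  rownames(reports) <- NULL
  reports$q <- bh_adjust(reports$p)
  reports$significant <- reports$q <= alpha
  reports <- reports[order(reports$q, reports$p, reports$set_id), ]
  rownames(reports) <- NULL
  reports
}
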