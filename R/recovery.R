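# Cited-references recovery.
#
# Reference-list scanning starts from the included studies a strategy DID
# retain: a missed record counts as recoverable iff some retained full-text
# include cites it. The proportion missed is then recomputed with the
# recovered records restored.

#' Recover missed records via the citation graph
#'
#' @param missed character vector of missed record ids (see
#'   [missed_records()]).
#' @param graph a [citation_graph()].
#' @param included_found the full-text includes the strategy retained
#'   (a missed record cannot be recovered via its own reference list).
#' @param n_fulltext total final-report includes, used to recompute the
#'   adjusted proportion missed; when `NULL` the percentages are omitted.
#' @param known_ids optional universe of record ids used to validate the
#'   graph's endpoints.
#' @return a `recovery_result`: list with `missed_before`, `recovered`,
#'   `missed_after`, `pct_recovered` (share of missed records recovered,
#'   rounded half-up), and — when `n_fulltext` is given — `missed_pct` and
#'   `adjusted_missed_pct` (proportion missed before/after recovery).
#' @export
recover_missed <- function(missed, graph, included_found,
                           n_fulltext = NULL, known_ids = NULL) {
  graph <- citation_graph(graph, known_ids = known_ids)
  missed <- unique(as.character(missed))
  cited_by_found <- graph$cited_id[graph$citing_id %in% included_found]
  recovered <- intersect(missed, cited_by_found)
  missed_after <- setdiff(missed, recovered)
  pct_recovered <- if (length(missed)) {
    round_half_up(100 * length(recovered) / length(missed))
  } else NA_real_
  out <- list(missed_before = missed, recovered = recovered,
              missed_after = missed_after, pct_recovered = pct_recovered)
  if (!is.null(n_fulltext)) {
    out$missed_pct <- proportion_missed(length(missed), n_fulltext)$pct
    out$adjusted_missed_pct <-
      proportion_missed(length(missed_after), n_fulltext)$pct
  }
  structure(out, class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("<recovery_result> %d missed, %d recovered via cited references, %d still missed\n",
              length(x$missed_before), length(x$recovered),
              length(x$missed_after)))
  if (!is.null(x$adjusted_missed_pct) && !is.na(x$adjusted_missed_pct)) {
    cat(sprintf("  proportion missed: %s%% -> %s%%\n",
                x$missed_pct, x$adjusted_missed_pct))
  }
  invisible(x)
}
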