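# Counts-only metric tabulation.
#
# Workload and time savings are pure arithmetic in (N, T, P, review type):
# no record-level data are needed. This closed-form path reproduces the
# published per-review savings/time tables from the reviews' printed
# characteristics (workloads and predicted-relevant counts) and doubles as
# an oracle for the record-level pipeline, which must agree with it exactly
# on every synthetic corpus.

#' Characteristics of the 17 emulated reviews
#'
#' The published per-review screening characteristics the package emulates
#' and recomputes from: per-reviewer workload, title/abstract and full-text
#' include counts, actual training screens (300 for the one review whose
#' predictions needed an extended training set, otherwise 200), training-set
#' includes, and the count of records the screening tool predicted relevant.
#'
#' @return data frame with columns `review`, `review_type`, `workload_n`,
#'   `ta_includes`, `ft_includes`, `screened_training`, `training_includes`,
#'   `predicted_relevant`.
#' @export
study_reviews <- function() {
  utils::read.csv(system.file("extdata", "review_characteristics.csv",
                              package = "screensim"),
                  check.names = FALSE, stringsAsFactors = FALSE)
}

#' Published per-review savings and time values
#'
#' The published workload/time table cells (savings records, savings
#' percentage, hours, days — days as character, `"<1"` below one day) for
#' each review and applicable strategy, used to cross-check the recomputed
#' tables. A handful of published cells are internally inconsistent with
#' their own inputs; [compare_with_reported()] flags them.
#'
#' @return data frame with columns `review`, `strategy`, `savings_records`,
#'   `savings_pct`, `hours`, `days`.
#' @export
reported_performance <- function() {
  utils::read.csv(system.file("extdata", "reported_performance.csv",
                              package = "screensim"),
                  check.names = FALSE, colClasses = c(days = "character"),
                  stringsAsFactors = FALSE)
}

#' Closed-form savings and time for all strategies from counts alone
#'
#' @param n per-reviewer workload N.
#' @param t_screened actual training screens T.
#' @param p hard-true predictions P among the N - T unscreened records.
#' @param review_type "systematic" or "rapid" (dual strategies apply only to
#'   systematic reviews).
#' @param tm a [time_model()].
#' @param nominal_training when `TRUE`, savings deduct the nominal
#'   `nominal_size`-record training set even if the actual training set was
#'   extended — the published reporting convention. Default `FALSE`
#'   (deduct the screens actually performed).
#' @param nominal_size nominal training-set size (200 records).
#' @return data frame with one row per strategy: `strategy`,
#'   `manual_screens`, `baseline_total`, `savings_records`, `savings_pct`,
#'   `hours`, `days` (character display), `days_raw`.
#' @export
tabulate_counts_only <- function(n, t_screened, p,
                                 review_type = c("systematic", "rapid"),
                                 tm = time_model(),
                                 nominal_training = FALSE,
                                 nominal_size = 200L) {
  review_type <- match.arg(review_type)
  if (t_screened > n) stop_("training screens exceed N")
  if (p > n - t_screened) stop_("P exceeds the N - T unscreened records")
  t_eff <- if (nominal_training) min(nominal_size, t_screened) else t_screened
  base <- baseline_total(n, review_type)
  strategies <- if (review_type == "systematic") {
    c("single_full_auto", "single_semi_auto", "dual_full_auto",
      "dual_semi_auto")
  } else {
    c("single_full_auto", "single_semi_auto")
  }
  rows <- lapply(strategies, function(s) {
    manual <- switch(s,
      single_full_auto = t_eff,
      single_semi_auto = t_eff + p,
      dual_full_auto   = t_eff + n,
      dual_semi_auto   = t_eff + p + n)
    sav <- workload_savings(manual, base)
    tim <- time_savings(sav$records, tm)
    data.frame(strategy = s, manual_screens = manual, baseline_total = base,
               savings_records = sav$records, savings_pct = sav$pct,
               hours = tim$hours, days = tim$days_display,
               days_raw = tim$days_raw)
  })
  do.call(rbind, rows)
}

#' Recompute the per-review savings/time table
#'
#' Applies [tabulate_counts_only()] to every review in `reviews`.
#'
#' @param reviews data frame in the layout of [study_reviews()].
#' @param tm a [time_model()].
#' @param nominal_training see [tabulate_counts_only()]; `TRUE` matches the
#'   published convention.
#' @return data frame: `review`, `review_type` plus the
#'   [tabulate_counts_only()] columns.
#' @export
performance_table <- function(reviews = study_reviews(), tm = time_model(),
                              nominal_training = TRUE) {
  rows <- lapply(seq_len(nrow(reviews)), function(i) {
    r <- reviews[i, ]
    tab <- tabulate_counts_only(r$workload_n, r$screened_training,
                                r$predicted_relevant, r$review_type,
                                tm = tm, nominal_training = nominal_training)
    cbind(review = r$review, review_type = r$review_type, tab)
  })
  do.call(rbind, rows)
}

#' Compare recomputed savings/time cells with the published values
#'
#' Joins the recomputed table with the published one and flags every cell
#' whose published value disagrees with its own arithmetic. Recomputed
#' values are authoritative; discrepancies are reported, never silently
#' matched.
#'
#' @param computed a [performance_table()] result.
#' @param reported the published values, see [reported_performance()].
#' @return data frame with computed and reported columns plus logical
#'   `match_records`, `match_pct`, `match_hours`, `match_days` and
#'   `all_match`; the attribute `"mismatches"` holds a data frame of the
#'   flagged cells (review, strategy, field, reported, computed).
#' @export
compare_with_reported <- function(computed = performance_table(),
                                  reported = reported_performance()) {
  m <- merge(reported, computed, by = c("review", "strategy"),
             suffixes = c("_reported", "_computed"))
  if (nrow(m) != nrow(reported)) {
    stop_("recomputed table does not cover every published row")
  }
  m$match_records <- m$savings_records_reported == m$savings_records_computed
  m$match_pct <- m$savings_pct_reported == m$savings_pct_computed
  m$match_hours <- m$hours_reported == m$hours_computed
  m$match_days <- m$days_reported == m$days_computed
  m$all_match <- m$match_records & m$match_pct & m$match_hours & m$match_days
  mm <- list()
  fields <- c(records = "savings_records", pct = "savings_pct",
              hours = "hours", days = "days")
  for (f in names(fields)) {
    bad <- !m[[paste0("match_", f)]]
    if (any(bad)) {
      mm[[f]] <- data.frame(
        review = m$review[bad], strategy = m$strategy[bad], field = fields[[f]],
        reported = as.character(m[[paste0(fields[[f]], "_reported")]][bad]),
        computed = as.character(m[[paste0(fields[[f]], "_computed")]][bad]))
    }
  }
  attr(m, "mismatches") <- if (length(mm)) do.call(rbind, mm) else
    data.frame(review = character(), strategy = character(),
               field = character(), reported = character(),
               computed = character())
  rownames(attr(m, "mismatches")) <- NULL
  m
}
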