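# Performance-metric calculus.
#
# Three metrics from 2x2 cross-tabulations of the strategy's title/abstract
# consensus against the final-report includes:
#   proportion missed  = fn / (tp + fn), among final-report includes
#   workload savings   = baseline_total - manual_screens (and % of baseline)
#   time savings       = records saved x 0.5 min, in hours and 8-h days
# The manual baseline is 2N screens for systematic reviews (dual independent
# screening) and N for rapid reviews (single reviewer). Displayed values are
# rounded half-up; days render "<1" when below one working day.

#' Screening time model
#'
#' @param minutes_per_record screening rate (default 0.5 min/record).
#' @param hours_per_day working-day length (default 8 h).
#' @return a `time_model` object.
#' @export
time_model <- function(minutes_per_record = 0.5, hours_per_day = 8) {
  assert_scalar_number(minutes_per_record, "minutes_per_record", 1e-9)
  assert_scalar_number(hours_per_day, "hours_per_day", 1e-9)
  structure(list(minutes_per_record = minutes_per_record,
                 hours_per_day = hours_per_day), class = "time_model")
}

#' Manual-screening baseline for a review
#'
#' The number of human title/abstract screens the conventional workflow
#' consumes: every record twice under dual independent screening
#' (systematic), once under single-reviewer screening (rapid).
#'
#' @param x a [review_dataset()], or the workload N as a number.
#' @param review_type required when `x` is a number.
#' @return integer total screens.
#' @export
baseline_total <- function(x, review_type = NULL) {
  if (inherits(x, "review_dataset")) {
    n <- x$workload_n
    review_type <- x$review_type
  } else {
    n <- x
    review_type <- match.arg(review_type, c("systematic", "rapid"))
  }
  as.integer(if (review_type == "systematic") 2L * n else n)
}

#' 2x2 cross-tabulation of a strategy's consensus against the final report
#'
#' @param result a `strategy_result`.
#' @param dataset the [review_dataset()].
#' @return a `confusion_table` with `tp` (final-report includes retained at
#'   title/abstract), `fn` (missed), `fp` (forwarded but not in the final
#'   report), `tn`.
#' @export
confusion_table <- function(result, dataset) {
  stopifnot(inherits(result, "strategy_result"),
            inherits(dataset, "review_dataset"))
  ft <- dataset$fulltext_includes
  cons <- result$consensus_includes
  tp <- length(intersect(ft, cons))
  fn <- length(setdiff(ft, cons))
  fp <- length(setdiff(cons, ft))
  tn <- dataset$workload_n - tp - fn - fp
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2,
              dimnames = list(c("forwarded", "excluded"),
                              c("in final report", "not in report")))
  print(m)
  invisible(x)
}

#' Proportion of final-report includes missed
#'
#' @param table a [confusion_table()], or the missed count `fn` (with
#'   `total` = tp + fn supplied).
#' @param total total final-report includes, when `table` is a count.
#' @return list with `n` (missed records), `pct` (display percentage,
#'   rounded half-up) and `pct_raw`. When the review has zero final-report
#'   includes the proportion is undefined and both percentages are `NA`
#'   ("not applicable").
#' @export
proportion_missed <- function(table, total = NULL) {
  if (inherits(table, "confusion_table")) {
    fn <- table$fn
    total <- table$tp + table$fn
  } else {
    fn <- table
    if (is.null(total)) stop_("`total` (tp + fn) is required")
  }
  if (total == 0L) {
    return(list(n = fn, pct = NA_real_, pct_raw = NA_real_,
                note = "not applicable: zero final-report includes"))
  }
  raw <- 100 * fn / total
  list(n = fn, pct = round_half_up(raw), pct_raw = raw)
}

#' Workload savings
#'
#' @param manual_screens human title/abstract screens a strategy consumes.
#' @param baseline_total the manual baseline, see [baseline_total()].
#' @return list with `records` (screens saved), `pct` (display percentage,
#'   rounded half-up) and `pct_raw`.
#' @export
workload_savings <- function(manual_screens, baseline_total) {
  if (manual_screens > baseline_total) {
    stop_("manual screens (", manual_screens, ") exceed the baseline (",
          baseline_total, "): strategy accounting error")
  }
  records <- baseline_total - manual_screens
  raw <- if (baseline_total > 0) 100 * records / baseline_total else 0
  list(records = as.integer(records), pct = round_half_up(raw), pct_raw = raw)
}

#' Time savings
#'
#' @param records screens saved.
#' @param tm a [time_model()].
#' @return list with `hours` (display, rounded half-up), `hours_raw`,
#'   `days_raw`, `days` (rounded half-up) and `days_display` (the character
#'   rendering, `"<1"` below one day).
#' @export
time_savings <- function(records, tm = time_model()) {
  stopifnot(records >= 0)
  hours_raw <- records * tm$minutes_per_record / 60
  days_raw <- hours_raw / tm$hours_per_day
  list(hours = round_half_up(hours_raw), hours_raw = hours_raw,
       days = round_half_up(days_raw), days_raw = days_raw,
       days_display = if (days_raw < 1) "<1" else
         as.character(round_half_up(days_raw)))
}

#' Median and range of per-review values
#'
#' The reporting convention for per-review metrics: median (middle value,
#' or mean of the two middle values) with the min-to-max range.
#'
#' @param values non-empty numeric vector.
#' @return a `summary_stat` with `median`, `min`, `max`.
#' @export
aggregate_summary <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop_("no values to aggregate")
  structure(list(median = stats::median(values), min = min(values),
                 max = max(values)), class = "summary_stat")
}

#' @export
format.summary_stat <- function(x, ...) {
  sprintf("%s (%s to %s)", x$median, x$min, x$max)
}

#' @export
print.summary_stat <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' All performance metrics for one strategy result
#'
#' @param result a `strategy_result`.
#' @param dataset the [review_dataset()].
#' @param tm a [time_model()].
#' @return a `performance_metrics` list: `strategy`, `missed` (from
#'   [proportion_missed()]), `savings` (from [workload_savings()]), `time`
#'   (from [time_savings()]), `baseline_total`, `manual_screens`.
#' @export
performance_metrics <- function(result, dataset, tm = time_model()) {
  ct <- confusion_table(result, dataset)
  base <- baseline_total(dataset)
  sav <- workload_savings(result$manual_screens, base)
  structure(list(review = dataset$name, strategy = result$strategy,
                 missed = proportion_missed(ct),
                 savings = sav, time = time_savings(sav$records, tm),
                 baseline_total = base,
                 manual_screens = result$manual_screens,
                 confusion = ct),
            class = "performance_metrics")
}

#' @export
print.performance_metrics <- function(x, ...) {
  pm <- if (is.na(x$missed$pct)) "n/a" else sprintf("%d (%s%%)",
                                                    x$missed$n, x$missed$pct)
  cat(sprintf("%s / %s\n", x$review, x$strategy))
  cat(sprintf("  proportion missed:  %s\n", pm))
  cat(sprintf("  workload savings:   %d of %d (%s%%)\n",
              x$savings$records, x$baseline_total, x$savings$pct))
  cat(sprintf("  time savings:       %s h (%s days)\n",
              x$time$hours, x$time$days_display))
  invisible(x)
}
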