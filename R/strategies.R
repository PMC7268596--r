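# Screening strategies.
#
# Four ways to leverage the classifier's hard predictions, plus two human
# baselines. T = actual training screens, P = hard-true predictions among
# the N - T unscreened records, N = per-reviewer workload. Per-record
# consensus (include = forwarded to full text):
#
#   single_full_auto     (training & senior-include) | (unscreened & hard)
#                        manual screens = T
#   single_semi_auto     (training & senior-include) | (hard & senior-include)
#                        manual screens = T + P   (senior verifies the P
#                        predicted-relevant records)
#   dual_full_auto       second-include | (training & senior-include) | hard
#                        manual screens = T + N   (second screens everything)
#   dual_semi_auto       second-include | (training & senior-include) |
#                        (hard & senior-include)
#                        manual screens = T + P + N
#   baseline_second_only second-include; manual screens = N
#   baseline_human       systematic: senior | second, manual screens = 2N
#                        rapid: senior, manual screens = N
#
# Training-set records always carry the senior's recorded decision into the
# consensus; in semi-automated modes the senior "verification" decision
# reuses the recorded decision for that record (retrospective design).

STRATEGIES <- c("single_full_auto", "single_semi_auto",
                "dual_full_auto", "dual_semi_auto",
                "baseline_second_only", "baseline_human")

#' Apply a screening strategy
#'
#' @param dataset a [review_dataset()].
#' @param predictions a `prediction_set` covering exactly the records outside
#'   `training_set` (not needed for the human baselines).
#' @param training_set the `training_set` used to fit the model (not needed
#'   for the human baselines).
#' @param strategy one of `"single_full_auto"`, `"single_semi_auto"`,
#'   `"dual_full_auto"`, `"dual_semi_auto"`, `"baseline_second_only"`,
#'   `"baseline_human"`. Dual strategies and the second-reviewer baseline
#'   require a systematic dataset.
#' @return a `strategy_result`: list with `strategy`, `consensus_includes`
#'   (record ids forwarded to full text), `manual_screens` (total human
#'   title/abstract screens consumed) and its `components`
#'   (training / senior / second screens).
#' @export
apply_strategy <- function(dataset, predictions = NULL, training_set = NULL,
                           strategy = STRATEGIES) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(dataset, "review_dataset"))
  dec <- dataset$decisions
  N <- dataset$workload_n
  ids <- dataset$records$record_id
  senior_inc <- dec$record_id[dec$senior == "include"]
  needs_second <- strategy %in% c("dual_full_auto", "dual_semi_auto",
                                  "baseline_second_only")
  if ((needs_second || (strategy == "baseline_human" &&
                        dataset$review_type == "systematic")) &&
      dataset$review_type != "systematic") {
    stop_("strategy '", strategy, "' requires a systematic dataset with a ",
          "second reviewer; '", dataset$name, "' is rapid")
  }
  second_inc <- if (dataset$review_type == "systematic")
    dec$record_id[!is.na(dec$second) & dec$second == "include"]
  else character()

  if (strategy == "baseline_second_only") {
    return(new_strategy_result(strategy, second_inc,
                               c(training = 0L, senior = 0L, second = N), ids))
  }
  if (strategy == "baseline_human") {
    if (dataset$review_type == "systematic") {
      return(new_strategy_result(strategy, union(senior_inc, second_inc),
                                 c(training = 0L, senior = N, second = N), ids))
    }
    return(new_strategy_result(strategy, senior_inc,
                               c(training = 0L, senior = N, second = 0L), ids))
  }

  stopifnot(inherits(predictions, "prediction_set"),
            inherits(training_set, "training_set"))
  unscreened <- setdiff(ids, training_set$record_id)
  if (!setequal(predictions$record_id, unscreened)) {
    stop_("predictions must cover exactly the unscreened records ",
          "(training set and predictions overlap or are incomplete)")
  }
  Tn <- attr(training_set, "size")
  P <- attr(predictions, "P")
  train_inc <- intersect(training_set$record_id, senior_inc)
  hard_true <- predictions$record_id[predictions$hard]

  consensus <- switch(strategy,
    single_full_auto = union(train_inc, hard_true),
    single_semi_auto = union(train_inc, intersect(hard_true, senior_inc)),
    dual_full_auto   = Reduce(union, list(second_inc, train_inc, hard_true)),
    dual_semi_auto   = Reduce(union, list(second_inc, train_inc,
                                          intersect(hard_true, senior_inc))))
  components <- switch(strategy,
    single_full_auto = c(training = Tn, senior = 0L, second = 0L),
    single_semi_auto = c(training = Tn, senior = P, second = 0L),
    dual_full_auto   = c(training = Tn, senior = 0L, second = N),
    dual_semi_auto   = c(training = Tn, senior = P, second = N))
  new_strategy_result(strategy, consensus, components, ids)
}

new_strategy_result <- function(strategy, consensus, components, ids) {
  consensus <- sort(unique(as.character(consensus)))
  stopifnot(all(consensus %in% ids))
  structure(list(strategy = strategy, consensus_includes = consensus,
                 manual_screens = as.integer(sum(components)),
                 components = as.integer(components) |>
                   stats::setNames(names(components))),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result> %s: %d consensus includes, %d manual screens",
              x$strategy, length(x$consensus_includes), x$manual_screens),
      sprintf("(training %d + senior %d + second %d)\n",
              x$components[["training"]], x$components[["senior"]],
              x$components[["second"]]))
  invisible(x)
}

#' Final-report records missed by a strategy
#'
#' The records included in the final report that the strategy's
#' title/abstract consensus excluded.
#'
#' @param result a `strategy_result`.
#' @param dataset the [review_dataset()] it was computed on.
#' @return character vector of missed record ids.
#' @export
missed_records <- function(result, dataset) {
  stopifnot(inherits(result, "strategy_result"),
            inherits(dataset, "review_dataset"))
  setdiff(dataset$fulltext_includes, result$consensus_includes)
}
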