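# End-to-end orchestration: corpus -> training -> predictions -> strategies
# -> metrics -> cited-references recovery, under one master seed.

#' Run the full screening simulation on one review
#'
#' Executes the whole pipeline: grow a random training set until predictions
#' become available, fit the relevance classifier, score the unscreened
#' records, apply the requested screening strategies, compute the
#' performance metrics for each, and (when a citation graph is supplied or
#' generated) run the cited-references recovery for each strategy. Every
#' stochastic stage draws a named sub-seed from `seed`, so the same inputs
#' and seed reproduce the bundle exactly.
#'
#' @param dataset a [review_dataset()], or a [synthetic_config()] from which
#'   one is generated.
#' @param strategies strategies to apply (see [apply_strategy()]); defaults
#'   to the four automated/semi-automated approaches applicable to the
#'   review type plus the human baselines.
#' @param training_size,batch,min_includes training protocol, see
#'   [grow_training_set()].
#' @param terms optional [term_labels()] for dual supervision.
#' @param delta,lambda,threshold classifier configuration, see
#'   [fit_relevance_model()].
#' @param tm a [time_model()].
#' @param graph a [citation_graph()], `TRUE` to simulate one with
#'   `rho`, or `NULL` to skip recovery.
#' @param rho per-pair citation probability when simulating the graph.
#' @param seed master integer seed.
#' @param out_dir when non-`NULL`, writes predictions, per-strategy consensus
#'   CSVs, a metrics CSV and a JSON run manifest there.
#' @return a `simulation_run`: list with `dataset`, `training_set`, `model`,
#'   `predictions`, and per-strategy entries (`result`, `metrics`, `missed`,
#'   `recovery`), plus a `manifest` of counts (N, T, P, availability
#'   batches, seed).
#' @export
run_screening_simulation <- function(dataset,
                                     strategies = NULL,
                                     training_size = 200, batch = 100,
                                     min_includes = 2,
                                     terms = NULL, delta = 2, lambda = 1,
                                     threshold = 0.5,
                                     tm = time_model(),
                                     graph = NULL, rho = 0.59,
                                     seed = 1L, out_dir = NULL) {
  seeds <- derive_seeds(seed, 3L)
  if (inherits(dataset, "synthetic_config")) {
    dataset$seed <- seeds[1]
    dataset <- generate_corpus(dataset)
  }
  stopifnot(inherits(dataset, "review_dataset"))
  if (is.null(strategies)) {
    strategies <- if (dataset$review_type == "systematic") {
      c("single_full_auto", "single_semi_auto", "dual_full_auto",
        "dual_semi_auto", "baseline_second_only", "baseline_human")
    } else {
      c("single_full_auto", "single_semi_auto", "baseline_human")
    }
  }
  bad <- setdiff(strategies, STRATEGIES)
  if (length(bad)) stop_("unknown strategy: ", paste(bad, collapse = ", "))
  if (dataset$review_type == "rapid" &&
      any(strategies %in% c("dual_full_auto", "dual_semi_auto",
                            "baseline_second_only"))) {
    stop_("config error for review '", dataset$name, "': dual-reviewer ",
          "strategies require a systematic dataset")
  }

  ts <- grow_training_set(dataset, size = training_size, batch = batch,
                          min_includes = min_includes, seed = seeds[2])
  model <- fit_relevance_model(dataset, ts, terms = terms, delta = delta,
                               lambda = lambda, threshold = threshold)
  preds <- predict(model, dataset, ts)

  if (isTRUE(graph)) {
    graph <- generate_citation_graph(dataset, rho = rho, seed = seeds[3])
  }

  per_strategy <- lapply(strategies, function(s) {
    res <- apply_strategy(dataset, preds, ts, s)
    met <- performance_metrics(res, dataset, tm)
    miss <- missed_records(res, dataset)
    rec <- if (inherits(graph, "citation_graph")) {
      recover_missed(miss, graph,
                     included_found = intersect(dataset$fulltext_includes,
                                                res$consensus_includes),
                     n_fulltext = length(dataset$fulltext_includes),
                     known_ids = dataset$records$record_id)
    }
    list(result = res, metrics = met, missed = miss, recovery = rec)
  })
  names(per_strategy) <- strategies

  manifest <- list(
    review = dataset$name, review_type = dataset$review_type,
    n = dataset$workload_n,
    t_screened = attr(ts, "size"),
    availability_batches = (attr(ts, "size") - training_size) / batch,
    p_predicted_relevant = attr(preds, "P"),
    n_fulltext_includes = length(dataset$fulltext_includes),
    strategies = strategies, seed = as.integer(seed))

  run <- structure(list(dataset = dataset, training_set = ts, model = model,
                        predictions = preds, strategies = per_strategy,
                        manifest = manifest),
                   class = "simulation_run")
  if (!is.null(out_dir)) write_simulation_run(run, out_dir)
  run
}

#' @export
print.simulation_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<simulation_run> %s (%s): N = %d, T = %d, P = %d\n",
              m$review, m$review_type, m$n, m$t_screened,
              m$p_predicted_relevant))
  for (s in names(x$strategies)) {
    met <- x$strategies[[s]]$metrics
    pm <- if (is.na(met$missed$pct)) "n/a" else
      sprintf("%d (%s%%)", met$missed$n, met$missed$pct)
    cat(sprintf("  %-22s missed %s, savings %d (%s%%), %s h\n", s, pm,
                met$savings$records, met$savings$pct, met$time$hours))
  }
  invisible(x)
}

#' Write a simulation run's outputs to a directory
#'
#' Writes `predictions.csv`, one `consensus_<strategy>.csv` per strategy
#' (`record_id, consensus` 0/1), `metrics.csv`, and `manifest.json`.
#'
#' @param run a `simulation_run`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_simulation_run <- function(run, dir) {
  stopifnot(inherits(run, "simulation_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_predictions_csv(run$predictions, file.path(dir, "predictions.csv"))
  ids <- run$dataset$records$record_id
  met_rows <- lapply(names(run$strategies), function(s) {
    st <- run$strategies[[s]]
    utils::write.csv(
      data.frame(record_id = ids, strategy = s,
                 consensus = as.integer(ids %in%
                                          st$result$consensus_includes)),
      file.path(dir, paste0("consensus_", s, ".csv")), row.names = FALSE)
    met <- st$metrics
    data.frame(review = met$review, strategy = s,
               missed_n = met$missed$n, missed_pct = met$missed$pct,
               savings_records = met$savings$records,
               savings_pct = met$savings$pct,
               hours = met$time$hours, days = met$time$days_display,
               manual_screens = met$manual_screens,
               baseline_total = met$baseline_total,
               recovered_n = if (!is.null(st$recovery))
                 length(st$recovery$recovered) else NA_integer_)
  })
  utils::write.csv(do.call(rbind, met_rows), file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
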