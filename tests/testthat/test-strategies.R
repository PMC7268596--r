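# record-level oracle for each strategy's consensus rule
oracle_consensus <- function(dataset, training_set, hard_ids, strategy) {
  dec <- dataset$decisions
  vapply(dataset$records$record_id, function(id) {
    i <- match(id, dec$record_id)
    senior <- dec$senior[i] == "include"
    second <- !is.na(dec$second[i]) && dec$second[i] == "include"
    in_train <- id %in% training_set$record_id
    hard <- id %in% hard_ids
    switch(strategy,
      single_full_auto = (in_train && senior) || (!in_train && hard),
      single_semi_auto = (in_train && senior) || (hard && senior),
      dual_full_auto   = second || (in_train && senior) || hard,
      dual_semi_auto   = second || (in_train && senior) || (hard && senior),
      baseline_second_only = second,
      baseline_human = senior || second)
  }, logical(1))
}

test_that("strategy consensus matches the per-record oracle", {
  for (seed in 1:4) {
    d <- make_random_dataset(80, seed = seed)
    ts <- draw_training_set(d, 25, seed = seed + 10)
    hard_ids <- withr::with_seed(seed, {
      un <- setdiff(d$records$record_id, ts$record_id)
      sample(un, 20)
    })
    preds <- make_predictions(d, ts, hard_ids)
    for (s in c("single_full_auto", "single_semi_auto", "dual_full_auto",
                "dual_semi_auto", "baseline_second_only", "baseline_human")) {
      res <- apply_strategy(d, preds, ts, s)
      want <- oracle_consensus(d, ts, hard_ids, s)
      expect_setequal(res$consensus_includes,
                      d$records$record_id[want])
    }
  }
})

test_that("manual screening counts follow the component arithmetic", {
  d <- make_random_dataset(80, seed = 2)
  ts <- draw_training_set(d, 25, seed = 5)
  preds <- make_predictions(d, ts,
                            setdiff(d$records$record_id, ts$record_id)[1:17])
  N <- d$workload_n
  Tn <- 25
  P <- attr(preds, "P")
  expect_equal(P, 17)
  want <- list(single_full_auto = Tn, single_semi_auto = Tn + P,
               dual_full_auto = Tn + N, dual_semi_auto = Tn + P + N,
               baseline_second_only = N, baseline_human = 2 * N)
  for (s in names(want)) {
    res <- apply_strategy(d, preds, ts, s)
    expect_equal(res$manual_screens, want[[s]])
    expect_equal(sum(res$components), res$manual_screens)
  }
  rap <- make_random_dataset(40, review_type = "rapid", seed = 3)
  expect_equal(apply_strategy(rap, strategy = "baseline_human")$manual_screens,
               40)
})

test_that("consensus sets nest: semi within fully, single within dual", {
  for (seed in 1:4) {
    d <- make_random_dataset(100, seed = seed + 20)
    ts <- draw_training_set(d, 30, seed = seed)
    un <- setdiff(d$records$record_id, ts$record_id)
    preds <- make_predictions(d, ts,
                              withr::with_seed(seed, sample(un, 25)))
    cons <- lapply(c(single_full_auto = "single_full_auto",
                     single_semi_auto = "single_semi_auto",
                     dual_full_auto = "dual_full_auto",
                     dual_semi_auto = "dual_semi_auto"),
                   function(s) apply_strategy(d, preds, ts, s)$consensus_includes)
    expect_true(all(cons$single_semi_auto %in% cons$single_full_auto))
    expect_true(all(cons$dual_semi_auto %in% cons$dual_full_auto))
    expect_true(all(cons$single_full_auto %in% cons$dual_full_auto))
    expect_true(all(cons$single_semi_auto %in% cons$dual_semi_auto))
    # hence missed counts are anti-monotone
    miss <- lapply(names(cons), function(s)
      length(missed_records(apply_strategy(d, preds, ts, s), d)))
    names(miss) <- names(cons)
    expect_gte(miss$single_semi_auto, miss$single_full_auto)
    expect_gte(miss$dual_semi_auto, miss$dual_full_auto)
    expect_gte(miss$single_full_auto, miss$dual_full_auto)
    expect_gte(miss$single_semi_auto, miss$dual_semi_auto)
  }
})

test_that("a perfect classifier with an error-free senior misses nothing", {
  cfg <- synthetic_config(n_records = 900, prevalence_ta = 0.12,
                          senior_profile = reviewer_profile(1, 1), seed = 6)
  d <- generate_corpus(cfg)
  ts <- draw_training_set(d, 200, seed = 2)
  truth_ids <- d$records$record_id[d$records$truth_ta]
  preds <- make_predictions(d, ts, truth_ids)  # hard = truth_ta
  for (s in c("single_full_auto", "single_semi_auto", "dual_full_auto",
              "dual_semi_auto")) {
    expect_length(missed_records(apply_strategy(d, preds, ts, s), d), 0)
  }
})

test_that("degenerate and invalid strategy inputs are handled", {
  d <- make_random_dataset(50, seed = 9)
  ts <- draw_training_set(d, 20, seed = 1)
  none <- make_predictions(d, ts, character())  # P = 0
  res <- apply_strategy(d, none, ts, "single_full_auto")
  train_inc <- intersect(ts$record_id,
                         d$decisions$record_id[d$decisions$senior == "include"])
  expect_setequal(res$consensus_includes, train_inc)

  rap <- make_random_dataset(30, review_type = "rapid", seed = 4)
  tsr <- draw_training_set(rap, 10, seed = 1)
  pr <- make_predictions(rap, tsr, character())
  expect_error(apply_strategy(rap, pr, tsr, "dual_full_auto"), "systematic")
  expect_error(apply_strategy(rap, pr, tsr, "baseline_second_only"),
               "systematic")

  # predictions overlapping the training set are rejected
  overlap <- prediction_set(d$records$record_id[1:30], rep(0, 30))
  expect_error(apply_strategy(d, overlap, ts, "single_full_auto"),
               "exactly the unscreened")
})

test_that("missed records are the set difference with the final report", {
  d <- make_tiny_dataset(8, senior_inc = c("rec1", "rec2", "rec3"),
                         second_inc = "rec4",
                         ft_inc = c("rec1", "rec2", "rec4"))
  ts <- screensim:::new_training_set(c("rec5", "rec6"), d)
  preds <- make_predictions(d, ts, c("rec1"))
  res <- apply_strategy(d, preds, ts, "single_full_auto")
  expect_setequal(res$consensus_includes, "rec1")
  expect_setequal(missed_records(res, d), c("rec2", "rec4"))

  full <- apply_strategy(d, preds, ts, "baseline_human")
  expect_length(missed_records(full, d), 0)  # consensus covers the report
})
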