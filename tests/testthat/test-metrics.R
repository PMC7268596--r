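test_that("half-up rounding follows the display convention", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.5, 2.49, -0.2)), c(1, 2, 3, 2, 0))
  expect_equal(round_half_up(94.483), 94)
  # values that are .5 only up to binary representation error still round up
  expect_equal(round_half_up(100 * 4892 / 10184), 48)
})

test_that("the manual baseline doubles for dual independent screening", {
  expect_equal(baseline_total(12156, "systematic"), 24312)
  expect_equal(baseline_total(1536, "rapid"), 1536)
  expect_equal(baseline_total(0, "rapid"), 0)
  d <- make_random_dataset(30, seed = 1)
  expect_equal(baseline_total(d), 60)
})

test_that("proportion missed comes from the 2x2 cross-tabulation", {
  expect_equal(proportion_missed(35, 127)$pct, 28)
  expect_equal(proportion_missed(8, 21)$pct, 38)
  expect_equal(proportion_missed(0, 40)$pct, 0)
  na_case <- proportion_missed(0, 0)
  expect_true(is.na(na_case$pct))
  expect_match(na_case$note, "not applicable")

  d <- make_tiny_dataset(8, senior_inc = c("rec1", "rec2"),
                         second_inc = "rec3",
                         ft_inc = c("rec1", "rec3"))
  ts <- screensim:::new_training_set(c("rec7", "rec8"), d)
  res <- apply_strategy(d, make_predictions(d, ts, "rec1"), ts,
                        "single_full_auto")
  ct <- confusion_table(res, d)
  expect_equal(ct$tp + ct$fn, length(d$fulltext_includes))
  expect_equal(ct$tp + ct$fn + ct$fp + ct$tn, d$workload_n)
  expect_equal(proportion_missed(ct)$n, length(missed_records(res, d)))
})

test_that("workload savings follow the published arithmetic", {
  s <- workload_savings(200, 24312)
  expect_equal(s$records, 24112)
  expect_equal(s$pct, 99)
  s2 <- workload_savings(14473, 24312)
  expect_equal(s2$records, 9839)
  expect_equal(s2$pct, 40)
  expect_equal(workload_savings(500, 500)$records, 0)
  expect_error(workload_savings(600, 500), "accounting")
})

test_that("time savings convert at 0.5 min per record and 8-h days", {
  t1 <- time_savings(24112)
  expect_equal(t1$hours, 201)
  expect_equal(t1$days_display, "25")
  expect_equal(time_savings(6062)$hours, 51)
  expect_equal(time_savings(0)$hours, 0)
  expect_equal(time_savings(451)$days_display, "<1")  # 3.8 h
  # a custom time model scales linearly
  t2 <- time_savings(1200, time_model(minutes_per_record = 1,
                                      hours_per_day = 6))
  expect_equal(t2$hours, 20)
  expect_equal(t2$days_display, "3")
})

test_that("median-and-range aggregation is sort-invariant", {
  vals <- c(56, 87, 79, 87, 92, 74)
  agg <- aggregate_summary(vals)
  expect_equal(agg$median, 83)
  expect_equal(c(agg$min, agg$max), c(56, 92))
  for (i in 1:3) {
    perm <- withr::with_seed(i, sample(vals))
    expect_equal(aggregate_summary(perm), agg)
  }
  single <- aggregate_summary(5)
  expect_equal(unlist(single[c("median", "min", "max")],
                      use.names = FALSE), c(5, 5, 5))
  expect_error(aggregate_summary(numeric()), "no values")
  expect_equal(format(agg), "83 (56 to 92)")
})

test_that("closed-form savings equal a brute-force count of screening events", {
  # event-log oracle: one event per human screen — every training record,
  # every predicted-relevant record in semi modes (senior verification),
  # every record screened by the second reviewer
  for (seed in 1:3) {
    d <- make_random_dataset(90, seed = seed + 40)
    ts <- draw_training_set(d, 30, seed = seed)
    un <- setdiff(d$records$record_id, ts$record_id)
    hard <- withr::with_seed(seed, sample(un, 33))
    preds <- make_predictions(d, ts, hard)
    base <- baseline_total(d)
    for (s in c("single_full_auto", "single_semi_auto", "dual_full_auto",
                "dual_semi_auto")) {
      events <- c(
        ts$record_id,                                    # training screens
        if (s %in% c("single_semi_auto", "dual_semi_auto")) hard,
        if (s %in% c("dual_full_auto", "dual_semi_auto"))
          d$records$record_id)                           # second reviewer
      res <- apply_strategy(d, preds, ts, s)
      expect_equal(res$manual_screens, length(events))
      expect_equal(performance_metrics(res, d)$savings$records,
                   base - length(events))
    }
  }
})

test_that("performance metrics bundle is internally consistent", {
  d <- make_random_dataset(120, seed = 77)
  ts <- draw_training_set(d, 40, seed = 3)
  un <- setdiff(d$records$record_id, ts$record_id)
  preds <- make_predictions(d, ts, un[1:25])
  met <- performance_metrics(apply_strategy(d, preds, ts, "dual_semi_auto"),
                             d)
  expect_equal(met$savings$records, met$baseline_total - met$manual_screens)
  expect_equal(met$time$hours_raw, met$savings$records * 0.5 / 60)
  expect_equal(met$confusion$tp + met$confusion$fn,
               length(d$fulltext_includes))
})
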