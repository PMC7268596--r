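test_that("training sets are uniform random draws labeled by the senior", {
  d <- make_random_dataset(50, seed = 8)
  ts <- draw_training_set(d, 20, seed = 3)
  expect_equal(attr(ts, "size"), 20)
  expect_identical(ts$record_id, draw_training_set(d, 20, seed = 3)$record_id)
  lab <- d$decisions$senior[match(ts$record_id, d$decisions$record_id)]
  expect_identical(ts$label, as.integer(lab == "include"))
  expect_equal(attr(ts, "n_includes") + attr(ts, "n_excludes"), 20)

  all_ts <- draw_training_set(d, 50, seed = 1)
  expect_setequal(all_ts$record_id, d$records$record_id)
  expect_error(draw_training_set(d, 51), "exceeds N")
})

test_that("prediction availability needs both classes at the minimum", {
  d <- make_tiny_dataset(30, senior_inc = paste0("rec", 1:6),
                         second_inc = character())
  grab <- function(ids) screensim:::new_training_set(ids, d)
  expect_true(predictions_available(grab(paste0("rec", 3:10)),
                                    min_includes = 2))   # 4 inc, 4 exc
  expect_false(predictions_available(grab(paste0("rec", 7:10))))  # 0 inc
  expect_false(predictions_available(grab(paste0("rec", 6:8)),
                                     min_includes = 2))  # 1 inc
  expect_false(predictions_available(grab(paste0("rec", 1:6))))   # 0 exc
})

test_that("training sets extend in batches until predictions are available", {
  d <- generate_corpus(synthetic_config(n_records = 2000,
                                        prevalence_ta = 0.005, seed = 31))
  ts <- draw_training_set(d, 200, seed = 1)
  ts2 <- extend_training_set(d, ts, batch = 100, seed = 2)
  expect_equal(attr(ts2, "size"), 300)
  expect_identical(ts2$record_id[1:200], ts$record_id)
  expect_error(extend_training_set(d, ts, batch = 0), "batch")

  grown <- grow_training_set(d, size = 200, batch = 100, min_includes = 2,
                             seed = 5)
  expect_true(predictions_available(grown, 2))
  expect_equal((attr(grown, "size") - 200) %% 100, 0)

  # a corpus whose senior includes nothing can never become available
  ids <- paste0("r", 1:50)
  recs <- data.frame(record_id = ids, title = "t", abstract = "a")
  dec <- data.frame(record_id = ids, senior = "exclude", second = "exclude")
  dead <- review_dataset("dead", "systematic", recs, dec)
  expect_error(grow_training_set(dead, size = 10, batch = 20, seed = 1),
               "no unscreened records remain")
})

test_that("the classifier separates a separable corpus", {
  cfg <- synthetic_config(n_records = 600, prevalence_ta = 0.15,
                          signal_enrichment = 10,
                          senior_profile = reviewer_profile(1, 1), seed = 17)
  d <- generate_corpus(cfg)
  ts <- draw_training_set(d, 200, seed = 2)
  m <- fit_relevance_model(d, ts)
  # training accuracy 1 on the separable, noise-free-label corpus
  recs <- d$records[match(ts$record_id, d$records$record_id), ]
  x <- screensim:::dtm(screensim:::record_tokens(recs), m$vocabulary)
  eta <- as.numeric(x %*% m$weights) + m$intercept
  expect_equal(mean((eta >= 0) == (ts$label == 1)), 1)

  p <- predict(m, d, ts)
  expect_equal(nrow(p), 400)
  expect_identical(p$hard, p$probability >= m$threshold)
  expect_equal(attr(p, "P"), sum(p$hard))
  # reproducibility of the whole fit/predict path
  p2 <- predict(fit_relevance_model(d, ts), d, ts)
  expect_identical(p, p2)
})

test_that("records without text score at the intercept", {
  d <- make_random_dataset(40, seed = 12)
  d$records$title[40] <- ""
  d$records$abstract[40] <- ""
  d$records$keywords[40] <- ""
  ts <- screensim:::new_training_set(paste0("rec", 1:30), d)
  m <- fit_relevance_model(d, ts)
  p <- predict(m, d, ts)
  expect_equal(p$probability[p$record_id == "rec40"],
               stats::plogis(m$intercept))
})

test_that("an all-textless corpus is an error", {
  ids <- paste0("r", 1:20)
  recs <- data.frame(record_id = ids, title = "", abstract = "")
  dec <- data.frame(record_id = ids,
                    senior = rep(c("include", "exclude"), 10),
                    second = "exclude")
  d <- review_dataset("blank", "systematic", recs, dec)
  ts <- draw_training_set(d, 20, seed = 1)
  expect_error(fit_relevance_model(d, ts), "empty vocabulary")
})

test_that("dual supervision shifts scores monotonically", {
  d <- make_random_dataset(60, seed = 5)
  ts <- draw_training_set(d, 40, seed = 2)
  m0 <- fit_relevance_model(d, ts)
  expect_identical(m0$term_offsets, setNames(rep(0, length(m0$vocabulary)),
                                             m0$vocabulary))

  m1 <- fit_relevance_model(d, ts, terms = term_labels("trial", "relevant"))
  p0 <- predict(m0, d, ts)
  p1 <- predict(m1, d, ts)
  un <- d$records[match(p0$record_id, d$records$record_id), ]
  has_term <- grepl("\\btrial\\b", paste(un$title, un$abstract, un$keywords))
  expect_true(all(p1$probability[has_term] >= p0$probability[has_term]))
  expect_equal(p1$probability[!has_term], p0$probability[!has_term])

  # a large offset forces any record containing the term over the threshold
  mBig <- fit_relevance_model(d, ts, terms = term_labels("trial", "relevant"),
                              delta = 50)
  pBig <- predict(mBig, d, ts)
  expect_true(all(pBig$hard[has_term]))

  # labeled terms outside the training vocabulary still act at scoring time
  mX <- fit_relevance_model(d, ts,
                            terms = term_labels("zzznovel", "irrelevant"),
                            delta = 50)
  expect_true("zzznovel" %in% mX$vocabulary)
  expect_equal(unname(mX$weights["zzznovel"]), 0)
})

test_that("term labels carry one polarity each", {
  expect_error(term_labels(c("a", "a"), c("relevant", "irrelevant")),
               "at most one polarity")
})

test_that("prediction sets enforce the hard-threshold identity", {
  expect_error(prediction_set(c("a", "b"), c(0.2, 0.9),
                              hard = c(TRUE, TRUE)),
               "must equal")
  ps <- prediction_set(c("a", "b", "c"), c(0.2, 0.5, 0.9))
  expect_identical(ps$hard, c(FALSE, TRUE, TRUE))
  expect_equal(attr(ps, "P"), 2)
})
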