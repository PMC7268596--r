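# Fixtures are built in code: a tiny hand-specified review and a randomised
# review with internally consistent truth, decisions and full-text includes.

word_pool <- c("trial", "cohort", "infant", "therapy", "outcome", "risk",
               "screening", "review", "exposure", "sample", "placebo",
               "protocol", "blinded", "registry", "survey", "baseline")

make_records <- function(ids, seed = 1) {
  withr::with_seed(seed, data.frame(
    record_id = ids,
    title = vapply(ids, function(i)
      paste(sample(word_pool, 5, replace = TRUE), collapse = " "), ""),
    abstract = vapply(ids, function(i)
      paste(sample(word_pool, 12, replace = TRUE), collapse = " "), ""),
    keywords = vapply(ids, function(i)
      paste(sample(word_pool, 2), collapse = "; "), ""),
    authors = paste("Author", seq_along(ids)),
    truth_ta = NA, truth_ft = NA))
}

# tiny review with the include sets spelled out
make_tiny_dataset <- function(n = 10, review_type = "systematic",
                              senior_inc = character(),
                              second_inc = character(),
                              ft_inc = character(), seed = 1) {
  ids <- paste0("rec", seq_len(n))
  dec <- data.frame(
    record_id = ids,
    senior = ifelse(ids %in% senior_inc, "include", "exclude"),
    second = if (review_type == "systematic")
      ifelse(ids %in% second_inc, "include", "exclude")
    else NA_character_)
  review_dataset("tiny", review_type, make_records(ids, seed), dec, ft_inc)
}

# randomised but internally consistent review, with truth labels
make_random_dataset <- function(n = 60, review_type = "systematic",
                                seed = 1, p_senior = 0.3, p_second = 0.3,
                                p_ta = 0.4, p_ft = 0.5) {
  withr::with_seed(seed, {
    ids <- paste0("rec", seq_len(n))
    truth_ta <- runif(n) < p_ta
    truth_ft <- truth_ta & runif(n) < p_ft
    senior <- ifelse(runif(n) < p_senior, "include", "exclude")
    second <- if (review_type == "systematic")
      ifelse(runif(n) < p_second, "include", "exclude")
    else rep(NA_character_, n)
    pass <- senior == "include" | (!is.na(second) & second == "include")
    recs <- make_records(ids, seed + 1)
    recs$truth_ta <- truth_ta | truth_ft
    recs$truth_ft <- truth_ft
    dec <- data.frame(record_id = ids, senior = senior, second = second)
    review_dataset("random", review_type, recs, dec, ids[truth_ft & pass])
  })
}

# a prediction set with a prescribed hard-true id set
make_predictions <- function(dataset, training_set, hard_ids) {
  un <- setdiff(dataset$records$record_id, training_set$record_id)
  prediction_set(un, as.numeric(un %in% hard_ids))
}
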