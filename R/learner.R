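# Active-learning relevance classifier.
#
# Stand-in for the prediction engine of screening tools such as Abstrackr:
# the senior reviewer screens a random training set; once both classes are
# represented at a configured minimum the model trains and emits, for every
# unscreened record, a probability of relevance and the binary "hard"
# prediction used by the screening strategies. The model is an
# L2-regularised logistic regression on bag-of-words counts of
# title + abstract + keywords (title tokens weighted x2), with optional
# dual supervision: reviewer-labeled relevant/irrelevant terms contribute a
# fixed additive log-odds offset (+delta / -delta, once per labeled term
# present in a record) at scoring time.

#' Tokenise bibliographic text
#'
#' Lowercases, splits on non-alphanumeric characters, and keeps tokens of
#' length >= 2. No stemming or stop-word removal, so results are
#' reproducible bit-for-bit across platforms.
#'
#' @param text character vector.
#' @return list of character vectors of tokens, one per input element.
#' @export
tokenize <- function(text) {
  toks <- strsplit(tolower(ifelse(is.na(text), "", text)), "[^a-z0-9]+")
  lapply(toks, function(t) t[nchar(t) >= 2])
}

# tokens per record with the title counted twice
record_tokens <- function(records) {
  ti <- tokenize(records$title)
  ab <- tokenize(records$abstract)
  kw <- tokenize(records$keywords)
  mapply(function(t, a, k) c(t, t, a, k), ti, ab, kw, SIMPLIFY = FALSE)
}

# sparse document-term count matrix over a fixed vocabulary
dtm <- function(token_list, vocab) {
  idx <- lapply(token_list, function(t) {
    m <- match(t, vocab)
    m[!is.na(m)]
  })
  ii <- rep.int(seq_along(idx), lengths(idx))
  jj <- as.integer(unlist(idx, use.names = FALSE) %||% integer(0))
  Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                       dims = c(length(token_list), length(vocab)),
                       dimnames = list(NULL, vocab))
}

#' Draw a random training set
#'
#' Emulates screening in random citation order: a uniform random sample of
#' `size` records without replacement, labeled with the senior reviewer's
#' recorded decisions.
#'
#' @param dataset a [review_dataset()].
#' @param size training-set size (default 200 records).
#' @param seed integer seed; the same seed reproduces the sample order.
#' @return a `training_set`: data frame with columns `record_id`, `label`
#'   (1 include / 0 exclude) in screening order, with attributes `size`,
#'   `n_includes`, `n_excludes`.
#' @export
draw_training_set <- function(dataset, size = 200, seed = 1L) {
  stopifnot(inherits(dataset, "review_dataset"))
  n <- dataset$workload_n
  if (size > n) stop_("training size ", size, " exceeds N = ", n)
  ids <- withr::with_seed(as.integer(seed),
                          sample(dataset$records$record_id, size))
  new_training_set(ids, dataset)
}

new_training_set <- function(ids, dataset) {
  dec <- dataset$decisions
  lab <- as.integer(dec$senior[match(ids, dec$record_id)] == "include")
  if (anyNA(lab)) stop_("senior decision missing for drawn training records")
  ts <- data.frame(record_id = ids, label = lab)
  structure(ts, class = c("training_set", "data.frame"),
            size = nrow(ts), n_includes = sum(lab),
            n_excludes = sum(lab == 0L))
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %d records: %d includes / %d excludes (%s%%)\n",
              attr(x, "size"), attr(x, "n_includes"), attr(x, "n_excludes"),
              round_half_up(100 * attr(x, "n_includes") /
                              max(attr(x, "size"), 1))))
  invisible(x)
}

#' Are relevance predictions available?
#'
#' Screening tools withhold predictions until the training set represents
#' both classes; predictions are considered available once the training set
#' holds at least `min_includes` includes and at least one exclude.
#'
#' @param training_set a [draw_training_set()] result.
#' @param min_includes minimum include count (default 2).
#' @return `TRUE`/`FALSE`.
#' @export
predictions_available <- function(training_set, min_includes = 2) {
  attr(training_set, "n_includes") >= min_includes &&
    attr(training_set, "n_excludes") >= 1L
}

#' Extend a training set by one screening batch
#'
#' When predictions are not yet available the reviewer keeps screening in
#' batches (default 100 records) of further uniform-random unscreened
#' records until they are.
#'
#' @param dataset a [review_dataset()].
#' @param training_set the current training set.
#' @param batch batch size (> 0).
#' @param seed integer seed for the batch draw.
#' @return the extended `training_set`.
#' @export
extend_training_set <- function(dataset, training_set, batch = 100, seed = 1L) {
  if (!is.numeric(batch) || batch <= 0) stop_("batch must be > 0")
  pool <- setdiff(dataset$records$record_id, training_set$record_id)
  if (!length(pool)) {
    stop_("no unscreened records remain to extend the training set ",
          sprintf("(includes = %d, excludes = %d)",
                  attr(training_set, "n_includes"),
                  attr(training_set, "n_excludes")))
  }
  take <- min(batch, length(pool))
  ids <- withr::with_seed(as.integer(seed), sample(pool, take))
  new_training_set(c(training_set$record_id, ids), dataset)
}

#' Grow a training set until predictions become available
#'
#' Draws the initial random training set and, while predictions are
#' unavailable, keeps appending batches — the screening protocol of starting
#' at 200 records and continuing in batches of 100.
#'
#' @inheritParams extend_training_set
#' @param size initial training-set size.
#' @param min_includes availability threshold, see [predictions_available()].
#' @return a `training_set` for which [predictions_available()] is `TRUE`.
#' @export
grow_training_set <- function(dataset, size = 200, batch = 100,
                              min_includes = 2, seed = 1L) {
  seeds <- derive_seeds(seed, 64L)
  ts <- draw_training_set(dataset, size, seeds[1])
  i <- 1L
  while (!predictions_available(ts, min_includes)) {
    i <- i + 1L
    if (i > length(seeds)) seeds <- c(seeds, derive_seeds(seeds[1], 64L))
    ts <- extend_training_set(dataset, ts, batch, seeds[i])
  }
  ts
}

#' Reviewer-labeled terms for dual supervision
#'
#' @param term character vector of tokens.
#' @param polarity "relevant" or "irrelevant", recycled; a term may carry at
#'   most one polarity.
#' @return a `term_labels` data frame.
#' @export
term_labels <- function(term, polarity) {
  polarity <- rep_len(match.arg(polarity, c("relevant", "irrelevant"),
                                several.ok = TRUE), length(term))
  term <- tolower(term)
  if (anyDuplicated(term)) stop_("a term may carry at most one polarity")
  structure(data.frame(term = term, polarity = polarity),
            class = c("term_labels", "data.frame"))
}

#' Fit the relevance classifier
#'
#' Fits an L2-regularised (ridge) logistic regression of the senior
#' reviewer's training decisions on bag-of-words token counts, via
#' [glmnet::glmnet()] at a fixed penalty (fitted along a decreasing penalty
#' path for convergence). Two refinements make the 0.5 "hard" threshold
#' behave like the emulated screening tool's:
#'
#' * classes are balanced by observation weights, reflecting the
#'   recall-oriented behaviour of screening tools, whose hard-true fractions
#'   run well above the include prevalence;
#' * the linear score is recalibrated by Platt scaling fitted on
#'   out-of-fold scores from a deterministic 5-fold split of the training
#'   set, so held-out probabilities — not the overfit in-sample ones — are
#'   centred on the threshold. The calibration is folded back into the
#'   stored weights and intercept.
#'
#' Labeled terms receive an additive log-odds offset of `+delta` (relevant)
#' or `-delta` (irrelevant), applied once per labeled term present in a
#' record at scoring time; labeled terms absent from the training
#' vocabulary are appended with weight zero so the offset still acts on
#' unscreened records containing them.
#'
#' @param dataset a [review_dataset()].
#' @param training_set a `training_set` for which predictions are available.
#' @param terms optional [term_labels()] for dual supervision.
#' @param delta magnitude of the labeled-term log-odds offset (default 2).
#' @param lambda ridge penalty (default 1).
#' @param threshold probability cut-off for hard predictions (default 0.5).
#' @param calibrate logical; disable to keep the raw ridge-logistic score.
#' @return a `relevance_model` with fields `vocabulary`, `weights`,
#'   `intercept`, `term_offsets`, `threshold`.
#' @export
fit_relevance_model <- function(dataset, training_set, terms = NULL,
                                delta = 2, lambda = 1, threshold = 0.5,
                                calibrate = TRUE) {
  stopifnot(inherits(dataset, "review_dataset"),
            inherits(training_set, "training_set"))
  if (!predictions_available(training_set, min_includes = 1)) {
    stop_("training set does not represent both classes ",
          sprintf("(includes = %d, excludes = %d)",
                  attr(training_set, "n_includes"),
                  attr(training_set, "n_excludes")))
  }
  recs <- dataset$records[match(training_set$record_id,
                                dataset$records$record_id), ]
  toks <- record_tokens(recs)
  vocab <- sort(unique(unlist(toks)))
  if (!length(vocab)) {
    stop_("empty vocabulary: no tokens in the training records' text")
  }
  x <- dtm(toks, vocab)
  y <- training_set$label
  wts <- ifelse(y == 1L, 0.5 / mean(y == 1L), 0.5 / mean(y == 0L))
  co <- ridge_logistic(x, y, wts, lambda)
  w <- co$weights
  b <- co$intercept
  if (calibrate) {
    cal <- platt_calibration(x, y, wts, lambda)
    w <- cal[2] * w
    b <- cal[1] + cal[2] * b
  }

  offsets <- stats::setNames(rep(0, length(vocab)), vocab)
  if (!is.null(terms) && nrow(terms)) {
    stopifnot(inherits(terms, "term_labels"))
    extra <- setdiff(terms$term, vocab)
    if (length(extra)) {
      vocab <- c(vocab, extra)
      w <- c(w, rep(0, length(extra)))
      offsets <- c(offsets, stats::setNames(rep(0, length(extra)), extra))
    }
    offsets[terms$term] <- ifelse(terms$polarity == "relevant", delta, -delta)
  }

  structure(list(vocabulary = vocab, weights = stats::setNames(w, vocab),
                 intercept = b, term_offsets = offsets,
                 threshold = threshold, delta = delta, lambda = lambda,
                 calibrated = calibrate,
                 training_size = attr(training_set, "size")),
            class = "relevance_model")
}

#' @export
print.relevance_model <- function(x, ...) {
  cat(sprintf(paste0("<relevance_model> ridge logistic on %d terms ",
                     "(lambda = %g), threshold = %g\n"),
              length(x$vocabulary), x$lambda, x$threshold))
  nlab <- sum(x$term_offsets != 0)
  if (nlab) cat(sprintf("  dual supervision: %d labeled terms, delta = %g\n",
                        nlab, x$delta))
  invisible(x)
}

#' @export
coef.relevance_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$weights)
}

#' Predict relevance of unscreened records
#'
#' Scores exactly the records outside the training set and returns the
#' probability of relevance and the binary "hard" prediction
#' (`probability >= threshold`) for each. A record with no recognised
#' tokens scores `plogis(intercept)`.
#'
#' @param object a fitted `relevance_model`.
#' @param dataset the [review_dataset()] to score.
#' @param training_set the training set whose records are skipped.
#' @param ... unused.
#' @return a `prediction_set`: data frame with columns `record_id`,
#'   `probability`, `hard`, with attributes `P` (count of hard-true
#'   predictions) and `threshold`.
#' @export
predict.relevance_model <- function(object, dataset, training_set, ...) {
  stopifnot(inherits(dataset, "review_dataset"))
  unscreened <- setdiff(dataset$records$record_id, training_set$record_id)
  recs <- dataset$records[match(unscreened, dataset$records$record_id), ]
  toks <- record_tokens(recs)
  x <- dtm(toks, object$vocabulary)
  eta <- as.numeric(x %*% object$weights) + object$intercept
  labeled <- which(object$term_offsets != 0)
  if (length(labeled)) {
    present <- x[, labeled, drop = FALSE] > 0
    eta <- eta + as.numeric(present %*% object$term_offsets[labeled])
  }
  prob <- stats::plogis(eta)
  prediction_set(unscreened, prob, threshold = object$threshold)
}

# ridge logistic at a fixed lambda, fitted along a decreasing penalty path
# and keeping the final solution: warm starts make the small-lambda fit
# converge where a single-lambda call does not
ridge_logistic <- function(x, y, wts, lambda) {
  lam_path <- exp(seq(log(max(50, lambda * 10)), log(lambda),
                      length.out = 30))
  fit <- suppressWarnings(
    glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lam_path,
                   weights = wts, standardize = FALSE, thresh = 1e-9,
                   maxit = 1e5))
  k <- ncol(fit$beta)
  list(weights = as.numeric(fit$beta[, k]), intercept = as.numeric(fit$a0[k]))
}

# Platt scaling (a, c) of the linear score, fitted on out-of-fold scores
# from a deterministic 5-fold split (the training set is already in random
# screening order, so systematic folds are a random partition). Smoothed
# targets avoid divergence on separable folds. Returns c(a = 0, c = 1) when
# a fold loses a class or the 1-d fit fails.
platt_calibration <- function(x, y, wts, lambda, nfolds = 5L) {
  n <- length(y)
  folds <- rep_len(seq_len(nfolds), n)
  oof <- rep(NA_real_, n)
  for (f in seq_len(nfolds)) {
    tr <- folds != f
    if (sum(y[tr] == 1L) < 2L || sum(y[tr] == 0L) < 2L) return(c(0, 1))
    co <- ridge_logistic(x[tr, , drop = FALSE], y[tr], wts[tr], lambda)
    oof[!tr] <- as.numeric(x[!tr, , drop = FALSE] %*% co$weights) +
      co$intercept
  }
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  target <- ifelse(y == 1L, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  cal <- tryCatch(
    stats::glm(target ~ oof, family = stats::quasibinomial(), weights = wts),
    error = function(e) NULL)
  a <- if (is.null(cal)) c(0, 1) else as.numeric(stats::coef(cal))
  if (anyNA(a) || a[2] <= 0) c(0, 1) else a
}

#' Assemble a prediction set
#'
#' Normally produced by [predict.relevance_model()]; exposed so that
#' hypothetical predictors (e.g. an oracle with `hard = truth`) can be fed
#' to the screening strategies.
#'
#' @param record_id character vector of unscreened record ids.
#' @param probability relevance probabilities in `[0, 1]`.
#' @param hard optional logical hard predictions; defaults to
#'   `probability >= threshold` and must equal it when supplied.
#' @param threshold the probability cut-off.
#' @return a `prediction_set` data frame.
#' @export
prediction_set <- function(record_id, probability, hard = NULL,
                           threshold = 0.5) {
  stopifnot(length(record_id) == length(probability),
            all(probability >= 0 & probability <= 1))
  h <- probability >= threshold
  if (!is.null(hard) && !identical(as.logical(hard), h)) {
    stop_("hard predictions must equal probability >= threshold")
  }
  ps <- data.frame(record_id = as.character(record_id),
                   probability = probability, hard = h)
  structure(ps, class = c("prediction_set", "data.frame"),
            P = sum(h), threshold = threshold)
}

#' @export
print.prediction_set <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<prediction_set> %d unscreened records, %d (%s%%) predicted relevant\n",
              n, attr(x, "P"), round_half_up(100 * attr(x, "P") / max(n, 1))))
  invisible(x)
}

#' Write predictions to CSV
#'
#' Mirrors downloading a screening tool's predictions: `record_id`,
#' `probability` (6 decimals), `hard` (true/false).
#'
#' @param predictions a `prediction_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions_csv <- function(predictions, path) {
  df <- data.frame(record_id = predictions$record_id,
                   probability = sprintf("%.6f", predictions$probability),
                   hard = ifelse(predictions$hard, "true", "false"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
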