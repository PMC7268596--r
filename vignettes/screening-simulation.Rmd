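---
title: "Methods: simulating semi-automated title and abstract screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating semi-automated title and abstract screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screensim)
```

## The screening workflow being simulated

A review team retrieves `N` citation records per reviewer. Under conventional
dual independent screening (systematic reviews) two reviewers each screen all
`N` titles and abstracts and a record advances to full text if either marks it
relevant; rapid reviews use a single senior reviewer. An active-learning
screening tool changes the accounting: the senior reviewer screens a random
training set of `T` records (nominally 200, extended in batches of 100 until
the tool's predictions become available), and the tool then predicts, for each
of the `N − T` unscreened records, a probability of relevance and a binary
"hard" prediction. `P` denotes the number of hard-true predictions.

`screensim` replays four ways of leveraging the predictions, retrospectively,
against the decisions the humans actually recorded. Training-set records
always carry the senior's recorded decision into the consensus; in
semi-automated modes the senior's "verification" of a predicted-relevant
record reuses the recorded decision for that record (a retrospective design —
no second guess is simulated). By construction the consensus sets nest:
semi-automated ⊆ fully automated and single ⊆ dual, so missed counts are
anti-monotone across approaches; this is asserted as a property test rather
than assumed.

Performance is summarised by three metrics from the 2×2 cross-tabulation of a
strategy's consensus against the final-report includes: the proportion missed
`fn/(tp + fn)`; workload savings, `baseline − manual screens` where the
baseline is `2N` (dual) or `N` (single); and time savings at 0.5 minutes per
record converted to 8-hour days. Displayed percentages, hours and days are
rounded half-up (an exactly half value rounds away from zero), and day counts
below one working day render as `"<1"`. Internal values keep full precision.

### Reporting conventions with non-obvious consequences

* **Training deduction.** Published evaluations deduct the nominal 200-record
  training set from the savings even for a review whose training set had to be
  extended to 300 records before predictions appeared. `nominal_training =
  TRUE` reproduces that convention; the default (`FALSE`) deducts the screens
  actually performed. Predicted-relevant proportions always use the actual
  `N − T`.
* **Internally inconsistent published cells.** Recomputing a published
  17-review savings/time table from its own inputs reproduces 214 of the 224
  printed numbers exactly. The remaining ten contradict their own arithmetic
  (three percentages computed from the wrong denominators, and two
  records-plus-percentage pairs exactly consistent with a digit-transposed
  predicted-relevant count of 846 where the characteristics table prints 864).
  `compare_with_reported()` flags these cells with the recomputed values,
  which are treated as authoritative; they are never silently matched.

## The synthetic corpus generator

Real screening corpora from completed reviews are rarely shareable, so every
downstream stage is exercised on synthetic corpora that emulate their
statistical structure. A corpus is drawn as:

* `truth_ta ~ Bernoulli(prevalence_ta)` per record, and among relevant
  records `truth_ft ~ Bernoulli(p_ft_given_ta)`;
* record text as `tokens_per_record` draws from a class-conditional
  multinomial over `vocab_size` terms: uniform base probabilities, with the
  odds of `n_signal_terms` "signal" terms multiplied by `signal_enrichment`
  in the relevant class (renormalised). The first 8 tokens form the title,
  the rest the abstract (empty with probability 0.05 to exercise
  missing-text handling), plus 3 class-biased keyword tokens;
* reviewer decisions independently per record and reviewer from a
  sensitivity/specificity profile;
* full-text includes per the human flow: a record enters the final report
  only if it is full-text relevant *and* at least one human reviewer
  forwarded it at title/abstract.

Defaults follow the emulated reviews' observed medians — `n_records = 2928`,
`prevalence_ta = 0.08`, `p_ft_given_ta = 0.42` — and otherwise values a
reviewer would recognise as realistic: `tokens_per_record = 180` (a title
plus a 150–250-word abstract), `vocab_size = 500` and `n_signal_terms = 30`
(deliberately compact so test corpora stay fast while leaving the feature
space much larger than the training set), `signal_enrichment = 5` (clearly
separable but not trivially so). Reviewer profiles default to senior
0.95/0.995 and second 0.85/0.99 sensitivity/specificity: no error rates are
published for the emulated reviews, so these are calibrated only in the weak
sense that a lone second reviewer then misses 0–43% of final-report includes,
the range observed in practice. Reviewer errors are independent across
records and reviewers — the simplest model consistent with single-versus-dual
comparisons; correlated errors (e.g. both reviewers fooled by the same
ambiguous abstract) are a known extension the generator does not model. Nor
does it model real language: there are no topics, collocations or length
effects, so passing tests show the pipeline's accounting and the learner's
statistical behaviour are correct, not that any particular real corpus would
yield the same miss rates.

The citation graph is likewise generative: each full-text-included study
cites every other title/abstract-relevant record independently with
probability `rho` (default 0.59, the empirically observed reference-list
recovery rate). With `k` retained includes the per-record recovery
probability is `1 − (1 − rho)^k`, which the tests check against simulation.
Recovery consults only the includes a strategy retained — reference-list
scanning starts from the studies the review did find.

## The relevance classifier

The emulated tool's internals are not published, so the stand-in is specified
to be transparent and reproducible rather than identical: an L2-regularised
logistic regression (`glmnet`, `alpha = 0`) on bag-of-words counts of
title + abstract + keywords. Tokenisation is lowercase, split on
non-alphanumeric characters, tokens of length ≥ 2, no stemming; title tokens
are counted twice. Numerical choices that matter:

* **Penalty.** `lambda = 1` by default, fitted along a decreasing penalty
  path from 50 with warm starts (a single small-lambda call fails to
  converge on separable text). The held-out ranking is insensitive to
  `lambda` over two orders of magnitude; the default sits where the
  out-of-fold calibration below is stable.
* **Balanced class weights.** Includes are rare (2–26%), and screening tools
  visibly over-call relevance — hard-true fractions of 10–67% against
  prevalences far lower. Weighting classes to equal mass reproduces exactly
  that recall-oriented behaviour and makes the hard threshold usable at low
  prevalence.
* **Out-of-fold Platt recalibration.** With a few hundred training documents
  and thousands of features, in-sample scores are saturated while held-out
  scores shrink asymmetrically — a 0.5 cut on the raw fit is meaningless. The
  linear score is therefore recalibrated by Platt scaling fitted on
  out-of-fold scores from a deterministic 5-fold split (the training set is
  already in random screening order, so systematic folds are a random
  partition; smoothed targets avoid divergence on separable folds). The
  calibration is folded back into the stored weights and intercept, so the
  model object remains vocabulary/weights/intercept/offsets/threshold. If a
  fold loses a class or the 1-d fit degenerates, calibration is skipped
  rather than guessed.
* **Hard threshold.** 0.5, with `hard ≡ probability ≥ threshold` enforced by
  the prediction-set constructor. A record with no recognised tokens scores
  `plogis(intercept)`.
* **Dual supervision.** A reviewer-labeled term contributes a fixed
  log-odds offset of `±delta` (default 2), applied once per labeled term
  *present* in a record, at scoring time. Presence rather than count keeps
  the monotonicity guarantee (adding a relevant-polarity label never lowers
  the score of a record containing the term) and the large-`delta` limit
  clean. Labeled terms outside the training vocabulary are appended with
  weight zero so they still act on unscreened records.
* **Availability rule.** Predictions are "available" once the training set
  holds at least `min_includes` (default 2) includes and one exclude. The
  real tool's rule is undocumented; 2 is the smallest value consistent with
  the observed behaviour that a review with 4 includes among 300 screened
  records had just crossed the line, and it is exposed as a parameter.

The replication path uses random screening order throughout; uncertainty-based
prioritisation is deliberately absent from the strategies because the emulated
protocol did not use it.

## Problem sizes and seeds

The test suite exercises the 17 emulated reviews at their real workloads
(451–12,156 records; ~63k records and 17 classifier fits in total, about half
a minute), plus dedicated corpora of 3,000 records for classifier sanity
(separable: hard-prediction sensitivity ≥ 0.95; signal-free: AUC within
0.5 ± 0.05) and 5,000 records for reviewer-profile recovery within three
binomial standard errors. All stochastic stages draw named sub-seeds from a
single master seed, so any stage can be replayed in isolation; identical
configuration and seed reproduce every object byte for byte.

## Known limitations

* The classifier is a stand-in: it reproduces the screening protocol and the
  qualitative behaviour (calibrated hard predictions, over-calling at low
  prevalence), not a proprietary decision boundary. Proportion-missed values
  on real corpora are therefore not reproducible from this package alone.
* The include/unsure/borderline equivalence is baked in at load time; a
  three-way decision model is out of scope, as are deduplication, full-text
  retrieval and live citation-database queries.
* The package's interface is R functions plus `scripts/acceptance.R`; there
  is no shell CLI, since the intended users drive analyses from R.
* Metric differences between strategies are reported without statistical
  inference, matching the descriptive reporting convention of the evaluations
  this package emulates.
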