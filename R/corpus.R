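#' Normalise raw screening labels to binary decisions
#'
#' Screening records kept during title and abstract screening may carry the
#' labels "include", "unsure" or "borderline" for records a reviewer would
#' forward to full text, and "exclude" otherwise. Because a record marked
#' unsure/borderline by either reviewer is scrutinised at full text exactly
#' like an include, the three forwarding labels are treated as equivalent and
#' collapsed to "include" at load time. Matching is case-insensitive and
#' ignores surrounding whitespace.
#'
#' @param raw_label character vector of raw labels.
#' @param record_id optional character vector of the same length, used to name
#'   the offending record in error messages.
#' @return character vector of "include"/"exclude".
#' @examples
#' normalize_decision(c("unsure", "Borderline", "EXCLUDE"))
#' @export
normalize_decision <- function(raw_label, record_id = NULL) {
  x <- tolower(trimws(as.character(raw_label)))
  out <- ifelse(x %in% c("include", "unsure", "borderline"), "include",
                ifelse(x == "exclude", "exclude", NA_character_))
  if (anyNA(out)) {
    bad <- which(is.na(out))
    where <- if (!is.null(record_id)) {
      paste0(" (record ", paste(record_id[bad], collapse = ", "), ")")
    } else {
      paste0(" at position ", paste(bad, collapse = ", "))
    }
    stop_("unrecognised screening label ",
          paste(unique(raw_label[bad]), collapse = ", "), where,
          "; expected include/unsure/borderline/exclude")
  }
  out
}

#' Construct a review dataset
#'
#' Bundles a review's citation records, per-reviewer title-and-abstract
#' decisions, and the consensus full-text includes into a validated
#' `review_dataset` object, the container every downstream stage consumes.
#'
#' `records` must have columns `record_id`, `title`, `abstract`, `keywords`,
#' `authors` (keywords/authors as "; "-separated strings) and may carry the
#' ground-truth columns `truth_ta`, `truth_ft` (logical; `NA` when unknown,
#' as for real screening data). `decisions` must have columns `record_id`,
#' `senior` and (for systematic reviews) `second`, each "include"/"exclude";
#' the raw pre-binarisation labels may be kept in `senior_raw`/`second_raw`
#' audit columns.
#'
#' @param name review name.
#' @param review_type "systematic" (dual independent screening) or "rapid"
#'   (single senior reviewer).
#' @param records data frame of citation records.
#' @param decisions data frame of screening decisions, one row per record.
#' @param fulltext_includes character vector of record ids included in the
#'   final report after full-text scrutiny.
#' @return an object of class `review_dataset` with fields `name`,
#'   `review_type`, `records`, `decisions`, `fulltext_includes` and
#'   `workload_n` (the per-reviewer screening workload, = number of records).
#' @export
review_dataset <- function(name, review_type = c("systematic", "rapid"),
                           records, decisions, fulltext_includes = character()) {
  review_type <- match.arg(review_type)
  records <- as.data.frame(records)
  decisions <- as.data.frame(decisions)
  fulltext_includes <- as.character(fulltext_includes)

  need <- c("record_id", "title", "abstract")
  if (!all(need %in% names(records))) {
    stop_("records must have columns ", paste(need, collapse = ", "))
  }
  records$record_id <- as.character(records$record_id)
  for (col in c("keywords", "authors")) {
    if (is.null(records[[col]])) records[[col]] <- ""
  }
  for (col in c("truth_ta", "truth_ft")) {
    if (is.null(records[[col]])) records[[col]] <- NA
    records[[col]] <- as.logical(records[[col]])
  }
  if (anyDuplicated(records$record_id)) {
    dup <- unique(records$record_id[duplicated(records$record_id)])
    stop_("duplicate record_id: ", paste(dup, collapse = ", "))
  }

  if (!all(c("record_id", "senior") %in% names(decisions))) {
    stop_("decisions must have columns record_id, senior")
  }
  decisions$record_id <- as.character(decisions$record_id)
  if (nrow(decisions) == 0L) {
    stop_("decisions are empty: no senior-reviewer decisions for review '",
          name, "'")
  }
  if (anyDuplicated(decisions$record_id)) {
    stop_("more than one decision row per record_id")
  }
  unknown <- setdiff(decisions$record_id, records$record_id)
  if (length(unknown)) {
    stop_("decision for unknown record_id: ", paste(unknown, collapse = ", "))
  }
  missing_dec <- setdiff(records$record_id, decisions$record_id)
  if (length(missing_dec)) {
    stop_(length(missing_dec), " records lack a senior decision (e.g. ",
          missing_dec[1], ")")
  }
  if (review_type == "systematic") {
    if (is.null(decisions$second) || all(is.na(decisions$second))) {
      stop_("systematic review '", name, "' is missing second-reviewer decisions")
    }
  } else {
    decisions$second <- decisions$second %||% NA_character_
    if (!all(is.na(decisions$second) | decisions$second == "")) {
      stop_("rapid review '", name, "' carries second-reviewer decisions; ",
            "rapid reviews are screened by the senior reviewer alone")
    }
    decisions$second <- NA_character_
  }

  # a full-text include must have passed the human title/abstract stage
  unknown_ft <- setdiff(fulltext_includes, records$record_id)
  if (length(unknown_ft)) {
    stop_("fulltext_includes reference unknown record_id: ",
          paste(unknown_ft, collapse = ", "))
  }
  senior_inc <- decisions$record_id[decisions$senior == "include"]
  ta_pass <- if (review_type == "systematic") {
    union(senior_inc, decisions$record_id[!is.na(decisions$second) &
                                            decisions$second == "include"])
  } else {
    senior_inc
  }
  stray <- setdiff(fulltext_includes, ta_pass)
  if (length(stray)) {
    stop_("fulltext_includes contain records no reviewer forwarded at ",
          "title/abstract: ", paste(stray, collapse = ", "))
  }
  # and (when truth is known) be relevant at both stages
  tr <- records[match(fulltext_includes, records$record_id), ]
  if (any(!is.na(tr$truth_ft) & !tr$truth_ft)) {
    stop_("fulltext_includes contain records with truth_ft = FALSE")
  }
  bad_truth <- !is.na(records$truth_ft) & records$truth_ft &
    !is.na(records$truth_ta) & !records$truth_ta
  if (any(bad_truth)) {
    stop_("truth_ft = TRUE requires truth_ta = TRUE (record ",
          paste(records$record_id[bad_truth], collapse = ", "), ")")
  }

  structure(
    list(name = name, review_type = review_type, records = records,
         decisions = decisions,
         fulltext_includes = sort(unique(fulltext_includes)),
         workload_n = nrow(records)),
    class = "review_dataset")
}

#' @export
print.review_dataset <- function(x, ...) {
  cat(sprintf("<review_dataset> %s (%s review)\n", x$name, x$review_type))
  cat(sprintf("  records (per-reviewer workload N): %d\n", x$workload_n))
  cat(sprintf("  title/abstract includes (human consensus): %d\n",
              length(ta_consensus_ids(x))))
  cat(sprintf("  full-text includes in final report: %d\n",
              length(x$fulltext_includes)))
  invisible(x)
}

#' @export
summary.review_dataset <- function(object, ...) {
  d <- object$decisions
  out <- list(
    name = object$name,
    review_type = object$review_type,
    workload_n = object$workload_n,
    senior_includes = sum(d$senior == "include"),
    second_includes = if (object$review_type == "systematic")
      sum(d$second == "include", na.rm = TRUE) else NA_integer_,
    ta_includes = length(ta_consensus_ids(object)),
    fulltext_includes = length(object$fulltext_includes))
  class(out) <- "summary.review_dataset"
  out
}

#' @export
print.summary.review_dataset <- function(x, ...) {
  cat(sprintf("%s (%s): N = %d, title/abstract includes = %d (%s%%), ",
              x$name, x$review_type, x$workload_n, x$ta_includes,
              round_half_up(100 * x$ta_includes / max(x$workload_n, 1))))
  cat(sprintf("full-text includes = %d\n", x$fulltext_includes))
  invisible(x)
}

# consensus ids without the systematic-only guard (rapid -> senior includes)
ta_consensus_ids <- function(dataset) {
  d <- dataset$decisions
  senior <- d$record_id[d$senior == "include"]
  if (dataset$review_type == "rapid") return(sort(unique(senior)))
  second <- d$record_id[!is.na(d$second) & d$second == "include"]
  sort(unique(union(senior, second)))
}

#' Human title-and-abstract consensus for a systematic review
#'
#' Under dual independent screening any record marked relevant by either
#' reviewer is forwarded to full text, so the consensus include set is the
#' union of the senior and second reviewers' includes.
#'
#' @param dataset a systematic [review_dataset()].
#' @return character vector of record ids forwarded to full text.
#' @export
title_abstract_consensus_human <- function(dataset) {
  stopifnot(inherits(dataset, "review_dataset"))
  if (dataset$review_type != "systematic") {
    stop_("human dual-reviewer consensus requires a systematic review; '",
          dataset$name, "' is rapid (no second reviewer)")
  }
  ta_consensus_ids(dataset)
}

#' Stable record identifiers from bibliographic fields
#'
#' Assigns a record id as a hash-like key built from the title (and year when
#' available) for imports whose source carries no identifier. Collisions are
#' an error: deduplication is out of scope, so two records that normalise to
#' the same key must be disambiguated upstream.
#'
#' @param title character vector of titles.
#' @param year optional vector of publication years.
#' @return character vector of ids.
#' @export
make_record_ids <- function(title, year = NULL) {
  key <- tolower(gsub("[^a-z0-9]+", "-", tolower(trimws(title))))
  if (!is.null(year)) key <- paste0(key, "-", year)
  # short stable hash: sum of character codes mixed with position
  hash <- vapply(key, function(k) {
    v <- utf8ToInt(k)
    sprintf("r%08x", sum(v * (seq_along(v) %% 31 + 1)) %% 0xffffffff)
  }, character(1), USE.NAMES = FALSE)
  id <- paste0(hash, "-", substr(gsub("[^a-z0-9]", "", key), 1, 12))
  if (anyDuplicated(id)) {
    stop_("record id collision for titles: ",
          paste(unique(title[duplicated(id) | duplicated(id, fromLast = TRUE)]),
                collapse = " | "))
  }
  id
}
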