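# I/O for citation records and screening decisions.
#
# Records travel either as CSV (one row per record) or RIS (the reference
# manager exchange format screening tools ingest); decisions always travel as
# CSV with the fixed schema
#   record_id, senior_decision, second_decision, fulltext_include
# where second_decision is empty for rapid reviews and fulltext_include is
# 0/1. Decisions are binarised on load via normalize_decision(); the raw
# labels are retained in *_raw audit columns.

RECORD_COLS <- c("record_id", "title", "abstract", "keywords", "authors",
                 "truth_ta", "truth_ft")

#' Read citation records from CSV
#'
#' @param path CSV file with a header row; must contain at least
#'   `record_id`, `title`, `abstract`.
#' @return data frame of records.
#' @export
read_records_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        encoding = "UTF-8")
  if (!all(c("record_id", "title", "abstract") %in% names(df))) {
    stop_("records CSV must have a header with record_id, title, abstract: ",
          path)
  }
  for (col in c("keywords", "authors")) if (is.null(df[[col]])) df[[col]] <- ""
  for (col in c("truth_ta", "truth_ft")) {
    df[[col]] <- if (is.null(df[[col]])) NA else {
      ifelse(df[[col]] == "", NA, df[[col]] %in% c("1", "TRUE", "true"))
    }
  }
  df[RECORD_COLS]
}

#' Write citation records to CSV
#'
#' @param records data frame of records (as in a [review_dataset()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  df <- records
  for (col in c("truth_ta", "truth_ft")) {
    if (!is.null(df[[col]])) {
      df[[col]] <- ifelse(is.na(df[[col]]), "", ifelse(df[[col]], "1", "0"))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read citation records from an RIS file
#'
#' Minimal RIS support covering the fields screening uses: `ID` (record id),
#' `TI`/`T1` (title), `AB`/`N2` (abstract), `AU` (authors, repeatable), `KW`
#' (keywords, repeatable). Records are delimited by `TY` ... `ER` tags.
#' Records without an `ID` tag get a stable id from [make_record_ids()].
#'
#' @param path RIS file path.
#' @return data frame of records.
#' @export
read_records_ris <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  tag_re <- "^([A-Z][A-Z0-9])  - ?(.*)$"
  recs <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    data.frame(
      record_id = cur$ID %||% NA_character_,
      title = paste(cur$TI %||% cur$T1 %||% "", collapse = " "),
      abstract = paste(cur$AB %||% cur$N2 %||% "", collapse = " "),
      keywords = paste(cur$KW %||% character(), collapse = "; "),
      authors = paste(cur$AU %||% character(), collapse = "; "),
      truth_ta = NA, truth_ft = NA)
  }
  last_tag <- NULL
  for (ln in lines) {
    if (!grepl(tag_re, ln)) {
      # continuation line: append to the last seen tag
      if (!is.null(cur) && !is.null(last_tag) && nzchar(trimws(ln))) {
        n <- length(cur[[last_tag]])
        cur[[last_tag]][n] <- paste(cur[[last_tag]][n], trimws(ln))
      }
      next
    }
    tag <- sub(tag_re, "\\1", ln)
    val <- sub(tag_re, "\\2", ln)
    if (tag == "TY") {
      cur <- list(); last_tag <- NULL
    } else if (tag == "ER") {
      recs[[length(recs) + 1L]] <- flush(cur); cur <- NULL; last_tag <- NULL
    } else if (!is.null(cur)) {
      cur[[tag]] <- c(cur[[tag]], val)
      last_tag <- tag
    }
  }
  if (!length(recs)) stop_("no RIS records found in ", path)
  df <- do.call(rbind, recs)
  if (anyNA(df$record_id)) {
    df$record_id[is.na(df$record_id)] <-
      make_record_ids(df$title[is.na(df$record_id)])
  }
  df
}

#' Write citation records to an RIS file
#'
#' @param records data frame of records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records_ris <- function(records, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  split_multi <- function(x) {
    x <- trimws(strsplit(x %||% "", ";", fixed = TRUE)[[1]])
    x[nzchar(x)]
  }
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    writeLines(c(
      "TY  - JOUR",
      paste0("ID  - ", r$record_id),
      paste0("TI  - ", r$title),
      if (nzchar(r$abstract %||% "")) paste0("AB  - ", r$abstract),
      paste0("AU  - ", split_multi(r$authors)),
      paste0("KW  - ", split_multi(r$keywords)),
      "ER  - ", ""), con)
  }
  invisible(path)
}

#' Read screening decisions from CSV
#'
#' Expects the fixed schema `record_id, senior_decision, second_decision,
#' fulltext_include`; labels are binarised via [normalize_decision()] and the
#' raw labels kept in audit columns.
#'
#' @param path decisions CSV path.
#' @return data frame with columns `record_id`, `senior`, `second`,
#'   `senior_raw`, `second_raw`, `fulltext_include`.
#' @export
read_decisions_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        encoding = "UTF-8")
  need <- c("record_id", "senior_decision")
  if (!all(need %in% names(df))) {
    stop_("decisions CSV must have a header with record_id, senior_decision: ",
          path)
  }
  if (nrow(df) == 0L) {
    stop_("decisions CSV is empty (zero decisions for every reviewer): ", path)
  }
  sec_raw <- df$second_decision %||% rep("", nrow(df))
  has_sec <- !is.na(sec_raw) & nzchar(trimws(sec_raw))
  out <- data.frame(
    record_id = df$record_id,
    senior = normalize_decision(df$senior_decision, df$record_id),
    senior_raw = df$senior_decision,
    second = NA_character_,
    second_raw = sec_raw,
    fulltext_include = (df$fulltext_include %||% "0") %in% c("1", "TRUE", "true"))
  out$second[has_sec] <- normalize_decision(sec_raw[has_sec],
                                            df$record_id[has_sec])
  out
}

#' Write screening decisions to CSV
#'
#' @param decisions decisions data frame (as in a [review_dataset()]).
#' @param fulltext_includes character vector of final-report include ids.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_decisions_csv <- function(decisions, fulltext_includes, path) {
  df <- data.frame(
    record_id = decisions$record_id,
    senior_decision = decisions$senior_raw %||% decisions$senior,
    second_decision = ifelse(is.na(decisions$second), "",
                             decisions$second_raw %||% decisions$second),
    fulltext_include = as.integer(decisions$record_id %in% fulltext_includes))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Load a review dataset from files
#'
#' @param records_path path to the records file (CSV or RIS per `format`).
#' @param decisions_path path to the decisions CSV.
#' @param format "csv" or "ris+csv" (RIS records + CSV decisions).
#' @param name review name (defaults to the records file name).
#' @param review_type "systematic" or "rapid"; when `NULL`, inferred from the
#'   presence of second-reviewer decisions.
#' @param quiet suppress the loaded-counts message.
#' @return a validated [review_dataset()].
#' @export
load_review_dataset <- function(records_path, decisions_path,
                                format = c("csv", "ris+csv"),
                                name = NULL, review_type = NULL,
                                quiet = FALSE) {
  format <- match.arg(format)
  records <- switch(format,
                    "csv" = read_records_csv(records_path),
                    "ris+csv" = read_records_ris(records_path))
  dec <- read_decisions_csv(decisions_path)
  if (is.null(review_type)) {
    review_type <- if (any(!is.na(dec$second))) "systematic" else "rapid"
  }
  ds <- review_dataset(
    name = name %||% sub("\\.[^.]+$", "", basename(records_path)),
    review_type = review_type,
    records = records,
    decisions = dec[c("record_id", "senior", "senior_raw", "second",
                      "second_raw")],
    fulltext_includes = dec$record_id[dec$fulltext_include])
  if (!quiet) {
    s <- summary(ds)
    message(sprintf(
      "loaded %s: N = %d, title/abstract includes = %d, full-text includes = %d",
      s$name, s$workload_n, s$ta_includes, s$fulltext_includes))
  }
  ds
}

#' Write a review dataset to a directory
#'
#' Writes `records.csv` (or `records.ris`), `decisions.csv`, and — when truth
#' labels are present — `truth.csv` (`record_id, truth_ta, truth_ft`).
#'
#' @param dataset a [review_dataset()].
#' @param dir output directory (created if needed).
#' @param format "csv" or "ris+csv".
#' @return the directory, invisibly.
#' @export
write_review_dataset <- function(dataset, dir, format = c("csv", "ris+csv")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "review_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "csv") {
    write_records_csv(dataset$records, file.path(dir, "records.csv"))
  } else {
    write_records_ris(dataset$records, file.path(dir, "records.ris"))
  }
  write_decisions_csv(dataset$decisions, dataset$fulltext_includes,
                      file.path(dir, "decisions.csv"))
  if (any(!is.na(dataset$records$truth_ta))) {
    tr <- data.frame(record_id = dataset$records$record_id,
                     truth_ta = as.integer(dataset$records$truth_ta),
                     truth_ft = as.integer(dataset$records$truth_ft))
    utils::write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  invisible(dir)
}
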