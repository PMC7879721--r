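#' Write / read messages as JSON-lines
#'
#' One JSON object per line with keys `message_id`, `transcript_id`,
#' `patient_id`, `timestamp` (ISO-8601) and `text`; the `date` column is
#' derived from the timestamp on read.
#'
#' @param messages Message data.frame.
#' @param path File path.
#' @return `write_messages_jsonl` returns `path` invisibly;
#'   `read_messages_jsonl` returns the message data.frame.
#' @export
write_messages_jsonl <- function(messages, path) {
  df <- messages[c("message_id", "transcript_id", "patient_id",
                   "timestamp", "text")]
  con <- file(path, open = "w")
  on.exit(close(con))
  jsonlite::stream_out(df, con, verbose = FALSE)
  invisible(path)
}

#' @rdname write_messages_jsonl
#' @export
read_messages_jsonl <- function(path) {
  con <- file(path, open = "r")
  on.exit(close(con))
  df <- jsonlite::stream_in(con, verbose = FALSE)
  df$date <- as_date(substr(df$timestamp, 1, 10))
  df[c("message_id", "transcript_id", "patient_id", "date", "timestamp",
       "text")]
}

#' Write / read intake assessments as CSV
#'
#' Columns: `patient_id`, `instrument` ("GAD7"/"PHQ9"), `item_1` ..
#' `item_9` (items 8-9 empty for GAD-7), `date`.
#'
#' @param assessments Assessment data.frame.
#' @param path File path.
#' @export
write_assessments_csv <- function(assessments, path) {
  utils::write.csv(assessments, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_assessments_csv
#' @export
read_assessments_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character",
                                       instrument = "character"))
  for (i in 1:9) {
    col <- paste0("item_", i)
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  }
  df$date <- as_date(df$date)
  df
}

#' Write planted ground truth as JSON
#' @param ground_truth A `ground_truth` object from [simulate_corpus()].
#' @param path File path.
#' @export
write_ground_truth_json <- function(ground_truth, path) {
  jsonlite::write_json(list(
    covid_assoc_terms = ground_truth$covid_assoc_terms,
    anti_assoc_terms = ground_truth$anti_assoc_terms,
    neutral_terms = ground_truth$neutral_terms,
    planted_gad7_shift = ground_truth$planted_gad7_shift,
    planted_phq9_shift = ground_truth$planted_phq9_shift,
    mention_flag = as.list(ground_truth$mention_flag)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
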