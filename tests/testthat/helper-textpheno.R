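# Small in-code fixtures shared across the suite.

make_messages <- function(texts, dates,
                          patients = rep("P00001", length(texts)),
                          transcripts = sub("^P", "T", patients)) {
  dates <- as.Date(dates)
  data.frame(
    message_id = sprintf("M%07d", seq_along(texts)),
    transcript_id = transcripts,
    patient_id = patients,
    date = dates,
    timestamp = if (length(dates)) paste0(format(dates, "%Y-%m-%d"), "T12:00:00Z") else character(0),
    text = texts,
    stringsAsFactors = FALSE
  )
}

make_assessments <- function(totals, dates, instrument = "GAD7",
                             patients = sprintf("P%05d", seq_along(totals))) {
  k <- if (instrument == "GAD7") 7L else 9L
  items <- t(vapply(as.integer(totals), function(tt) {
    # spread a total over k items without exceeding 3 per item
    base <- rep(tt %/% k, k)
    extra <- tt %% k
    if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    stopifnot(all(base <= 3), sum(base) == tt)
    base
  }, integer(k)))
  out <- data.frame(patient_id = patients, instrument = instrument,
                    stringsAsFactors = FALSE)
  for (i in 1:9) out[[paste0("item_", i)]] <- if (i <= k) items[, i] else NA_integer_
  out$date <- as.Date(dates)
  out
}

# Character-scan substring oracle, independent of grepl().
scan_contains <- function(text, pattern) {
  text <- tolower(text)
  np <- nchar(pattern)
  nt <- nchar(text)
  if (np == 0 || nt < np) return(FALSE)
  for (i in seq_len(nt - np + 1)) {
    if (substr(text, i, i + np - 1) == pattern) return(TRUE)
  }
  FALSE
}

# Exhaustive Benjamini-Hochberg step-up oracle: try every rank k and select
# everything at or below the largest passing one.
bh_oracle_select <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  passing <- which(ps <= seq_len(m) * q / m)
  if (!length(passing)) return(integer(0))
  sort(o[seq_len(max(passing))])
}
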