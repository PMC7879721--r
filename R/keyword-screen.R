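#' Seed-keyword lexicon for pandemic mentions
#'
#' @param patterns Nonempty character vector of lowercase literal substrings.
#'   The defaults are the four pandemic seed keywords.
#' @return Character vector of class `"seed_lexicon"`.
#' @export
seed_lexicon <- function(patterns = seed_keywords()) {
  patterns <- as.character(patterns)
  if (!length(patterns) || any(!nzchar(patterns)))
    stop("seed lexicon needs at least one nonempty pattern")
  if (any(patterns != tolower(patterns)))
    stop("seed patterns must be lowercase")
  structure(patterns, class = "seed_lexicon")
}

#' Flag messages containing pandemic seed keywords
#'
#' A message is flagged for a pattern iff the pattern occurs as a
#' case-insensitive substring of its text (so "corona" and "virus" both hit
#' "coronavirus"). Optionally the match can be restricted to whole words.
#'
#' @param messages data.frame with at least `message_id` and `text`.
#' @param lexicon A [seed_lexicon()].
#' @param word_boundary If `TRUE`, require the pattern to match at word
#'   boundaries instead of as a bare substring.
#' @return data.frame keyed by `message_id` with one logical column per
#'   pattern and an `any_pattern` column (the OR over patterns).
#' @export
flag_messages <- function(messages, lexicon = seed_lexicon(),
                          word_boundary = FALSE) {
  if (!inherits(lexicon, "seed_lexicon")) lexicon <- seed_lexicon(lexicon)
  txt <- tolower(as.character(messages$text))
  txt[is.na(txt)] <- ""
  hit <- vapply(unclass(lexicon), function(p) {
    if (word_boundary) grepl(paste0("\\b", p, "\\b"), txt, perl = TRUE)
    else grepl(p, txt, fixed = TRUE)
  }, logical(length(txt)))
  hit <- matrix(hit, nrow = length(txt),
                dimnames = list(NULL, unclass(lexicon)))
  out <- data.frame(message_id = messages$message_id,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out[colnames(hit)] <- as.data.frame(hit)
  out$any_pattern <- rowSums(hit) > 0
  out
}

# Align a flag table to a message table; errors if any message is uncovered.
align_flags <- function(messages, flags) {
  idx <- match(messages$message_id, flags$message_id)
  if (anyNA(idx)) stop("flags do not cover all messages")
  flags[idx, , drop = FALSE]
}

message_dates <- function(messages) {
  if (!is.null(messages$date)) return(as_date(messages$date))
  as_date(substr(messages$timestamp, 1, 10))
}

#' Monthly incidence of each seed pattern
#'
#' For every calendar month with at least one message, the percentage of
#' that month's messages containing each pattern, reported to 4 decimal
#' places (rounding half away from zero). Months with no messages are
#' absent, not zero.
#'
#' @param messages Message data.frame (needs `message_id` and a `date` or
#'   `timestamp` column).
#' @param flags Output of [flag_messages()] covering all messages.
#' @return data.frame with `year`, `month`, `n_messages`, and one percentage
#'   column per pattern, in chronological order.
#' @export
monthly_incidence <- function(messages, flags) {
  patterns <- setdiff(names(flags), c("message_id", "any_pattern"))
  if (nrow(messages) == 0) {
    out <- data.frame(year = integer(0), month = integer(0),
                      n_messages = integer(0), check.names = FALSE)
    out[patterns] <- numeric(0)
    return(out)
  }
  f <- align_flags(messages, flags)
  dates <- message_dates(messages)
  ym <- format(dates, "%Y-%m")
  lev <- sort(unique(ym))
  g <- factor(ym, levels = lev)
  n <- as.integer(table(g))
  out <- data.frame(
    year = as.integer(substr(lev, 1, 4)),
    month = as.integer(substr(lev, 6, 7)),
    n_messages = n, check.names = FALSE
  )
  for (p in patterns)
    out[[p]] <- percent(as.numeric(tapply(f[[p]], g, sum)), n, digits = 4)
  out
}

#' Share of transcripts containing any pandemic mention
#'
#' A transcript counts as mentioning iff at least one of its messages has
#' the any-pattern flag set.
#'
#' @inheritParams monthly_incidence
#' @return List with `n_mentioning`, `n_total`, and `rate_pct` (the
#'   percentage rounded half-away-from-zero to 1 decimal).
#' @export
transcript_mention_rate <- function(messages, flags) {
  if (nrow(messages) == 0) stop("undefined rate: zero transcripts")
  f <- align_flags(messages, flags)
  by_tr <- tapply(f$any_pattern, messages$transcript_id, any)
  n_total <- length(by_tr)
  n_mentioning <- sum(by_tr)
  list(n_mentioning = n_mentioning, n_total = n_total,
       rate_pct = percent(n_mentioning, n_total, digits = 1))
}

#' Daily proportion of mention-flagged messages
#'
#' For every day in the window with at least one message, the proportion of
#' that day's messages whose any-pattern flag is true. Days without
#' messages are absent from the signal (a zero would inject artificial
#' structure into downstream correlations).
#'
#' @inheritParams monthly_incidence
#' @param window Date window (Date[2] or "YYYY-MM-DD:YYYY-MM-DD").
#' @return data.frame of class `"daily_mention_signal"` with `date`,
#'   `n_messages`, `proportion`.
#' @export
daily_mention_proportion <- function(messages, flags, window) {
  window <- as_window(window)
  dates <- message_dates(messages)
  keep <- dates >= window[1] & dates <= window[2]
  out <- data.frame(date = as.Date(character(0)), n_messages = integer(0),
                    proportion = numeric(0))
  if (any(keep)) {
    f <- align_flags(messages[keep, , drop = FALSE], flags)
    d <- dates[keep]
    lev <- sort(unique(d))
    g <- factor(as.character(d), levels = as.character(lev))
    n <- as.integer(table(g))
    out <- data.frame(
      date = lev, n_messages = n,
      proportion = as.numeric(tapply(f$any_pattern, g, sum)) / n
    )
  }
  class(out) <- c("daily_mention_signal", "data.frame")
  out
}
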