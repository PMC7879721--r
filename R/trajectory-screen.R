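#' Tokenize a text into unigrams through n-grams
#'
#' Lowercases, strips punctuation characters from whitespace-delimited
#' tokens (so "COVID-19" becomes the single token "covid19"), and emits all
#' contiguous n-grams up to `n_max`, joined by single spaces.
#'
#' @param text A single character string.
#' @param n_max Highest n-gram order (>= 1).
#' @return Character vector (a multiset: repeated n-grams repeat).
#' @export
#' @examples
#' tokenize_ngrams("so so tired", n_max = 2)
tokenize_ngrams <- function(text, n_max = 2) {
  if (n_max < 1) stop("n_max must be >= 1")
  toks <- tokenize_words(text)
  if (!length(toks)) return(character(0))
  out <- toks
  n <- 2
  while (n <= n_max && length(toks) >= n) {
    windows <- embed(toks, n)[, n:1, drop = FALSE]
    out <- c(out, apply(windows, 1, paste, collapse = " "))
    n <- n + 1
  }
  out
}

# Unigram word tokens of one string: lowercase, punctuation removed.
tokenize_words <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- gsub("[^[:alnum:][:space:]]", "", tolower(text))
  toks <- strsplit(x, "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

# Vectorized tokens + n-grams over many texts, preserving text membership
# (n-grams never cross a text boundary). Returns term and group vectors.
tokenize_corpus <- function(texts, groups, n_max) {
  x <- gsub("[^[:alnum:][:space:]]", "", tolower(texts))
  toklist <- strsplit(x, "[[:space:]]+")
  lens <- lengths(toklist)
  toks <- unlist(toklist, use.names = FALSE)
  grp <- rep(groups, lens)
  keep <- nzchar(toks)
  toks <- toks[keep]
  grp <- grp[keep]
  txt_id <- rep(seq_along(texts), lens)[keep]
  term <- toks
  term_grp <- grp
  if (n_max >= 2 && length(toks) >= 2) {
    for (n in 2:n_max) {
      if (length(toks) < n) break
      m <- length(toks) - n + 1
      same <- txt_id[seq_len(m)] == txt_id[seq_len(m) + n - 1]
      if (!any(same)) next
      idx <- which(same)
      piece <- toks[idx]
      for (k in 1:(n - 1)) piece <- paste(piece, toks[idx + k])
      term <- c(term, piece)
      term_grp <- c(term_grp, grp[idx])
    }
  }
  list(term = term, group = term_grp)
}

#' Build the day-by-term count matrix
#'
#' Pools all messages of each calendar day in the window into one "text
#' day" document, counts unigrams through `n_max`-grams (n-grams never span
#' message boundaries), and drops terms appearing on fewer than `min_df`
#' distinct days.
#'
#' @param messages Message data.frame (`text` plus `date`/`timestamp`).
#' @param window Date window.
#' @param n_max Highest n-gram order (default 2: words and bigram phrases).
#' @param min_df Minimum document (day) frequency for a term to be kept
#'   (default 3; a correlation over fewer support points is meaningless).
#' @return Object of class `"daily_term_matrix"`: a list with sparse
#'   `counts` (days x terms, `Matrix::dgCMatrix`), `days` (Date), `terms`,
#'   `df` (per-term day frequency), `N` (number of days).
#' @export
build_daily_matrix <- function(messages, window, n_max = 2, min_df = 3) {
  window <- as_window(window)
  dates <- message_dates(messages)
  keep <- !is.na(dates) & dates >= window[1] & dates <= window[2]
  msgs <- messages[keep, , drop = FALSE]
  dates <- dates[keep]

  empty <- function(days) {
    structure(list(
      counts = Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                    dims = c(length(days), 0),
                                    dimnames = list(as.character(days), character(0))),
      days = days, terms = character(0),
      df = stats::setNames(numeric(0), character(0)), N = length(days)
    ), class = "daily_term_matrix")
  }
  if (nrow(msgs) == 0) return(empty(as.Date(character(0))))

  days <- sort(unique(dates))
  tk <- tokenize_corpus(msgs$text, match(dates, days), n_max)
  if (!length(tk$term)) return(empty(days))

  terms <- sort(unique(tk$term))
  m <- Matrix::sparseMatrix(
    i = tk$group, j = match(tk$term, terms), x = 1,
    dims = c(length(days), length(terms)),
    dimnames = list(as.character(days), terms)
  )
  df <- Matrix::colSums(m > 0)
  keep_t <- df >= min_df
  m <- m[, keep_t, drop = FALSE]
  structure(list(counts = m, days = days, terms = colnames(m),
                 df = df[keep_t], N = length(days)),
            class = "daily_term_matrix")
}

#' @export
print.daily_term_matrix <- function(x, ...) {
  cat(sprintf("day-by-term count matrix: %d days x %d terms (%.2f%% nonzero)\n",
              x$N, length(x$terms),
              if (x$N * length(x$terms) > 0)
                100 * Matrix::nnzero(x$counts) / (x$N * length(x$terms)) else 0))
  invisible(x)
}

#' TF-IDF transform of a day-by-term matrix
#'
#' Weight = raw count x smoothed log inverse document frequency,
#' `count * (1 + ln((1 + N) / (1 + df)))`, with no per-day normalization:
#' trajectories stay on a count-proportional scale for correlation, the
#' sparsity pattern is preserved, and a term present on every day keeps its
#' raw counts (idf factor exactly 1).
#'
#' @param matrix A [build_daily_matrix()] result.
#' @return Object of class `"tfidf_matrix"` with `weights` in place of
#'   `counts` (same axes, `df`, `N`).
#' @export
tfidf_transform <- function(matrix) {
  if (!inherits(matrix, "daily_term_matrix")) stop("need a daily_term_matrix")
  idf <- 1 + log((1 + matrix$N) / (1 + matrix$df))
  w <- matrix$counts
  if (length(w@x)) w@x <- w@x * idf[rep(seq_along(idf), diff(w@p))]
  structure(list(weights = w, days = matrix$days, terms = matrix$terms,
                 df = matrix$df, N = matrix$N, idf = idf),
            class = "tfidf_matrix")
}

#' Correlate every term's TF-IDF trajectory with the daily mention signal
#'
#' Pearson correlation over the days common to the matrix and the signal,
#' with a two-sided p-value from the exact t transform of r on n - 2
#' degrees of freedom. Terms with zero variance over the paired days are
#' skipped with a warning; a zero-variance signal skips everything.
#'
#' @param tfidf A [tfidf_transform()] result, a [build_daily_matrix()]
#'   result, or a plain numeric matrix with day rownames (`"YYYY-MM-DD"`)
#'   and term colnames.
#' @param signal A [daily_mention_proportion()] result, or a named numeric
#'   vector keyed by day.
#' @return data.frame with `term`, `r`, `p`, `n` (paired days).
#' @export
correlate_terms <- function(tfidf, signal) {
  if (inherits(tfidf, "tfidf_matrix")) {
    X <- tfidf$weights
  } else if (inherits(tfidf, "daily_term_matrix")) {
    X <- tfidf$counts
  } else {
    X <- tfidf
  }
  if (inherits(signal, "data.frame")) {
    y <- stats::setNames(signal$proportion, as.character(signal$date))
  } else {
    y <- signal
  }
  y <- y[!is.na(y)]
  common <- intersect(rownames(X), names(y))
  n <- length(common)
  if (n < 3) stop("insufficient data: fewer than 3 paired days")
  X <- as.matrix(X[common, , drop = FALSE])
  y <- as.numeric(y[common])

  empty <- data.frame(term = character(0), r = numeric(0), p = numeric(0),
                      n = integer(0), stringsAsFactors = FALSE)
  if (ncol(X) == 0) return(empty)

  yc <- y - mean(y)
  syy <- sum(yc^2)
  if (syy <= 0) {
    warning("mention signal has zero variance over the paired days; all terms skipped")
    return(empty)
  }
  Xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(Xc^2)
  zero_var <- sxx <= 0
  if (any(zero_var))
    warning(sprintf("skipping %d zero-variance term(s)", sum(zero_var)))
  Xc <- Xc[, !zero_var, drop = FALSE]
  sxx <- sxx[!zero_var]
  r <- as.numeric(crossprod(Xc, yc)) / sqrt(sxx * syy)
  r <- pmin(1, pmax(-1, r))
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- ifelse(abs(r) >= 1, 0, 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE))
  data.frame(term = colnames(Xc), r = r, p = pmin(p, 1), n = n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg selection of correlated terms
#'
#' Step-up selection over all tested terms' p-values at FDR level `q`
#' (`stats::p.adjust(method = "BH")`), with survivors partitioned by the
#' sign of their correlation.
#'
#' @param correlations Output of [correlate_terms()].
#' @param q FDR level in (0, 1); default 0.01.
#' @return Object of class `"selection_result"`: a `table` data.frame
#'   (`term`, `r`, `p`, `p_adjusted`, `selected`, `sign`), the
#'   `positive_terms` / `negative_terms` character vectors, `q_threshold`,
#'   and `n_tested`.
#' @export
bh_select <- function(correlations, q = 0.01) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  if (nrow(correlations) < 1) stop("need at least one correlation record")
  p_adj <- stats::p.adjust(correlations$p, method = "BH")
  selected <- p_adj <= q
  sgn <- ifelse(correlations$r > 0, "positive",
                ifelse(correlations$r < 0, "negative", "zero"))
  tab <- data.frame(correlations[c("term", "r", "p")], p_adjusted = p_adj,
                    selected = selected, sign = sgn,
                    stringsAsFactors = FALSE)
  structure(list(
    table = tab,
    positive_terms = tab$term[selected & sgn == "positive"],
    negative_terms = tab$term[selected & sgn == "negative"],
    q_threshold = q, n_tested = nrow(tab)
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("FDR selection at q = %g over %d tested terms\n",
              x$q_threshold, x$n_tested))
  cat(sprintf("  %d positively and %d negatively correlated terms selected\n",
              length(x$positive_terms), length(x$negative_terms)))
  invisible(x)
}
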