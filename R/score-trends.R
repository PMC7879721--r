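#' Score a single questionnaire administration
#'
#' Both instruments use the published summation rule: the total is the sum
#' of the item responses (GAD-7: 7 items, total 0-21; PHQ-9: 9 items,
#' total 0-27).
#'
#' @param items Integer vector of item responses, each in 0-3.
#' @param instrument `"GAD7"` or `"PHQ9"`.
#' @return The integer total score.
#' @export
#' @examples
#' score_instrument(c(1, 2, 0, 3, 1, 0, 2), "GAD7")  # 9
score_instrument <- function(items, instrument) {
  k <- instrument_items(instrument)
  if (length(items) != k)
    stop(sprintf("%s needs %d items, got %d", instrument, k, length(items)))
  if (anyNA(items) || any(items != as.integer(items)) ||
      any(items < 0 | items > 3))
    stop("item responses must be integers in 0-3")
  sum(as.integer(items))
}

# Totals for one instrument from an assessment table. Incomplete
# questionnaires (any NA among the instrument's items) are excluded;
# out-of-range responses are an error.
assessment_totals <- function(records, instrument) {
  k <- instrument_items(instrument)
  r <- records[records$instrument == instrument, , drop = FALSE]
  if (nrow(r) == 0)
    return(data.frame(patient_id = character(0), date = as.Date(character(0)),
                      total = integer(0)))
  items <- as.matrix(r[paste0("item_", seq_len(k))])
  complete <- rowSums(is.na(items)) == 0
  items <- items[complete, , drop = FALSE]
  if (length(items) && (any(items < 0 | items > 3) || any(items != round(items))))
    stop("item responses must be integers in 0-3")
  data.frame(patient_id = r$patient_id[complete],
             date = as_date(r$date)[complete],
             total = as.integer(rowSums(items)))
}

#' Rolling pooled mean of intake scores
#'
#' For every day `d` with at least one intake in the trailing window
#' `(d - window_days, d]`, the pooled (intake-weighted) mean total score of
#' all intakes in that window. Days whose window is empty are omitted.
#'
#' @param records Assessment data.frame (see [simulate_assessments()] for
#'   the column layout).
#' @param instrument `"GAD7"` or `"PHQ9"`.
#' @param window_days Trailing window length in days (default 14, i.e. a
#'   2-week rolling average).
#' @return data.frame of class `"rolling_series"` with `date`, `mean`, `n`.
#' @export
rolling_intake_series <- function(records, instrument, window_days = 14) {
  if (window_days < 1) stop("window_days must be >= 1")
  tot <- assessment_totals(records, instrument)
  if (nrow(tot) == 0) {
    out <- data.frame(date = as.Date(character(0)), mean = numeric(0),
                      n = integer(0))
  } else {
    days <- seq(min(tot$date), max(tot$date), by = "day")
    g <- factor(as.character(tot$date), levels = as.character(days))
    day_sum <- as.numeric(tapply(tot$total, g, sum, default = 0))
    day_n <- as.integer(table(g))
    csum <- cumsum(day_sum)
    cn <- cumsum(day_n)
    lag <- function(x, k) c(rep(0, min(k, length(x))), utils::head(x, -k))
    wsum <- csum - lag(csum, window_days)
    wn <- cn - lag(cn, window_days)
    keep <- wn >= 1
    out <- data.frame(date = days[keep], mean = wsum[keep] / wn[keep],
                      n = wn[keep])
  }
  attr(out, "instrument") <- instrument
  attr(out, "window_days") <- window_days
  class(out) <- c("rolling_series", "data.frame")
  out
}

#' @export
plot.rolling_series <- function(x, ..., col = "steelblue", lwd = 2) {
  instrument <- attr(x, "instrument")
  graphics::plot(x$date, x$mean, type = "l", col = col, lwd = lwd,
                 xlab = "date",
                 ylab = sprintf("%s rolling mean (%d-day window)",
                                instrument, attr(x, "window_days")),
                 ...)
  invisible(x)
}

#' Pre/post shift in mean intake severity
#'
#' Point estimate: mean total score in the comparison window minus the mean
#' in the baseline window. Uncertainty: percentile bootstrap over patients
#' (independent resampling within each arm); significance: Welch's
#' unequal-variance two-sample t test.
#'
#' @param records Assessment data.frame.
#' @param instrument `"GAD7"` or `"PHQ9"`.
#' @param baseline_window,comparison_window Disjoint date windows, each
#'   containing at least 2 intakes.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Integer seed for the bootstrap stream.
#' @param conf_level Confidence level for the percentile interval.
#' @return Object of class `"shift_estimate"`: `delta`, `ci_low`, `ci_high`,
#'   `p_value`, `n_baseline`, `n_comparison`, plus metadata.
#' @export
estimate_shift <- function(records, instrument, baseline_window,
                           comparison_window, n_boot = 10000, seed = 1L,
                           conf_level = 0.95) {
  baseline_window <- as_window(baseline_window)
  comparison_window <- as_window(comparison_window)
  if (baseline_window[1] <= comparison_window[2] &&
      comparison_window[1] <= baseline_window[2])
    stop("baseline and comparison windows must be disjoint")
  tot <- assessment_totals(records, instrument)
  base <- tot$total[tot$date >= baseline_window[1] & tot$date <= baseline_window[2]]
  comp <- tot$total[tot$date >= comparison_window[1] & tot$date <= comparison_window[2]]
  if (length(base) < 2 || length(comp) < 2)
    stop("insufficient data: each window needs at least 2 intakes")

  delta <- mean(comp) - mean(base)
  boots <- with_seed(substream_seed(seed, "shift-bootstrap"), {
    bm <- matrix(sample(base, length(base) * n_boot, replace = TRUE),
                 ncol = n_boot)
    cm <- matrix(sample(comp, length(comp) * n_boot, replace = TRUE),
                 ncol = n_boot)
    colMeans(cm) - colMeans(bm)
  })
  alpha <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
  # Welch test degenerates when both arms are constant; fall back to the
  # limiting p-value (1 for equal means, 0 otherwise)
  p <- tryCatch(stats::t.test(comp, base)$p.value,
                error = function(e)
                  if (isTRUE(all.equal(mean(comp), mean(base)))) 1 else 0)

  structure(list(
    delta = delta, ci_low = ci[1], ci_high = ci[2], p_value = p,
    n_baseline = length(base), n_comparison = length(comp),
    instrument = instrument, n_boot = n_boot, conf_level = conf_level,
    baseline_window = baseline_window, comparison_window = comparison_window
  ), class = "shift_estimate")
}

#' @export
print.shift_estimate <- function(x, ...) {
  cat(sprintf("%s intake severity shift (comparison - baseline)\n", x$instrument))
  cat(sprintf("  delta = %.2f (%d%% CI %.2f to %.2f), P = %s\n",
              x$delta, round(100 * x$conf_level), x$ci_low, x$ci_high,
              format.pval(x$p_value, digits = 3, eps = 0.001)))
  cat(sprintf("  n = %d baseline, %d comparison; percentile bootstrap, %d resamples\n",
              x$n_baseline, x$n_comparison, x$n_boot))
  invisible(x)
}
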