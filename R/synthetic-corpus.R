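#' Configuration for the synthetic message-corpus generator
#'
#' Bundles every parameter of the simulated study: cohort size, calendar
#' geometry (a pre-pandemic era, a changepoint, and a linear ramp of the
#' per-message mention probability), the three planted vocabulary strata,
#' and the intake-instrument score model. The generator's defaults describe
#' a cohort of 200 patients observed from January through early June 2020
#' whose messages start mentioning the pandemic at the March 1 changepoint,
#' and whose GAD-7 intake severity rises by 1.4 total points after the
#' changepoint while PHQ-9 severity does not move.
#'
#' @param n_patients Number of patients (each owns exactly one transcript).
#' @param start_date,changepoint_date,end_date Calendar dates delimiting the
#'   study; `start_date < end_date` and `changepoint_date > start_date` are
#'   required. A changepoint past `end_date` simply means the pandemic era
#'   never arrives.
#' @param messages_per_patient_day Poisson mean number of messages a patient
#'   sends per calendar day.
#' @param words_per_message Poisson mean filler words per message (min 1).
#' @param vocab_sizes Integer triple: number of covid-associated,
#'   anti-associated and neutral vocabulary words.
#' @param mention_prob_pre,mention_prob_post Probability that a message is
#'   generated in "mention" mode (i.e. carries a seed keyword) before the
#'   changepoint and after the ramp; `pre <= post`.
#' @param ramp_days Length in days of the linear ramp from
#'   `mention_prob_pre` at the changepoint to `mention_prob_post`;
#'   0 means an instantaneous jump at the changepoint.
#' @param assoc_boost Multiplicative sampling weight (> 1) of
#'   covid-associated words inside mention-mode messages.
#' @param anti_suppress Multiplicative weight in `[0, 1)` of anti-associated
#'   words inside mention-mode messages.
#' @param gad7_baseline_mean,phq9_baseline_mean Item-level mean response
#'   (0-3 scale) before the changepoint.
#' @param gad7_shift,phq9_shift Item-level mean shift applied to intakes
#'   dated on/after the changepoint. The planted total-score shift is
#'   `7 * gad7_shift` (GAD-7) and `9 * phq9_shift` (PHQ-9).
#' @param seed Master integer RNG seed; corpus and assessments draw from
#'   separate substreams derived from it.
#' @return A list of class `"generator_config"`.
#' @seealso [simulate_corpus()], [simulate_assessments()], [simulate_cohort()]
#' @export
generator_config <- function(n_patients = 200,
                             start_date = "2020-01-01",
                             changepoint_date = "2020-03-01",
                             end_date = "2020-06-09",
                             messages_per_patient_day = 0.5,
                             words_per_message = 20,
                             vocab_sizes = c(n_covid_assoc = 20,
                                             n_anti_assoc = 20,
                                             n_neutral = 160),
                             mention_prob_pre = 0.001,
                             mention_prob_post = 0.30,
                             ramp_days = 30,
                             assoc_boost = 8,
                             anti_suppress = 0.2,
                             gad7_baseline_mean = 1.2,
                             gad7_shift = 0.2,
                             phq9_baseline_mean = 1.2,
                             phq9_shift = 0,
                             seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    start_date = as_date(start_date),
    changepoint_date = as_date(changepoint_date),
    end_date = as_date(end_date),
    messages_per_patient_day = messages_per_patient_day,
    words_per_message = words_per_message,
    vocab_sizes = as.integer(vocab_sizes),
    mention_prob_pre = mention_prob_pre,
    mention_prob_post = mention_prob_post,
    ramp_days = as.integer(ramp_days),
    assoc_boost = assoc_boost,
    anti_suppress = anti_suppress,
    gad7_baseline_mean = gad7_baseline_mean,
    gad7_shift = gad7_shift,
    phq9_baseline_mean = phq9_baseline_mean,
    phq9_shift = phq9_shift,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(config) {
  if (!inherits(config, "generator_config")) stop("not a generator_config")
  with(config, {
    if (n_patients < 0) stop("configuration error: n_patients must be >= 0")
    if (!(start_date < end_date)) stop("configuration error: start_date must precede end_date")
    if (!(changepoint_date > start_date)) stop("configuration error: changepoint_date must follow start_date")
    if (messages_per_patient_day < 0) stop("configuration error: negative message rate")
    if (words_per_message <= 0) stop("configuration error: words_per_message must be positive")
    if (length(vocab_sizes) != 3 || any(vocab_sizes < 0)) stop("configuration error: vocab_sizes must be 3 nonnegative counts")
    if (mention_prob_pre < 0 || mention_prob_pre > 1 ||
        mention_prob_post < 0 || mention_prob_post > 1)
      stop("configuration error: mention probabilities must lie in [0,1]")
    if (mention_prob_pre > mention_prob_post)
      stop("configuration error: mention_prob_pre must not exceed mention_prob_post")
    if (ramp_days < 0) stop("configuration error: ramp_days must be >= 0")
    if (assoc_boost <= 1) stop("configuration error: assoc_boost must exceed 1")
    if (anti_suppress < 0 || anti_suppress >= 1) stop("configuration error: anti_suppress must lie in [0,1)")
  })
  invisible(config)
}

# The four literal pandemic seed keywords.
seed_keywords <- function() c("corona", "virus", "covid", "pandemic")

make_vocab <- function(vocab_sizes) {
  list(
    covid_assoc = if (vocab_sizes[1]) sprintf("cvw%03d", seq_len(vocab_sizes[1])) else character(0),
    anti_assoc = if (vocab_sizes[2]) sprintf("anw%03d", seq_len(vocab_sizes[2])) else character(0),
    neutral = if (vocab_sizes[3]) sprintf("neu%03d", seq_len(vocab_sizes[3])) else character(0)
  )
}

#' Expected mention probability on each calendar day
#'
#' Before the changepoint the probability is `mention_prob_pre`; from the
#' changepoint it ramps linearly to `mention_prob_post` over `ramp_days`
#' days and stays there (with `ramp_days = 0` it jumps at the changepoint).
#'
#' @param dates Date vector.
#' @param config A [generator_config()].
#' @return Numeric vector of per-message mention probabilities.
#' @export
mention_probability <- function(dates, config) {
  validate_generator_config(config)
  dates <- as_date(dates)
  d <- as.numeric(dates - config$changepoint_date)
  frac <- if (config$ramp_days == 0) as.numeric(d >= 0) else pmin(1, pmax(0, d / config$ramp_days))
  config$mention_prob_pre + (config$mention_prob_post - config$mention_prob_pre) * frac
}

#' Simulate a message corpus with planted vocabulary structure
#'
#' Generates one transcript per patient. Message counts per patient-day are
#' Poisson; each message is independently flagged "mention mode" with the
#' day's [mention_probability()]. Filler words are drawn bag-of-words from
#' the three vocabulary strata — uniformly in ordinary messages, with
#' covid-associated words up-weighted by `assoc_boost` and anti-associated
#' words down-weighted by `anti_suppress` in mention-mode messages — and
#' every mention-mode message additionally carries one uniformly chosen seed
#' keyword as a literal token. Identical config (including seed) yields
#' byte-identical output.
#'
#' @param config A [generator_config()].
#' @return A list with components:
#'   \describe{
#'     \item{messages}{data.frame with columns `message_id`, `transcript_id`,
#'       `patient_id`, `date` (Date), `timestamp` (ISO-8601 character),
#'       `text`.}
#'     \item{ground_truth}{list of class `"ground_truth"`: the three disjoint
#'       term sets, the planted total-score shifts, and the per-message
#'       mention-mode flag.}
#'   }
#' @export
simulate_corpus <- function(config) {
  validate_generator_config(config)
  vocab <- make_vocab(config$vocab_sizes)
  all_terms <- unlist(vocab, use.names = FALSE)
  if (!length(all_terms)) stop("configuration error: empty vocabulary")
  seeds <- seed_keywords()

  days <- seq(config$start_date, config$end_date, by = "day")
  p_day <- mention_probability(days, config)
  n_pat <- config$n_patients

  empty_messages <- data.frame(
    message_id = character(0), transcript_id = character(0),
    patient_id = character(0), date = as.Date(character(0)),
    timestamp = character(0), text = character(0),
    stringsAsFactors = FALSE
  )

  res <- with_seed(substream_seed(config$seed, "corpus"), {
    if (n_pat == 0) {
      list(messages = empty_messages, mention = logical(0))
    } else {
      counts <- stats::rpois(n_pat * length(days), config$messages_per_patient_day)
      pat_idx <- rep(rep(seq_len(n_pat), each = length(days)), counts)
      day_idx <- rep(rep(seq_along(days), times = n_pat), counts)
      n_msg <- length(pat_idx)
      if (n_msg == 0) {
        list(messages = empty_messages, mention = logical(0))
      } else {
        mention <- stats::rbinom(n_msg, 1L, p_day[day_idx]) == 1L
        n_words <- pmax(1L, stats::rpois(n_msg, config$words_per_message))

        # stratified filler: one categorical draw per token
        w_mention <- rep(c(config$assoc_boost, config$anti_suppress, 1),
                         times = config$vocab_sizes)
        tok_msg <- rep(seq_len(n_msg), n_words)
        tok_mention <- mention[tok_msg]
        words <- character(length(tok_msg))
        if (any(!tok_mention))
          words[!tok_mention] <- sample(all_terms, sum(!tok_mention), replace = TRUE)
        if (any(tok_mention))
          words[tok_mention] <- sample(all_terms, sum(tok_mention), replace = TRUE,
                                       prob = w_mention)
        texts <- vapply(split(words, factor(tok_msg, levels = seq_len(n_msg))),
                        paste, character(1), collapse = " ")
        if (any(mention)) {
          injected <- sample(seeds, sum(mention), replace = TRUE)
          texts[mention] <- paste(texts[mention], injected)
        }

        secs <- floor(stats::runif(n_msg, 0, 86400))
        stamp <- format(as.POSIXct(days[day_idx], tz = "UTC") + secs,
                        "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
        msgs <- data.frame(
          message_id = sprintf("M%07d", seq_len(n_msg)),
          transcript_id = sprintf("T%05d", pat_idx),
          patient_id = sprintf("P%05d", pat_idx),
          date = days[day_idx],
          timestamp = stamp,
          text = unname(texts),
          stringsAsFactors = FALSE
        )
        list(messages = msgs, mention = mention)
      }
    }
  })

  gt <- structure(list(
    covid_assoc_terms = vocab$covid_assoc,
    anti_assoc_terms = vocab$anti_assoc,
    neutral_terms = vocab$neutral,
    planted_gad7_shift = 7 * config$gad7_shift,
    planted_phq9_shift = 9 * config$phq9_shift,
    mention_flag = stats::setNames(res$mention, res$messages$message_id)
  ), class = "ground_truth")

  list(messages = res$messages, ground_truth = gt)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Planted ground truth\n")
  cat(sprintf("  vocabulary strata: %d covid-associated, %d anti-associated, %d neutral\n",
              length(x$covid_assoc_terms), length(x$anti_assoc_terms),
              length(x$neutral_terms)))
  cat(sprintf("  planted total-score shifts: GAD-7 %+.2f, PHQ-9 %+.2f\n",
              x$planted_gad7_shift, x$planted_phq9_shift))
  cat(sprintf("  mention-mode messages: %d of %d\n",
              sum(x$mention_flag), length(x$mention_flag)))
  invisible(x)
}

instrument_items <- function(instrument) {
  switch(instrument, GAD7 = 7L, PHQ9 = 9L,
         stop("unknown instrument: ", instrument))
}

# Item responses around a clamped item-level mean: Binomial(3, mean/3), so
# responses stay in {0,1,2,3} and the item mean is hit exactly.
draw_items <- function(n, k_items, item_mean) {
  p <- min(3, max(0, item_mean)) / 3
  matrix(stats::rbinom(n * k_items, 3L, p), nrow = n, ncol = k_items)
}

#' Simulate intake GAD-7 and PHQ-9 assessments
#'
#' One GAD-7 and one PHQ-9 intake per patient. Item responses are integers
#' in 0-3 drawn as Binomial(3, mean/3) around the configured item-level
#' mean; intakes dated on/after the changepoint use the shifted mean. Draws
#' come from an "assessments" RNG substream of the master seed, independent
#' of the corpus stream.
#'
#' @param config A [generator_config()].
#' @param intake_dates Optional Date vector of length `n_patients` giving
#'   each patient's intake date (NAs are filled with uniform draws from the
#'   study window). When omitted, all intake dates are drawn uniformly;
#'   [simulate_cohort()] passes first-message dates here instead.
#' @return data.frame with columns `patient_id`, `instrument`
#'   ("GAD7"/"PHQ9"), `item_1` .. `item_9` (items 8-9 `NA` for GAD-7),
#'   `date`.
#' @export
simulate_assessments <- function(config, intake_dates = NULL) {
  validate_generator_config(config)
  n_pat <- config$n_patients
  if (!is.null(intake_dates) && length(intake_dates) != n_pat)
    stop("intake_dates must have one date per patient")

  empty <- data.frame(
    patient_id = character(0), instrument = character(0),
    matrix(integer(0), 0, 9, dimnames = list(NULL, paste0("item_", 1:9))),
    date = as.Date(character(0)), stringsAsFactors = FALSE
  )
  if (n_pat == 0) return(empty)

  with_seed(substream_seed(config$seed, "assessments"), {
    days <- seq(config$start_date, config$end_date, by = "day")
    if (is.null(intake_dates)) intake_dates <- rep(as.Date(NA), n_pat)
    intake_dates <- as_date(intake_dates)
    nas <- is.na(intake_dates)
    if (any(nas)) intake_dates[nas] <- sample(days, sum(nas), replace = TRUE)
    post <- intake_dates >= config$changepoint_date

    one_instrument <- function(instrument, base_mean, shift) {
      k <- instrument_items(instrument)
      items <- matrix(NA_integer_, n_pat, 9,
                      dimnames = list(NULL, paste0("item_", 1:9)))
      if (any(!post)) items[!post, 1:k] <- draw_items(sum(!post), k, base_mean)
      if (any(post)) items[post, 1:k] <- draw_items(sum(post), k, base_mean + shift)
      data.frame(
        patient_id = sprintf("P%05d", seq_len(n_pat)),
        instrument = instrument, items,
        date = intake_dates, stringsAsFactors = FALSE
      )
    }
    out <- rbind(
      one_instrument("GAD7", config$gad7_baseline_mean, config$gad7_shift),
      one_instrument("PHQ9", config$phq9_baseline_mean, config$phq9_shift)
    )
    rownames(out) <- NULL
    out
  })
}

#' Simulate a full cohort: corpus plus matching intake assessments
#'
#' Runs [simulate_corpus()] and then [simulate_assessments()] with each
#' patient's intake dated at their first message (patients who happened to
#' send no messages get a uniformly drawn intake date).
#'
#' @param config A [generator_config()].
#' @return List with `messages`, `assessments`, `ground_truth`.
#' @export
simulate_cohort <- function(config) {
  corpus <- simulate_corpus(config)
  first_dates <- rep(as.Date(NA), config$n_patients)
  if (nrow(corpus$messages)) {
    firsts <- tapply(corpus$messages$date, corpus$messages$patient_id, min)
    ids <- sprintf("P%05d", seq_len(config$n_patients))
    hit <- ids %in% names(firsts)
    first_dates[hit] <- as.Date(as.numeric(firsts[ids[hit]]),
                                origin = "1970-01-01")
  }
  assessments <- simulate_assessments(config, intake_dates = first_dates)
  list(messages = corpus$messages, assessments = assessments,
       ground_truth = corpus$ground_truth)
}
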