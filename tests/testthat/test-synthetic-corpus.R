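test_that("config validation enforces the documented invariants", {
  expect_error(generator_config(start_date = "2020-06-01", end_date = "2020-01-01"),
               "configuration error")
  expect_error(generator_config(mention_prob_pre = 0.5, mention_prob_post = 0.1),
               "configuration error")
  expect_error(generator_config(assoc_boost = 0.9), "configuration error")
  expect_error(generator_config(anti_suppress = 1), "configuration error")
  expect_error(generator_config(mention_prob_post = 1.5), "configuration error")
})

test_that("empty cohort yields an empty corpus, not an error", {
  sim <- simulate_corpus(generator_config(n_patients = 0))
  expect_identical(nrow(sim$messages), 0L)
  expect_length(sim$ground_truth$mention_flag, 0)
  expect_identical(nrow(simulate_assessments(generator_config(n_patients = 0))), 0L)
})

test_that("changepoint past the end with zero pre-probability plants no seed keyword", {
  cfg <- generator_config(n_patients = 30, start_date = "2020-01-01",
                          changepoint_date = "2020-12-01", end_date = "2020-02-15",
                          mention_prob_pre = 0, seed = 11)
  sim <- simulate_corpus(cfg)
  expect_gt(nrow(sim$messages), 0)
  hits <- vapply(seed_keywords(),
                 function(p) any(grepl(p, sim$messages$text, fixed = TRUE)),
                 logical(1))
  expect_false(any(hits))
  expect_false(any(sim$ground_truth$mention_flag))
})

test_that("identical config and seed reproduce the corpus and assessments exactly", {
  cfg <- generator_config(n_patients = 25, end_date = "2020-03-20", seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$messages, b$messages)
  expect_identical(a$assessments, b$assessments)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("vocabulary strata are pairwise disjoint and mention flags are exact", {
  cfg <- generator_config(n_patients = 40, end_date = "2020-04-15", seed = 3)
  sim <- simulate_corpus(cfg)
  gt <- sim$ground_truth
  expect_length(intersect(gt$covid_assoc_terms, gt$anti_assoc_terms), 0)
  expect_length(intersect(gt$covid_assoc_terms, gt$neutral_terms), 0)
  expect_length(intersect(gt$anti_assoc_terms, gt$neutral_terms), 0)
  # flags exactly identify messages carrying a seed keyword (injection is
  # the only route by which a seed word can appear)
  has_seed <- Reduce(`|`, lapply(seed_keywords(),
                                 function(p) grepl(p, sim$messages$text, fixed = TRUE)))
  expect_identical(unname(gt$mention_flag[sim$messages$message_id]), has_seed)
})

test_that("expected mention probability ramps monotonically over ramp_days", {
  cfg <- generator_config(ramp_days = 30)
  days <- seq(cfg$changepoint_date, cfg$changepoint_date + 30, by = "day")
  p <- mention_probability(days, cfg)
  expect_true(all(diff(p) >= 0))
  expect_equal(p[1], cfg$mention_prob_pre)
  expect_equal(p[length(p)], cfg$mention_prob_post)
  # instantaneous ramp
  cfg0 <- generator_config(ramp_days = 0)
  expect_equal(mention_probability(cfg0$changepoint_date - 1, cfg0),
               cfg0$mention_prob_pre)
  expect_equal(mention_probability(cfg0$changepoint_date, cfg0),
               cfg0$mention_prob_post)
})

test_that("post-changepoint mention fraction matches the binomial oracle", {
  cfg <- generator_config(n_patients = 200,
                          start_date = "2020-02-29",
                          changepoint_date = "2020-03-01",
                          end_date = "2020-06-09",
                          mention_prob_pre = 0, mention_prob_post = 0.3,
                          ramp_days = 0, seed = 5)
  sim <- simulate_corpus(cfg)
  post <- sim$messages$date >= cfg$changepoint_date
  frac <- mean(sim$ground_truth$mention_flag[post])
  se <- sqrt(0.3 * 0.7 / sum(post))
  expect_lt(abs(frac - 0.3), 3 * se)
})

test_that("item responses and totals stay in the instruments' legal ranges", {
  cfg <- generator_config(n_patients = 150, gad7_baseline_mean = 2.7,
                          gad7_shift = 1.5, phq9_baseline_mean = 0.2, seed = 9)
  a <- simulate_assessments(cfg)
  g <- a[a$instrument == "GAD7", paste0("item_", 1:7)]
  p <- a[a$instrument == "PHQ9", paste0("item_", 1:9)]
  expect_true(all(as.matrix(g) %in% 0:3))
  expect_true(all(as.matrix(p) %in% 0:3))
  expect_true(all(rowSums(g) >= 0 & rowSums(g) <= 21))
  expect_true(all(rowSums(p) >= 0 & rowSums(p) <= 27))
  expect_true(all(is.na(a[a$instrument == "GAD7", c("item_8", "item_9")])))
})

test_that("all-zero item means force every total to zero", {
  cfg <- generator_config(n_patients = 50, gad7_baseline_mean = 0,
                          gad7_shift = 0, phq9_baseline_mean = 0,
                          phq9_shift = 0, seed = 2)
  a <- simulate_assessments(cfg)
  g <- rowSums(a[a$instrument == "GAD7", paste0("item_", 1:7)])
  p <- rowSums(a[a$instrument == "PHQ9", paste0("item_", 1:9)])
  expect_true(all(g == 0) && all(p == 0))
})

test_that("a null GAD-7 shift leaves the two arms statistically level", {
  cfg <- generator_config(n_patients = 2000, gad7_shift = 0, seed = 13)
  dates <- rep(c(as.Date("2020-02-01"), as.Date("2020-04-01")), 1000)
  a <- simulate_assessments(cfg, intake_dates = dates)
  g <- a[a$instrument == "GAD7", ]
  tot <- rowSums(g[paste0("item_", 1:7)])
  pre <- tot[g$date < cfg$changepoint_date]
  post <- tot[g$date >= cfg$changepoint_date]
  se <- sqrt(var(pre) / length(pre) + var(post) / length(post))
  expect_lt(abs(mean(post) - mean(pre)), 3 * se)
})

test_that("cohort assessments are dated at each patient's first message", {
  cfg <- generator_config(n_patients = 30, end_date = "2020-03-15", seed = 21)
  sim <- simulate_cohort(cfg)
  firsts <- tapply(sim$messages$date, sim$messages$patient_id, min)
  a <- sim$assessments[sim$assessments$instrument == "GAD7", ]
  covered <- a$patient_id %in% names(firsts)
  expect_true(any(covered))
  expect_equal(as.numeric(a$date[covered]),
               as.numeric(firsts[a$patient_id[covered]]),
               ignore_attr = TRUE)
})
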