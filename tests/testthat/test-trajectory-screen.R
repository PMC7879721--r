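test_that("tokenizer produces the documented unigrams and n-grams", {
  expect_setequal(tokenize_ngrams("I feel anxious", n_max = 1),
                  c("i", "feel", "anxious"))
  expect_length(tokenize_ngrams("", n_max = 3), 0)
  got <- tokenize_ngrams("so so tired", n_max = 2)
  expect_identical(sort(got),
                   sort(c("so", "so", "tired", "so so", "so tired")))
  # punctuation is stripped inside whitespace tokens
  expect_identical(tokenize_ngrams("COVID-19 update!", n_max = 1),
                   c("covid19", "update"))
  expect_error(tokenize_ngrams("x", n_max = 0), "n_max")
})

test_that("daily matrix pools per calendar day and applies the df filter", {
  m1 <- build_daily_matrix(make_messages("a b a", "2020-03-01"),
                           c("2020-03-01", "2020-03-01"), n_max = 1, min_df = 1)
  expect_equal(as.numeric(m1$counts[1, c("a", "b")]), c(2, 1))
  # min_df larger than the day count empties the term axis
  m2 <- build_daily_matrix(make_messages("a b a", "2020-03-01"),
                           c("2020-03-01", "2020-03-01"), n_max = 1, min_df = 5)
  expect_length(m2$terms, 0)
  # disjoint texts on two days never reach df 2
  m3 <- build_daily_matrix(
    make_messages(c("apple pear", "plum fig"), c("2020-03-01", "2020-03-02")),
    c("2020-03-01", "2020-03-02"), n_max = 1, min_df = 2)
  expect_length(m3$terms, 0)
  # n-grams never cross message boundaries
  m4 <- build_daily_matrix(
    make_messages(c("a b", "c d"), c("2020-03-01", "2020-03-01")),
    c("2020-03-01", "2020-03-01"), n_max = 2, min_df = 1)
  expect_true("a b" %in% m4$terms)
  expect_false("b c" %in% m4$terms)
})

test_that("tf-idf uses the smoothed log idf and preserves sparsity", {
  msgs <- make_messages(
    c("alpha beta", "alpha", "alpha", "alpha gamma"),
    c("2020-03-01", "2020-03-02", "2020-03-03", "2020-03-04")
  )
  dtm <- build_daily_matrix(msgs, c("2020-03-01", "2020-03-04"),
                            n_max = 1, min_df = 1)
  tf <- tfidf_transform(dtm)
  # term on every day: idf factor 1 + ln(1) = 1, weights equal raw counts
  expect_equal(as.numeric(tf$weights[, "alpha"]),
               as.numeric(dtm$counts[, "alpha"]))
  # df = 1, N = 4: weight = count * (1 + ln(5/2))
  expect_equal(as.numeric(tf$weights["2020-03-01", "beta"]), 1 * (1 + log(5 / 2)))
  # closed form at count 2
  msgs2 <- make_messages(c("beta beta", "x", "x", "x"),
                         c("2020-03-01", "2020-03-02", "2020-03-03", "2020-03-04"))
  tf2 <- tfidf_transform(build_daily_matrix(msgs2, c("2020-03-01", "2020-03-04"),
                                            n_max = 1, min_df = 1))
  expect_equal(as.numeric(tf2$weights["2020-03-01", "beta"]), 2 * (1 + log(5 / 2)))
  # zero count stays exactly zero
  expect_identical(as.numeric(tf$weights["2020-03-02", "beta"]), 0)
  expect_identical(Matrix::nnzero(tf$weights), Matrix::nnzero(dtm$counts))
})

test_that("scaling one day's counts scales that day's tf-idf weights", {
  msgs <- make_messages(c("a a b", "a b b", "a b"),
                        c("2020-03-01", "2020-03-02", "2020-03-03"))
  dtm <- build_daily_matrix(msgs, c("2020-03-01", "2020-03-03"),
                            n_max = 1, min_df = 1)
  tf <- tfidf_transform(dtm)
  scaled <- dtm
  scaled$counts[2, ] <- dtm$counts[2, ] * 5  # same sparsity and df
  tf_s <- tfidf_transform(scaled)
  expect_equal(as.numeric(tf_s$weights[2, ]), 5 * as.numeric(tf$weights[2, ]))
  expect_equal(as.numeric(tf_s$weights[1, ]), as.numeric(tf$weights[1, ]))
})

test_that("correlations hit the exact endpoints and the direct formula", {
  days <- as.character(as.Date("2020-03-01") + 0:3)
  y <- stats::setNames(c(0.1, 0.2, 0.3, 0.5), days)
  X <- cbind(same = c(0.1, 0.2, 0.3, 0.5),
             anti = 1 - c(0.1, 0.2, 0.3, 0.5),
             traj = c(1, 2, 3, 4))
  rownames(X) <- days
  got <- correlate_terms(X, y)
  expect_equal(got$r[got$term == "same"], 1)
  expect_equal(got$p[got$term == "same"], 0)
  expect_equal(got$r[got$term == "anti"], -1)
  ct <- stats::cor.test(c(1, 2, 3, 4), as.numeric(y))
  expect_equal(got$r[got$term == "traj"], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p[got$term == "traj"], ct$p.value, tolerance = 1e-12)
  expect_true(all(got$n == 4))
})

test_that("correlation is invariant to affine rescaling of the signal", {
  set.seed(12)
  days <- as.character(as.Date("2020-03-01") + 0:19)
  X <- matrix(rpois(20 * 5, 4), 20, 5,
              dimnames = list(days, paste0("t", 1:5)))
  y <- stats::setNames(runif(20), days)
  a <- correlate_terms(X, y)
  b <- correlate_terms(X, 3.7 * y + 11)
  expect_equal(a$r, b$r, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("zero-variance terms are skipped with a warning, short overlap errors", {
  days <- as.character(as.Date("2020-03-01") + 0:4)
  X <- cbind(flat = rep(2, 5), live = c(1, 3, 2, 5, 4))
  rownames(X) <- days
  y <- stats::setNames(c(0.1, 0.3, 0.2, 0.5, 0.4), days)
  expect_warning(got <- correlate_terms(X, y), "zero-variance")
  expect_identical(got$term, "live")
  expect_error(correlate_terms(X[1:2, , drop = FALSE], y[1:2]),
               "insufficient data")
  expect_warning(flat_sig <- correlate_terms(X, stats::setNames(rep(0.2, 5), days)),
                 "zero variance")
  expect_identical(nrow(flat_sig), 0L)
})

test_that("BH selection follows the step-up rule and partitions by sign", {
  mk <- function(p, r = rep(0.5, length(p)))
    data.frame(term = paste0("t", seq_along(p)), r = r, p = p, n = 30)
  # all p = 1 -> nothing
  s <- bh_select(mk(rep(1, 5)), q = 0.01)
  expect_length(c(s$positive_terms, s$negative_terms), 0)
  # single p < q reduces to the raw threshold
  s1 <- bh_select(mk(0.004), q = 0.01)
  expect_identical(s1$positive_terms, "t1")
  # worked step-up example against the exhaustive oracle
  p <- c(0.001, 0.002, 0.009, 0.04, 0.2)
  s5 <- bh_select(mk(p, r = c(0.5, -0.4, 0.3, 0.2, -0.1)), q = 0.01)
  oracle <- bh_oracle_select(p, 0.01)
  expect_setequal(which(s5$table$selected), oracle)
  expect_setequal(s5$positive_terms, "t1")
  expect_setequal(s5$negative_terms, "t2")
  expect_error(bh_select(mk(0.5), q = 0), "q must")
})
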