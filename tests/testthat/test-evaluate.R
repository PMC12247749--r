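test_that("event and prediction rates are exact arithmetic on counts", {
  er <- event_rate(c(rep(1, 46), rep(0, 1002)))
  expect_equal(er$count, 46L)
  expect_equal(er$total, 1048L)
  expect_equal(er$percent, 4.39)

  expect_equal(event_rate(rep(0, 100))$percent, 0)
  er1 <- event_rate(c(1, rep(0, 1047)))
  expect_equal(er1$percent, 0.1)             # 0.095% prints as < 0.1%
  expect_lt(er1$count / er1$total, 0.001)
  expect_error(event_rate(integer(0)), "no pulses")

  rec <- fake_record(10, event_pulses = c(3, 7))
  expect_equal(event_rate(rec)$count, 2L)
  expect_equal(event_rate(list(rec, rec))$total, 20L)
})

test_that("percent reduction reproduces the printed 93%", {
  red <- percent_reduction(14 / 1048, 1 / 1048)
  expect_equal(as.numeric(red), 100 * 13 / 14, tolerance = 1e-12)
  expect_equal(attr(red, "rounded"), 93)
  expect_equal(as.numeric(percent_reduction(0.1, 0.1)), 0)
  expect_equal(as.numeric(percent_reduction(0.1, 0)), 100)
  expect_error(percent_reduction(0, 0.1), "positive")
})

test_that("tanh fits recover noiseless parameters to high precision", {
  x <- seq(0.1, 0.35, length.out = 40)
  y <- 1 + 2 * tanh((x - 0.22) / 0.03)
  fit <- fit_tanh(x, y)
  expect_false(fit$degenerate)
  expect_equal(fit$c, 0.22, tolerance = 1e-6)
  expect_equal(fit$b, 2, tolerance = 1e-4)
  expect_gt(fit$d, 0)

  # constant y is flagged degenerate
  fit0 <- fit_tanh(x, rep(3, 40))
  expect_true(fit0$degenerate)
  expect_equal(fit0$b, 0)

  # symmetric data: c equals the symmetry point
  xs <- seq(-1, 1, length.out = 21)
  fits <- fit_tanh(xs, tanh(xs / 0.4))
  expect_equal(fits$c, 0, tolerance = 1e-6)

  expect_error(fit_tanh(1:3, 1:3), ">= 5")
  expect_error(fit_tanh(rep(1, 6), rnorm(6)), "spread")
})

test_that("treatment windows follow the printed bounds", {
  w <- treatment_window(0.17, 0.26)
  expect_equal(w$width, 0.09)
  w2 <- treatment_window(0.17, 0.19)
  expect_equal(w2$width, 0.02)
  expect_error(treatment_window(0.2, 0.2), "empty")

  fit <- fit_tanh(seq(0.1, 0.35, length.out = 30),
                  1 + 2 * tanh((seq(0.1, 0.35, length.out = 30) - 0.26) / 0.03))
  w3 <- treatment_window(0.17, fit)
  expect_equal(w3$width, 0.09, tolerance = 1e-4)
})

test_that("distribution stats use sample SD and adjusted skewness", {
  s <- distribution_stats(c(-1, 0, 1))
  expect_equal(s$skewness, 0)
  expect_equal(s$sd, 1)

  x <- c(0, 0, 0, 10)
  s2 <- distribution_stats(x)
  n <- 4
  g1 <- mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5
  expect_equal(s2$skewness, g1 * sqrt(n * (n - 1)) / (n - 2))
  expect_gt(s2$skewness, 0)

  expect_error(distribution_stats(c(1, 2)), "n >= 3")
  expect_error(distribution_stats(rep(2, 5)), "constant")
})

test_that("variance tests match their closed forms and an ANOVA oracle", {
  set.seed(9)
  a <- rnorm(200)
  vt <- variance_tests(a, a)
  expect_equal(vt$f_statistic, 1)
  expect_gt(vt$f_p, 0.99)

  # the SD pair reported for the rat open-loop comparison
  b1 <- rnorm(500, sd = 10.9)
  b2 <- rnorm(500, sd = 4.0)
  vt2 <- variance_tests(b1, b2)
  expect_equal(vt2$f_statistic, var(b1) / var(b2))
  expect_gt(vt2$f_statistic, 4)
  expect_lt(vt2$f_p, 1e-10)
  expect_lt(vt2$levene_p, 1e-10)
  expect_equal((10.9 / 4.0)^2, 7.43, tolerance = 1e-2)

  # Brown-Forsythe equals one-way ANOVA on |x - group median|
  z <- c(abs(b1 - median(b1)), abs(b2 - median(b2)))
  g <- factor(rep(1:2, each = 500))
  aov_f <- summary(stats::aov(z ~ g))[[1]]$`F value`[1]
  expect_equal(vt2$levene_statistic, aov_f, tolerance = 1e-10)

  expect_error(variance_tests(1, 1:3), "n >= 2")
  expect_error(variance_tests(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("experiment summaries aggregate deterministically", {
  rec <- small_corpus(10, seed = 77)[[1]]
  sm <- summarize_experiment(list(a = list(rec), b = list(rec)))
  expect_equal(sm$arms$event_percent[1], sm$arms$event_percent[2])
  expect_equal(sm$arms$h7_mean[1], sm$arms$h7_mean[2])

  z <- rec
  z$pulses$is_event <- 0L
  z$pulses$prediction <- 0L
  sm0 <- summarize_experiment(list(quiet = list(z)))
  expect_equal(sm0$arms$events, 0L)
  expect_equal(sm0$arms$prediction_percent, 0)
  expect_error(summarize_experiment(list()), "arm")
})

test_that("tanh inflection recovery stays within d/5 under 10% noise", {
  set.seed(31)
  errs <- replicate(100, {
    cc <- runif(1, 0.15, 0.3)
    dd <- runif(1, 0.02, 0.06)
    bb <- runif(1, 1, 3)
    x <- seq(0.05, 0.4, length.out = 60)
    y <- runif(1, -1, 1) + bb * tanh((x - cc) / dd) + rnorm(60, 0, 0.1 * bb)
    fit <- fit_tanh(x, y, n_starts = 8, seed = 1)
    abs(fit$c - cc) / dd
  })
  expect_lt(median(errs), 1 / 5)
})
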