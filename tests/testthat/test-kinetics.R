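test_that("binding detection is an inclusive first-crossing scan", {
  s <- observable_series(0:4, c(0, 12, 49, 50, 63), "contacts")
  d <- detect_binding(s, threshold = 50)
  expect_false(d$censored)
  expect_equal(d$fpt, 3)
  s49 <- observable_series(0:9, rep(49, 10), "contacts")
  expect_true(detect_binding(s49)$censored)
  # randomized series against a plain linear scan
  set.seed(42)
  for (i in 1:25) {
    v <- rpois(50, 30)
    s <- observable_series(seq(0, 4.9, 0.1), v)
    d <- detect_binding(s, threshold = 35)
    hit <- NA_real_
    for (j in seq_along(v)) if (v[j] >= 35) { hit <- s$time[j]; break }
    if (is.na(hit)) expect_true(d$censored) else expect_equal(d$fpt, hit)
  }
  expect_error(detect_binding(observable_series(numeric(0), numeric(0))),
               "empty")
})

test_that("time-scale conversion is plain multiplication", {
  expect_equal(apply_timescale(500), 2000)
  expect_equal(apply_timescale(123.4, factor = 1), 123.4)
  expect_error(apply_timescale(10, factor = -1), "factor")
  # composition with the rate formula reproduces table arithmetic from
  # CG-clock inputs equal to printed values divided by four
  ka <- ka_from_mean_fpt(apply_timescale(2326.98 / 4), 3.375e-21)
  expect_equal(round(ka / 1e8, 2), 8.73)
})

test_that("bootstrap mean matches closed-form dispersion and is seeded", {
  const <- fpt_sample(rep(100, 200), t_max = 2000)
  bs <- bootstrap_mean_fpt(const, seed = 1)
  expect_equal(bs$mean, 100)
  expect_equal(bs$sd, 0)
  # two-point sample: SE of the mean is sd/sqrt(n)
  x <- rep(c(1, 3), 100)
  samp <- fpt_sample(x, censored = rep(FALSE, 200), t_max = 10)
  bs2 <- bootstrap_mean_fpt(samp, n_boot = 1e4, seed = 2)
  se_analytic <- sd(x) / sqrt(200)
  expect_equal(bs2$sd, se_analytic, tolerance = 0.05)
  a <- bootstrap_mean_fpt(samp, seed = 9)
  b <- bootstrap_mean_fpt(samp, seed = 9)
  expect_identical(a$boot_means, b$boot_means)
  allcens <- fpt_sample(rep(NA_real_, 5), t_max = 10)
  expect_error(bootstrap_mean_fpt(allcens), "censored")
})

test_that("the rate formula reproduces printed table values exactly", {
  expect_equal(round(ka_from_mean_fpt(2326.98, 3.375e-21) / 1e8, 2), 8.73)
  expect_equal(round(ka_from_mean_fpt(1247.78, 3.375e-21) / 1e8, 2), 16.29)
  # ka strictly decreasing in the mean FPT, limit to zero
  t_grid <- c(100, 500, 1000, 5000, 1e7)
  ka <- ka_from_mean_fpt(t_grid)
  expect_true(all(diff(ka) < 0))
  expect_lt(ka_from_mean_fpt(1e12), 1e3)
  expect_error(ka_from_mean_fpt(-5), "> 0")
})

test_that("exponential fit is the MLE and flags degenerate data", {
  set.seed(13)
  x <- rexp(1e4, rate = 1e-3)
  f <- fit_exponential(x)
  expect_equal(f$rate, 1e-3, tolerance = 0.03)
  expect_equal(f$rate, 1 / mean(x), tolerance = 1e-12)
  expect_warning(fit_exponential(rep(5, 20)), "degenerate")
  expect_error(fit_exponential(1:5), "at least 10")
})

test_that("Welch's test matches the textbook formula and its limits", {
  a <- fpt_sample(c(10, 12, 14, 16, 18), t_max = 100)
  b <- fpt_sample(c(30, 33, 36, 39, 42), t_max = 100)
  res <- compare_conditions(a, b)
  # hand computation
  ma <- mean(a$times); mb <- mean(b$times)
  va <- var(a$times) / 5; vb <- var(b$times) / 5
  t_hand <- (ma - mb) / sqrt(va + vb)
  df_hand <- (va + vb)^2 / (va^2 / 4 + vb^2 / 4)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(res$statistic, t_hand, tolerance = 1e-9)
  expect_equal(res$df, df_hand, tolerance = 1e-9)
  expect_equal(res$p_value, p_hand, tolerance = 1e-9)
  # identical samples: t = 0, p = 1
  same <- compare_conditions(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # far-separated large samples: decisive
  set.seed(3)
  big_a <- fpt_sample(rexp(200, 1 / 1000), t_max = 1e6)
  big_b <- fpt_sample(rexp(200, 1 / 2000), t_max = 1e6)
  expect_lt(compare_conditions(big_a, big_b)$p_value, 1e-3)
})

test_that("fpt_sample enforces its invariants", {
  expect_error(fpt_sample(c(1, 2, 3000), t_max = 2000), "t_max")
  expect_error(fpt_sample(c(1, -2), t_max = 2000), "t_max|0")
  s <- fpt_sample(c(5, NA, 10), t_max = 100)
  expect_equal(s$n_trials, 3)
  expect_equal(sum(s$censored), 1)
})

test_that("rate estimate propagates censoring transparently", {
  set.seed(10)
  x <- rexp(200, 1 / 800)
  cens <- x > 2000
  x[cens] <- NA
  samp <- fpt_sample(x, t_max = 2000)
  est <- rate_estimate(samp, timescale_factor = 1, seed = 4)
  expect_equal(est$n_censored, sum(cens))
  # treating censored as t_max can only lengthen the mean, lowering ka
  expect_lte(est$ka_censored_sensitivity, est$ka)
})
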