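test_that("hyper-exponential evaluation matches direct computation", {
  bla <- hyperexp_model(0.104, 0.019)
  expect_equal(p_loc(bla, 0), 1)
  expect_equal(p_loc(bla, 17), exp(-0.104 * 17 - 0.019 * 289),
               tolerance = 1e-12)
  expect_equal(signif(p_loc(bla, 17), 3), 7.04e-4)
  gfp <- hyperexp_model(-0.062, 0.058)
  expect_equal(signif(p_loc(gfp, 12), 3), 4.96e-4)
  expect_equal(predict(gfp, 0:3), p_loc(gfp, 0:3))
  expect_error(p_loc(bla, -1), "non-negative")
  expect_error(hyperexp_model(0.1, -0.01), "decay")
  expect_error(hyperexp_model(-0.1, 0), "decay")
})

test_that("p_loc decreases beyond the stationary point when beta > 0", {
  for (a in c(-0.2, 0, 0.1)) {
    m <- hyperexp_model(a, 0.03)
    n0 <- max(0, -a / (2 * 0.03))
    grid <- n0 + seq(0, 40, by = 0.5)
    expect_true(all(diff(p_loc(m, grid)) < 0))
  }
})

test_that("continuous-root n_max reproduces the published wildtype regions", {
  expect_equal(n_max_from_model(hyperexp_model(-0.062, 0.058), 0.00056), 12,
               ignore_attr = TRUE)
  expect_equal(n_max_from_model(hyperexp_model(0.165, 0.065), 0.00054), 10,
               ignore_attr = TRUE)
  expect_equal(n_max_from_model(hyperexp_model(0.104, 0.019), 0.00051), 17,
               ignore_attr = TRUE)
  # closed form: beta n^2 = -ln P_th
  r <- n_max_from_model(hyperexp_model(0, 1), exp(-4))
  expect_equal(as.integer(r), 2L)
  expect_equal(attr(r, "root"), 2, tolerance = 1e-12)
  # rounding consistency: integer within 0.5 of the continuous root
  set.seed(11)
  for (i in 1:25) {
    m <- hyperexp_model(runif(1, -0.1, 0.3), runif(1, 0.01, 0.1))
    nm <- n_max_from_model(m, runif(1, 1e-5, 0.1))
    expect_lte(abs(attr(nm, "root") - as.integer(nm)), 0.5)
  }
  expect_error(n_max_from_model(hyperexp_model(0.1, 0.01), 1.5), "0, 1")
})

test_that("stepwise tolerance product matches brute-force cumulation", {
  bla <- c(1.00, 0.61, 0.61, 0.55, 0.55, 0.39)
  expect_identical(n_max_from_schedule(bla, 0.00051), 10L)
  expect_identical(n_max_from_schedule(c(0.5), 0.25), 1L)
  # cumulative products 1.0, 0.61, 0.372: last product above 0.5 is the 2nd
  expect_identical(n_max_from_schedule(bla, 0.5), 2L)
  # oracle equivalence on random schedules
  set.seed(21)
  for (i in 1:40) {
    sched <- runif(sample(1:50, 1), 0.2, 0.95)
    p_th <- runif(1, 1e-12, 0.5)
    steps <- c(sched, rep(sched[length(sched)], 400))
    oracle <- sum(cumprod(steps) > p_th)
    expect_identical(n_max_from_schedule(sched, p_th), as.integer(oracle))
  }
  expect_error(n_max_from_schedule(c(0.5, 1.0), 0.1), "never decays")
  expect_error(tolerance_schedule(numeric(0)), "non-empty")
  expect_error(tolerance_schedule(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("nonsynonymous rescaling inverts and reproduces published coefficients", {
  m <- rescale_nonsynonymous(0.07176, 0.009048, 0.69)
  expect_equal(coef(m), c(alpha = 0.104, beta = 0.019), tolerance = 1e-3)
  id <- rescale_nonsynonymous(0.2, 0.05, 1)
  expect_equal(coef(id), c(alpha = 0.2, beta = 0.05))
  # round trip
  fwd <- rescale_nonsynonymous(0.2, 0.05, 0.69)
  back <- rescale_nonsynonymous(fwd$alpha, fwd$beta, 1 / 0.69)
  expect_equal(coef(back), c(alpha = 0.2, beta = 0.05), tolerance = 1e-12)
  expect_error(rescale_nonsynonymous(0.1, 0.01, 0), "fraction")
})

test_that("hyper-exponential fitting recovers generating parameters", {
  # noiseless data: exact recovery
  m <- hyperexp_model(0.104, 0.019)
  f <- fit_hyperexponential(1:10, p_loc(m, 1:10))
  expect_equal(coef(f), c(alpha = 0.104, beta = 0.019), tolerance = 1e-6)
  expect_lt(f$rss, 1e-20)
  expect_equal(residuals(f), f$data$p - fitted(f))
  # 50 random parameter draws, still noiseless
  set.seed(9)
  for (i in 1:50) {
    a <- runif(1, -0.1, 0.3); b <- runif(1, 0.001, 0.1)
    fi <- fit_hyperexponential(1:10, exp(-a * (1:10) - b * (1:10)^2))
    expect_equal(unname(coef(fi)), c(a, b), tolerance = 1e-6)
  }
})

test_that("fit is unbiased under multiplicative noise and honours exclusions", {
  set.seed(3)
  m <- hyperexp_model(-0.062, 0.058)
  cfs <- t(replicate(100, {
    p <- p_loc(m, 2:10) * exp(rnorm(9, 0, 0.05))
    coef(fit_hyperexponential(2:10, p))
  }))
  expect_lt(abs(mean(cfs[, "alpha"]) - (-0.062)), 0.01)
  expect_lt(abs(mean(cfs[, "beta"]) - 0.058), 0.005)
  # an outlying n = 1 point is dropped before fitting
  n <- 1:10
  p <- p_loc(m, n); p[1] <- p[1] * 50
  f <- fit_hyperexponential(n, p, exclude_n = 1)
  expect_equal(coef(f), coef(m), tolerance = 1e-6)
  expect_false(1 %in% f$data$n)
  expect_error(fit_hyperexponential(1:2, c(0.5, 0.2)), "at least 3")
  expect_error(fit_hyperexponential(1:4, c(0.9, 0.5, 0.2, 0)), "positive")
})

test_that("log-space fitting option works on decade-spanning data", {
  m <- hyperexp_model(0.104, 0.019)
  f <- fit_hyperexponential(1:15, p_loc(m, 1:15), log_space = TRUE)
  expect_equal(coef(f), coef(m), tolerance = 1e-8)
})
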