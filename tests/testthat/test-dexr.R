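# DEXR fitting: reference decay, ratio construction, rate fit.

test_that("biexponential reference fit recovers well-separated synthetic parameters", {
  tm <- c(0.2, 1, 2, 4, 7, 10, 20, 40, 80, 160, 300, 600, 1200)
  t_s <- tm / 1000
  y <- 0.6 * exp(-2 * t_s) + 0.4 * exp(-0.5 * t_s)
  fit <- fit_reference_decay(tm, y)
  # up to label swap
  rates <- sort(c(fit$R11, fit$R12))
  w_fast <- if (fit$R11 >= fit$R12) fit$w1 else 1 - fit$w1
  expect_equal(rates, c(0.5, 2), tolerance = 1e-5)
  expect_equal(fit$I0, 1, tolerance = 1e-5)
  expect_equal(w_fast, 0.6, tolerance = 1e-5)
})

test_that("monoexponential data is fit exactly even though parameters degenerate", {
  tm <- c(0.2, 1, 2, 4, 7, 10, 20, 40, 80, 160, 300)
  y <- exp(-tm / 1000 * 1)
  fit <- fit_reference_decay(tm, y)
  expect_lt(sqrt(mean((fit$fitted - y)^2)), 1e-8)
  expect_lt(max(abs(predict(fit, c(0.5, 50, 250)) -
                      exp(-c(0.5, 50, 250) / 1000))), 1e-6)
})

test_that("DEXR signal construction isolates exchange", {
  tm <- c(0.2, 1, 2, 4, 7, 10, 20, 40, 80, 160, 300)
  ref <- 0.5 * exp(-tm / 1000)
  fit <- fit_reference_decay(tm, ref)
  # identical signals -> ratio of one
  expect_equal(compute_dexr_signal(tm, predict(fit, tm), fit),
               rep(1, length(tm)), tolerance = 1e-12)
  # no exchange, equal R1: the DEXR signal is constant in tm
  sys <- compartment_system(c(0.4, 0.3, 0.3), ADC = c(1, 1, 0.1), R1 = 1)
  tab <- simulate_dexsy(sys, exchange_general(matrix(0, 3, 3)),
                        ref_protocol())
  res <- estimate_axr(tab)
  expect_lt(diff(range(res$dexr_signal)), 1e-6)
})

test_that("rate fit recovers exact three-parameter synthetic data", {
  tm <- c(0.2, 1, 2, 4, 7, 10, 20, 40, 80, 160, 300)
  y <- 0.8 * exp(-tm / 1000 * 100) + 0.2
  fit <- fit_axr(tm, y)
  expect_equal(fit$AXR, 100, tolerance = 1e-8)
  expect_equal(fit$I0, 0.8, tolerance = 1e-8)
  expect_equal(fit$B, 0.2, tolerance = 1e-8)
  # property over random draws
  set.seed(404)
  for (rep in 1:20) {
    I0 <- runif(1, 0.2, 1); AXR <- runif(1, 20, 400); B <- runif(1, 0, 0.8)
    fit <- fit_axr(tm, I0 * exp(-tm / 1000 * AXR) + B)
    expect_lt(abs(fit$AXR - AXR) / AXR, 1e-6)
    expect_lt(abs(fit$I0 - I0) / I0, 1e-6)
    expect_lt(abs(fit$B - B) / max(B, 1e-3), 1e-4)
  }
  # constant data degenerates to a flagged zero rate
  cst <- fit_axr(tm, rep(0.5, length(tm)))
  expect_true(cst$degenerate)
  expect_equal(cst$AXR, 0)
})

test_that("rate fit has small median bias under noise", {
  tm <- c(0.2, 1, 2, 4, 7, 10, 20, 40, 80, 160, 300)
  truth <- 140
  set.seed(505)
  est <- replicate(200, {
    y <- 0.45 * exp(-tm / 1000 * truth) + 0.55 + rnorm(length(tm), sd = 0.005)
    fit_axr(tm, y)$AXR
  })
  expect_lt(abs(stats::median(est) - truth) / truth, 0.02)
})

test_that("two-site end-to-end estimate stays within 10% of the ground-truth rate", {
  for (fa in seq(0.1, 0.9, by = 0.2)) {
    tab <- simulate_dexsy(system_two_site(fa), exchange_two_site(300),
                          ref_protocol())
    axr <- estimate_axr(tab)$AXR
    expect_lt(abs(axr - 300) / 300, 0.10)
  }
})

test_that("three-site estimate is bounded by the exchange rates and monotone in the ECS fraction", {
  fa_grid <- seq(0.05, 0.95, by = 0.1)
  axr <- vapply(fa_grid, function(fa) {
    tab <- simulate_dexsy(system_three_site(fa), ref_spec_3xm(),
                          ref_protocol())
    estimate_axr(tab)$AXR
  }, numeric(1))
  expect_true(all(axr >= 30 - 1e-6 & axr <= 300 + 1e-6))
  expect_true(all(diff(axr) > 0))
  # extremes approach the pure rates
  tab_hi <- simulate_dexsy(compartment_system(c(0.999, 5e-4, 5e-4),
                                              c(1, 1, 0.1), R1 = 1),
                           ref_spec_3xm(), ref_protocol())
  expect_equal(estimate_axr(tab_hi)$AXR, 300, tolerance = 0.02)
  tab_lo <- simulate_dexsy(compartment_system(c(1e-4, 0.49995, 0.49995),
                                              c(1, 1, 0.1), R1 = 1),
                           ref_spec_3xm(), ref_protocol())
  expect_equal(estimate_axr(tab_lo)$AXR, 30, tolerance = 0.02 * 30)
})

test_that("pipeline validates its inputs", {
  sys <- system_three_site(0.3)
  tab <- simulate_dexsy(sys, ref_spec_3xm(), ref_protocol())
  expect_error(estimate_axr(tab[tab$encoding == 1, ]), "two encodings")
  expect_error(fit_reference_decay(c(1, 2, 3), c(1, 0.9, 0.8)), "at least 5")
  expect_error(fit_axr(c(1, 2), c(1, 0.9)), "at least 3")
  expect_error(fit_reference_decay(c(0.2, 1, 2, 4, 7), c(1, 0.9, -0.1, 0.8, 0.7)),
               "positive")
})

test_that("signal tables round-trip through delimited text", {
  sys <- system_three_site(0.3)
  tab <- simulate_dexsy(sys, ref_spec_3xm(), ref_protocol())
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_table(tab, path)
  back <- read_signal_table(path)
  expect_equal(back$signal, tab$signal, tolerance = 1e-12)
  expect_equal(estimate_axr(back)$AXR, estimate_axr(tab)$AXR,
               tolerance = 1e-6)
})
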