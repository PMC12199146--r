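# CLEANEX build-up model and fits, CPMG R2eff, mono-exponential decays,
# hetNOE ratios.

test_that("cleanex_model limits and an independently evaluated point", {
  tau <- c(0, 0.005, 0.05, 0.2, 1)
  expect_equal(cleanex_model(tau, kex = 0, R1A = 2, R1W = 0.5), rep(0, 5))
  expect_equal(cleanex_model(0, 5, 2, 0.5), 0)
  # printed expression at (kex=5, R1A=2, R1W=0.5, tau=0.1), evaluated
  # independently term by term
  pref <- 5 / (2 + 5 + 0.5)
  val <- pref * (exp(-0.5 * 0.1) - exp(-(2 + 5) * 0.1))
  expect_equal(cleanex_model(0.1, 5, 2, 0.5), val)
  # conventional variant flips the sign of R1W in the prefactor only
  pref2 <- 5 / (2 + 5 - 0.5)
  val2 <- pref2 * (exp(-0.5 * 0.1) - exp(-(2 + 5) * 0.1))
  expect_equal(cleanex_model(0.1, 5, 2, 0.5, variant = "conventional"), val2)
})

test_that("cleanex_model has a single interior maximum, increasing in kex", {
  tau <- seq(0, 40, by = 0.002)
  y <- cleanex_model(tau, 3, 2, 0.4)
  expect_equal(y[1], 0)
  expect_lt(abs(y[length(y)]), 1e-3 * max(y))
  s <- sign(diff(y))
  expect_equal(sum(diff(s[s != 0]) != 0), 1)  # one sign change: single max
  # monotone increasing in kex at fixed small tau
  ks <- seq(0.5, 20, by = 0.5)
  v <- vapply(ks, function(k) cleanex_model(0.01, k, 2, 0.4), numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("fit_cleanex round-trips noise-free curves", {
  cv <- simulate_cleanex(3, 2, 0.4, noise_sd = 0)
  ft <- fit_cleanex(cv, R1W = 0.4)
  expect_equal(ft$kex, 3, tolerance = 1e-6)
  expect_equal(ft$R1A, 2, tolerance = 1e-5)
  # flat curve pins kex at 0 with a flag
  flat <- cleanex_curve(c(5, 10, 30, 40, 60, 80, 100) / 1000, rep(0, 7))
  ff <- fit_cleanex(flat, R1W = 0.4)
  expect_true(ff$flat)
  expect_equal(ff$kex, 0)
  expect_error(fit_cleanex(cleanex_curve(c(0.01, 0.02, 0.03), rep(0.1, 3)),
                           0.4), "4 points")
})

test_that("fit_cleanex recovers kex within 10% at 2% noise (200 seeds)", {
  tau <- c(5, 10, 30, 40, 60, 80, 100) / 1000
  amp <- max(cleanex_model(tau, 3, 2, 0.4))
  errs <- vapply(1:200, function(s) {
    cv <- simulate_cleanex(3, 2, 0.4, noise_sd = 0.02 * amp, seed = s)
    abs(fit_cleanex(cv, 0.4)$kex - 3) / 3
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("fit bias is below 2% of kex at 1% noise", {
  tau <- c(5, 10, 30, 40, 60, 80, 100) / 1000
  amp <- max(cleanex_model(tau, 3, 2, 0.4))
  k <- vapply(1:150, function(s) {
    cv <- simulate_cleanex(3, 2, 0.4, noise_sd = 0.01 * amp, seed = 1000 + s)
    fit_cleanex(cv, 0.4)$kex
  }, numeric(1))
  expect_lt(abs(mean(k) - 3) / 3, 0.02)
})

test_that("r2eff_cpmg closed-form identity and edge cases", {
  expect_equal(r2eff_cpmg(1, 1, 0.05), 0)
  expect_equal(r2eff_cpmg(exp(-1), 1, 0.05), 20)
  # identity for arbitrary R, T
  for (R in c(0.5, 7, 33)) for (Tc in c(0.02, 0.05, 0.2)) {
    expect_equal(r2eff_cpmg(exp(-R * Tc) * 3, 3, Tc), R)
  }
  expect_warning(out <- r2eff_cpmg(-0.1, 1, 0.05), "non-positive")
  expect_true(is.na(out))
  expect_warning(neg <- r2eff_cpmg(1.2, 1, 0.05), "negative")
  expect_lt(neg, 0)
})

test_that("fit_monoexp: round trip, constant signal, noisy recovery", {
  d <- c(0, 2.5, 5, 5, 7.5, 10, 15, 20, 30, 40, 50) / 1000
  f <- fit_monoexp(d, 7 * exp(-10 * d))
  expect_equal(f$rate, 10, tolerance = 1e-8)
  expect_equal(f$I0, 7, tolerance = 1e-8)
  fc <- fit_monoexp(d, rep(4, length(d)))
  expect_equal(fc$rate, 0, tolerance = 1e-8)
  # 3% noise on the transverse-relaxation delay schedule (22.4-179.2 ms):
  # rate within 5% (median over 200 seeds)
  d2 <- c(22.4, 44.8, 67.2, 89.6, 112.0, 134.4, 156.8, 179.2) / 1000
  errs <- vapply(1:200, function(s) {
    set.seed(s)
    y <- 7 * exp(-10 * d2) + rnorm(length(d2), 0, 0.03 * 7)
    abs(fit_monoexp(d2, y)$rate - 10) / 10
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("hetnoe_ratio is the saturated/reference intensity ratio", {
  expect_equal(hetnoe_ratio(1, 1), 1)
  expect_equal(hetnoe_ratio(0, 1), 0)
  expect_equal(hetnoe_ratio(0.8, 1.0), 0.8)
  expect_error(hetnoe_ratio(1, 0), "zero reference")
})
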