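# Maximum-entropy reweighting: analytic cases, convexity, limits,
# planted-truth recovery.

test_that("targets at the prior averages leave weights unchanged", {
  set.seed(21)
  X <- matrix(rnorm(80), 40, 2)
  om <- observable_matrix(X, targets = colMeans(X), sigma = c(1, 1))
  for (model in c("exact", "gaussian")) {
    wv <- reweight(om, error_model = model)
    expect_equal(wv$w, rep(1 / 40, 40), tolerance = 1e-8)
    expect_equal(unname(wv$lambda), c(0, 0), tolerance = 1e-6)
  }
})

test_that("two-conformer analytic weights: J = 1/11 Hz, target 8.5", {
  om <- observable_matrix(matrix(c(1, 11), 2, 1, dimnames = list(NULL, "J9")),
                          targets = 8.5, sigma = 0.5)
  wv <- reweight(om, error_model = "exact")
  expect_equal(wv$w, c(0.25, 0.75), tolerance = 1e-6)
  expect_equal(unname(wv$achieved), 8.5, tolerance = 1e-6)
})

test_that("weighted_average matches a brute-force loop", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(3:30, 1)
    w <- runif(n); x <- rnorm(n)
    brute <- 0
    wn <- w / sum(w)
    for (i in seq_len(n)) brute <- brute + wn[i] * x[i]
    expect_equal(weighted_average(w, x), brute)
  }
  expect_equal(weighted_average(rep(1, 4), c(1, 2, 3, 4)), 2.5)
  expect_equal(weighted_average(c(0, 0, 1), c(5, 6, 7)), 7)
})

test_that("effective sample size identities", {
  expect_equal(effective_sample_size(rep(1 / 7, 7)), 7)
  expect_equal(effective_sample_size(c(1, rep(0, 9))), 1)
  expect_equal(effective_sample_size(c(0.5, 0.5, 0, 0)), 2)
})

test_that("ESS decreases as the target moves away from the prior mean", {
  set.seed(33)
  x <- rnorm(300)
  ess <- vapply(c(0, 0.3, 0.6, 0.9, 1.2), function(shift) {
    om <- observable_matrix(matrix(x, ncol = 1), targets = mean(x) + shift,
                            sigma = 0.1)
    reweight(om)$ess
  }, numeric(1))
  expect_true(all(diff(ess) < 0))
})

test_that("gaussian model bridges exact (sigma -> 0) and prior (sigma -> Inf)", {
  set.seed(9)
  x <- runif(50, 0, 10)
  target <- mean(x) + 1.5
  om_exact <- observable_matrix(matrix(x, ncol = 1), target, sigma = 1)
  w_exact <- reweight(om_exact, error_model = "exact")$w
  w_small <- reweight(observable_matrix(matrix(x, ncol = 1), target, 1e-5))$w
  w_large <- reweight(observable_matrix(matrix(x, ncol = 1), target, 1e5))$w
  expect_equal(w_small, w_exact, tolerance = 1e-3)
  expect_equal(w_large, rep(1 / 50, 50), tolerance = 1e-5)
})

test_that("optimum is independent of the starting point (convex dual)", {
  set.seed(14)
  X <- matrix(rnorm(60 * 3), 60, 3)
  om <- observable_matrix(X, targets = colMeans(X) + c(0.2, -0.4, 0.1),
                          sigma = rep(0.3, 3))
  w0 <- reweight(om)$w
  for (s in 1:4) {
    ws <- reweight(om, start = rnorm(3, sd = 2))$w
    expect_equal(ws, w0, tolerance = 1e-6)
  }
})

test_that("solution has minimal relative entropy among constraint-matchers", {
  set.seed(77)
  x <- rnorm(40)
  target <- mean(x) + 0.5
  om <- observable_matrix(matrix(x, ncol = 1), target, sigma = 1)
  wv <- reweight(om, error_model = "exact")
  kl <- function(w) sum(w[w > 0] * log(w[w > 0] * length(w)))
  kl_opt <- kl(wv$w)
  # random perturbations inside the constraint surface: add a direction
  # orthogonal to both the constraint gradient and the normalization
  for (rep in 1:20) {
    d <- rnorm(40)
    d <- d - mean(d)
    xc <- x - sum(wv$w * x)
    d <- d - sum(d * xc) / sum(xc * xc) * xc
    d <- d - mean(d)   # re-center after projection
    w2 <- wv$w + 1e-3 * d / max(abs(d))
    if (any(w2 <= 0)) next
    w2 <- w2 / sum(w2)
    # verify the perturbed weights still match the constraint to first order
    if (abs(sum(w2 * x) - target) > 1e-4) next
    expect_gte(kl(w2), kl_opt - 1e-12)
  }
})

test_that("exact model rejects unattainable targets, naming the observable", {
  X <- cbind(J9 = c(1, 2, 3), rg2 = c(300, 310, 320))
  om <- suppressWarnings(
    observable_matrix(X, targets = c(9, 310), sigma = c(0.5, 5)))
  expect_error(reweight(om, error_model = "exact"), "J9")
  expect_warning(observable_matrix(X, targets = c(9, 310),
                                   sigma = c(0.5, 5)), "outside")
})

test_that("planted pucker fractions are recovered on a synthetic ensemble", {
  sp <- spec20_I()
  jres <- c(9:12, 29:32)
  names_c2 <- as.character(jres)
  rec <- ensemble_recipe(sp, n_conformers = 200,
                         c2_fraction = setNames(rep(0.5, 8), names_c2),
                         noise_sd = 0.02, seed = 101)
  ens <- generate_ensemble(rec)
  Jmat <- t(vapply(ens$conformers, function(cf) j_from_conformer(cf, jres),
                   numeric(8)))
  # planted truth: target fractions differing from the 0.5 prior
  f_star <- setNames(c(0.3, 0.6, 0.45, 0.7, 0.35, 0.55, 0.25, 0.65), names_c2)
  j_c3 <- j_from_conformer(build_ribose(18, 38))[[1]]
  j_c2 <- j_from_conformer(build_ribose(162, 38))[[1]]
  targets <- f_star * j_c2 + (1 - f_star) * j_c3
  om <- observable_matrix(Jmat, targets = targets, sigma = rep(0.2, 8),
                          labels = paste0("J", jres))
  wv <- reweight(om)
  expect_true(wv$converged)
  # reweighted averages within sigma of the targets
  expect_true(all(abs(wv$achieved - targets) <= 0.2))
  # per-residue C2'-endo fractions from the ground-truth table
  frac <- as.vector(t(ens$truth$pucker[, names_c2]) %*% wv$w)
  expect_true(all(abs(frac - f_star) <= 0.05))
})
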