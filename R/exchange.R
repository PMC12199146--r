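# Hydrogen-exchange and relaxation fitting: CLEANEX-PM build-up curves,
# CPMG R2eff, mono-exponential decays, heteronuclear NOE ratios.

#' CLEANEX-PM build-up model
#'
#' Intensity ratio of an exchanging imino proton after mixing time tau:
#' I(tau)/I_ref = kex / (R1A + kex +/- R1W) *
#'                (exp(-R1W tau) - exp(-(R1A + kex) tau)).
#' The default variant "as-printed" uses + R1W in the prefactor denominator,
#' reproducing the build-up expression as published with the data this
#' package targets; "conventional" uses - R1W there (the standard CLEANEX
#' initial-rate derivation). The two differ only by a bounded scale factor
#' over typical imino-proton rate regimes; neither is silently corrected.
#'
#' @param tau mixing time(s) in seconds.
#' @param kex apparent exchange rate (1/s, >= 0).
#' @param R1A longitudinal relaxation rate of the imino proton (1/s).
#' @param R1W longitudinal relaxation rate of water (1/s), measured
#'   independently.
#' @param variant "as-printed" or "conventional".
#' @return intensity ratio(s), dimensionless.
#' @export
cleanex_model <- function(tau, kex, R1A, R1W,
                          variant = c("as-printed", "conventional")) {
  variant <- match.arg(variant)
  if (kex < 0 || R1A < 0 || R1W < 0) stop("rates must be non-negative")
  denom <- if (variant == "as-printed") R1A + kex + R1W else R1A + kex - R1W
  if (abs(denom) < 1e-12) return(rep(0, length(tau)))
  kex / denom * (exp(-R1W * tau) - exp(-(R1A + kex) * tau))
}

#' CLEANEX build-up curve container
#'
#' @param tau mixing times in seconds (non-negative, strictly increasing).
#' @param ratio measured I(tau)/I_ref.
#' @param sigma optional per-point uncertainties.
#' @return an object of class `cleanex_curve` (data.frame).
#' @export
cleanex_curve <- function(tau, ratio, sigma = NA_real_) {
  if (any(tau < 0)) stop("tau must be non-negative")
  if (is.unsorted(tau, strictly = TRUE)) stop("tau must be strictly increasing")
  if (length(ratio) != length(tau)) stop("tau and ratio lengths differ")
  if (any(!is.finite(ratio))) stop("ratios must be finite")
  if (length(sigma) == 1) sigma <- rep(sigma, length(tau))
  structure(data.frame(tau = tau, ratio = ratio, sigma = sigma),
            class = c("cleanex_curve", "data.frame"))
}

#' Fit a CLEANEX-PM build-up curve
#'
#' Weighted nonlinear least squares over (kex, R1A) with R1W held fixed (it
#' is measured independently by saturation recovery). Uses per-point sigma
#' when available, else unweighted. kex is bounded to [0, 1e4] 1/s.
#'
#' @param curve a [cleanex_curve()].
#' @param R1W fixed water relaxation rate (1/s).
#' @param variant model variant, see [cleanex_model()].
#' @return an object of class `cleanex_fit`: list with kex, R1A, R1W,
#'   covariance of (kex, R1A), fitted values, chi2 and a `flat` flag set when
#'   the curve carries no build-up (kex pinned at 0).
#' @export
fit_cleanex <- function(curve, R1W, variant = c("as-printed", "conventional")) {
  variant <- match.arg(variant)
  stopifnot(inherits(curve, "cleanex_curve"))
  if (nrow(curve) < 4) stop("need at least 4 points to fit (kex, R1A)")
  tau <- curve$tau
  y <- curve$ratio
  w <- if (all(is.finite(curve$sigma)) && all(curve$sigma > 0))
    1 / curve$sigma^2 else rep(1, length(y))
  if (all(abs(y) < 1e-12)) {
    return(structure(list(kex = 0, R1A = NA_real_, R1W = R1W,
                          cov = matrix(NA_real_, 2, 2), fitted = y * 0,
                          chi2 = 0, flat = TRUE, variant = variant),
                     class = "cleanex_fit"))
  }
  ssq <- function(p) {
    f <- cleanex_model(tau, p[1], p[2], R1W, variant)
    sum(w * (f - y)^2)
  }
  # coarse start grid, then bounded quasi-Newton
  grid <- expand.grid(kex = c(0.1, 1, 5, 20, 100), R1A = c(0.5, 2, 10, 50))
  v <- apply(grid, 1, ssq)
  p0 <- as.numeric(grid[which.min(v), ])
  fit <- stats::optim(p0, ssq, method = "L-BFGS-B",
                      lower = c(0, 1e-6), upper = c(1e4, 1e4),
                      control = list(maxit = 2000, factr = 1e4))
  fit <- stats::optim(fit$par, ssq, method = "L-BFGS-B",
                      lower = c(0, 1e-6), upper = c(1e4, 1e4),
                      control = list(maxit = 2000, factr = 1e1))
  p <- fit$par
  # Gauss-Newton covariance from the numeric Jacobian
  jac <- matrix(NA_real_, length(tau), 2)
  h <- pmax(1e-6, abs(p) * 1e-6)
  for (k in 1:2) {
    pp <- p; pm <- p
    pp[k] <- pp[k] + h[k]; pm[k] <- max(pm[k] - h[k], 0)
    jac[, k] <- (cleanex_model(tau, pp[1], pp[2], R1W, variant) -
                   cleanex_model(tau, pm[1], pm[2], R1W, variant)) /
      (pp[k] - pm[k])
  }
  JWJ <- crossprod(jac * sqrt(w))
  cov <- tryCatch(solve(JWJ), error = function(e) matrix(NA_real_, 2, 2))
  if (!all(is.finite(curve$sigma))) {
    dof <- max(length(y) - 2, 1)
    cov <- cov * fit$value / dof
  }
  fitted <- cleanex_model(tau, p[1], p[2], R1W, variant)
  chi2v <- if (all(is.finite(curve$sigma)) && all(curve$sigma > 0))
    mean(((fitted - y) / curve$sigma)^2) else NA_real_
  structure(list(kex = p[1], R1A = p[2], R1W = R1W, cov = cov,
                 fitted = fitted, chi2 = chi2v, flat = FALSE,
                 variant = variant),
            class = "cleanex_fit")
}

#' @export
print.cleanex_fit <- function(x, ...) {
  if (x$flat) {
    cat("cleanex_fit: flat curve, kex pinned at 0\n")
  } else {
    cat(sprintf("cleanex_fit (%s): kex = %.3f 1/s, R1A = %.3f 1/s (R1W fixed %.3f)\n",
                x$variant, x$kex, x$R1A, x$R1W))
  }
  invisible(x)
}

#' Effective transverse relaxation rate from a CPMG experiment
#'
#' R2eff = -(1/T_cpmg) ln(I / I0). Non-positive intensities yield NA with a
#' warning (undefined logarithm); intensities above the reference yield a
#' negative rate with a warning.
#'
#' @param I peak intensity with the CPMG pulse train (vectorized).
#' @param I0 reference intensity (> 0).
#' @param T_cpmg constant-time relaxation delay in seconds (> 0).
#' @return rate(s) in 1/s.
#' @export
r2eff_cpmg <- function(I, I0, T_cpmg) {
  if (I0 <= 0) stop("I0 must be positive")
  if (T_cpmg <= 0) stop("T_cpmg must be positive")
  out <- rep(NA_real_, length(I))
  bad <- I <= 0
  if (any(bad)) warning("non-positive intensity: R2eff undefined, set NA")
  out[!bad] <- -log(I[!bad] / I0) / T_cpmg
  if (any(I > I0)) warning("intensity above reference: negative R2eff")
  out
}

#' Fit a single-exponential decay
#'
#' Least-squares fit of I(t) = I0 exp(-R t). Duplicate delays are allowed
#' (repeat measurements). A constant positive signal fits R = 0.
#'
#' @param delays relaxation delays in seconds.
#' @param intensities measured intensities.
#' @return list with `rate` (1/s), `I0` and `fitted`.
#' @export
fit_monoexp <- function(delays, intensities) {
  if (length(delays) != length(intensities)) stop("length mismatch")
  if (length(delays) < 3) stop("need at least 3 points")
  pos <- intensities > 0
  if (sum(pos) >= 2 && stats::var(delays[pos]) > 0) {
    lf <- stats::lm.fit(cbind(1, delays[pos]), log(intensities[pos]))
    p0 <- c(exp(lf$coefficients[1]), max(0, -lf$coefficients[2]))
  } else {
    p0 <- c(max(intensities), 1)
  }
  ssq <- function(p) sum((p[1] * exp(-p[2] * delays) - intensities)^2)
  fit <- stats::optim(p0, ssq, method = "L-BFGS-B",
                      lower = c(1e-12, 0), upper = c(Inf, 1e6),
                      control = list(maxit = 2000, factr = 1e1))
  if (fit$par[1] <= 0) stop("non-positive fitted I0")
  list(rate = unname(fit$par[2]), I0 = unname(fit$par[1]),
       fitted = fit$par[1] * exp(-fit$par[2] * delays))
}

#' Heteronuclear NOE intensity ratio
#'
#' @param I_sat intensity in the proton-saturated experiment.
#' @param I_ref intensity in the reference (non-saturated) experiment;
#'   must be non-zero.
#' @return I_sat / I_ref.
#' @export
hetnoe_ratio <- function(I_sat, I_ref) {
  if (any(I_ref == 0)) stop("zero reference intensity")
  I_sat / I_ref
}
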