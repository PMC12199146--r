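# SAXS back-calculation and analysis: Debye profiles, Guinier fits.

#' SAXS profile container
#'
#' @param q scattering-vector grid; strictly increasing, non-negative. Unit
#'   per `q_unit` ("A^-1", the internal standard, or "nm^-1", converted on
#'   input).
#' @param I intensities (arbitrary units).
#' @param sigma per-point uncertainties (> 0 wherever fitting occurs; may be
#'   NA for back-calculated profiles).
#' @param q_unit unit of the supplied grid.
#' @return an object of class `saxs_profile` with q in inverse Angstrom.
#' @export
saxs_profile <- function(q, I, sigma = NA_real_, q_unit = c("A^-1", "nm^-1")) {
  q_unit <- match.arg(q_unit)
  if (q_unit == "nm^-1") q <- q / 10
  if (length(I) != length(q)) stop("q and I lengths differ")
  if (length(sigma) == 1) sigma <- rep(sigma, length(q))
  if (length(sigma) != length(q)) stop("sigma length mismatch")
  if (any(!is.finite(q)) || any(q < 0)) stop("q must be finite and >= 0")
  if (is.unsorted(q, strictly = TRUE)) stop("q must be strictly increasing")
  if (any(!is.na(sigma) & sigma <= 0)) stop("sigma must be positive")
  structure(data.frame(q = q, I = I, sigma = sigma), class =
              c("saxs_profile", "data.frame"))
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("saxs_profile: %d points, q in [%.4g, %.4g] A^-1\n",
              nrow(x), min(x$q), max(x$q)))
  invisible(x)
}

#' Debye scattering profile of a conformer or ensemble
#'
#' I(q) = sum_i sum_j f_i f_j sin(q r_ij) / (q r_ij) over heavy atoms, with
#' the i = j and q -> 0 limits handled analytically (sinc -> 1). Form factors
#' default to a uniform per-heavy-atom constant (coarse-grained; no hydration
#' layer). For an ensemble the weighted average profile is returned.
#'
#' @param x a `conformer` or `rna_ensemble`.
#' @param q scattering-vector grid in inverse Angstrom.
#' @param form_factor per-atom constant (scalar) or per-atom vector.
#' @param weights optional conformer weights (ensemble case).
#' @return a `saxs_profile` with NA sigma.
#' @export
debye_profile <- function(x, q, form_factor = 1, weights = NULL) {
  if (any(!is.finite(q)) || any(q < 0)) stop("q must be finite and >= 0")
  if (inherits(x, "rna_ensemble")) {
    w <- .ens_weights(x, weights)
    Is <- vapply(x$conformers,
                 function(cf) debye_profile(cf, q, form_factor)$I,
                 numeric(length(q)))
    return(saxs_profile(q, as.vector(Is %*% w)))
  }
  X <- heavy_xyz(as_conformer(x))
  n <- nrow(X)
  if (n < 1) stop("empty conformer")
  f <- if (length(form_factor) == 1) rep(form_factor, n) else form_factor
  if (length(f) != n) stop("form_factor length must be 1 or n_atoms")
  self <- sum(f^2)
  if (n == 1) return(saxs_profile(q, rep(self, length(q))))
  d <- as.vector(stats::dist(X))
  # pairwise form-factor products for the i < j pairs, in dist() order
  fp <- tcrossprod(f)[lower.tri(diag(n))]
  I <- vapply(q, function(qi) {
    if (qi == 0) return(self + 2 * sum(fp))
    x <- qi * d
    self + 2 * sum(fp * sin(x) / x)
  }, numeric(1))
  saxs_profile(q, I)
}

#' Guinier fit of a SAXS profile
#'
#' Weighted linear fit of ln I against q^2 at low q; Rg = sqrt(-3 slope).
#' The fitting window is shrunk iteratively until q_max * Rg <= `qrg_limit`
#' (default 1.3).
#'
#' @param profile a `saxs_profile`.
#' @param qrg_limit upper bound on q * Rg inside the fitting window.
#' @param min_points minimum number of points in the window.
#' @return list with `rg` (Angstrom), `I0`, `window` (row indices used),
#'   and `qrg_max`.
#' @export
guinier_fit <- function(profile, qrg_limit = 1.3, min_points = 3) {
  q <- profile$q
  I <- profile$I
  sig <- profile$sigma
  use_w <- all(is.finite(sig)) && all(sig > 0)
  # the window only ever shrinks, which guarantees termination
  win <- which(q > 0)
  for (iter in 1:100) {
    if (length(win) < min_points)
      stop("Guinier window collapsed below ", min_points, " points")
    if (any(I[win] <= 0))
      stop("non-positive intensities inside the Guinier window")
    x <- q[win]^2
    y <- log(I[win])
    # error propagation: sigma(ln I) = sigma / I
    w <- if (use_w) (I[win] / sig[win])^2 else rep(1, length(win))
    fit <- stats::lm.wfit(cbind(1, x), y, w)
    slope <- fit$coefficients[2]
    if (!is.finite(slope) || slope >= 0)
      stop("Guinier fit did not converge (non-negative slope)")
    rg <- sqrt(-3 * slope)
    win_new <- win[q[win] * rg <= qrg_limit]
    if (identical(win_new, win)) {
      return(list(rg = unname(rg), I0 = unname(exp(fit$coefficients[1])),
                  window = win, qrg_max = max(q[win]) * rg))
    }
    win <- win_new
  }
  stop("Guinier window iteration did not converge")
}
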