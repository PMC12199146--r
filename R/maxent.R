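# Maximum-entropy ensemble reweighting against experimental averages.
#
# The reweighted ensemble w_j proportional to w0_j * exp(-sum_i lambda_i
# O_i(x_j)) is the minimal relative-entropy distribution whose averages match
# the targets. The multipliers are found by minimizing the convex dual
#   Gamma(lambda) = ln Z(lambda) + sum_i lambda_i O_i^exp
#                   (+ 1/2 sum_i lambda_i^2 sigma_i^2 for the gaussian model)
# with analytic gradient  O^exp - <O>_lambda (+ sigma^2 lambda).

#' Observable matrix for maximum-entropy reweighting
#'
#' @param values n_conformers x n_observables matrix of back-calculated
#'   values (e.g. Hz for J couplings, Angstrom^2 for Rg^2).
#' @param targets experimental averages, one per observable.
#' @param sigma experimental uncertainties, one per observable (> 0).
#' @param labels observable names.
#' @return an object of class `observable_matrix`.
#' @export
observable_matrix <- function(values, targets, sigma,
                              labels = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(labels)) labels <- paste0("obs", seq_len(ncol(values)))
  if (length(targets) != ncol(values) || length(sigma) != ncol(values))
    stop("targets and sigma must have one entry per observable column")
  if (any(!is.finite(values))) stop("non-finite observable values")
  if (any(!is.finite(targets))) stop("non-finite targets")
  if (any(sigma <= 0)) stop("sigma must be positive")
  colnames(values) <- labels
  lo <- apply(values, 2, min)
  hi <- apply(values, 2, max)
  outside <- targets < lo | targets > hi
  if (any(outside))
    warning("target(s) outside the ensemble's value range: ",
            paste(labels[outside], collapse = ", "))
  structure(list(values = values, targets = targets, sigma = sigma,
                 labels = labels), class = "observable_matrix")
}

#' @export
print.observable_matrix <- function(x, ...) {
  cat(sprintf("observable_matrix: %d conformers x %d observables (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(utils::head(x$labels, 5), collapse = ", ")))
  invisible(x)
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Maximum-entropy reweighting
#'
#' Finds conformer weights w_j proportional to prior_j *
#' exp(-sum_i lambda_i O_ij) whose averages match the experimental targets:
#' exactly (error model "exact") or within the experimental uncertainty
#' (model "gaussian", which adds the regularizer 1/2 lambda^2 sigma^2 to the
#' dual and is equivalent to allowing gaussian discrepancies of width sigma).
#'
#' @param obs an [observable_matrix()].
#' @param prior prior weights (default uniform); normalized on input.
#' @param error_model "gaussian" (default) or "exact".
#' @param config pipeline configuration (optimizer tolerance, default model).
#' @param start optional starting multipliers.
#' @return an object of class `weight_vector`: list with `w` (normalized
#'   weights), `lambda` (per-observable multipliers), `achieved` (reweighted
#'   averages), `targets`, `ess` (Kish effective sample size) and
#'   `converged`.
#' @export
reweight <- function(obs, prior = NULL, error_model = NULL,
                     config = default_config(), start = NULL) {
  config <- validate_config(config)
  stopifnot(inherits(obs, "observable_matrix"))
  if (is.null(error_model)) error_model <- config$maxent$error_model
  error_model <- match.arg(error_model, c("gaussian", "exact"))
  O <- obs$values
  n <- nrow(O)
  m <- ncol(O)
  if (is.null(prior)) prior <- rep(1 / n, n)
  if (length(prior) != n || any(prior < 0) || sum(prior) <= 0)
    stop("invalid prior weights")
  prior <- prior / sum(prior)
  if (error_model == "exact") {
    lo <- apply(O[prior > 0, , drop = FALSE], 2, min)
    hi <- apply(O[prior > 0, , drop = FALSE], 2, max)
    bad <- obs$targets <= lo - 1e-12 | obs$targets >= hi + 1e-12
    # a target equal to an extreme value is attainable only by a point mass;
    # treat strictly-outside as infeasible
    bad <- obs$targets < lo | obs$targets > hi
    if (any(bad))
      stop("exact reweighting infeasible: target outside ensemble range for ",
           paste(obs$labels[bad], collapse = ", "))
  }
  lp <- log(prior)
  lp[prior == 0] <- -Inf
  s2 <- if (error_model == "gaussian") obs$sigma^2 else rep(0, m)
  # center observables for numerical conditioning; Gamma is shifted by a
  # lambda-linear term that the gradient handles transparently
  ctr <- obs$targets
  Oc <- sweep(O, 2, ctr)
  dual <- function(lambda) {
    a <- lp - as.vector(Oc %*% lambda)
    .logsumexp(a) + 0.5 * sum(lambda^2 * s2)
  }
  grad <- function(lambda) {
    a <- lp - as.vector(Oc %*% lambda)
    a <- a - .logsumexp(a)
    w <- exp(a)
    -as.vector(t(Oc) %*% w) + lambda * s2
  }
  l0 <- if (is.null(start)) rep(0, m) else start
  fit <- stats::optim(l0, dual, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  # polish with a second pass (BFGS restarts cheaply from the optimum)
  fit <- stats::optim(fit$par, dual, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  lambda <- fit$par
  g <- grad(lambda)
  converged <- max(abs(g)) < max(config$maxent$grad_tol, 1e-6 * max(1, max(abs(obs$targets))))
  a <- lp - as.vector(Oc %*% lambda)
  a <- a - .logsumexp(a)
  w <- exp(a)
  achieved <- as.vector(t(O) %*% w)
  if (error_model == "exact") {
    err <- max(abs(achieved - obs$targets) / pmax(1, abs(obs$targets)))
    if (err > 1e-6)
      stop("exact reweighting did not converge for ",
           paste(obs$labels[which.max(abs(achieved - obs$targets))],
                 collapse = ", "))
  }
  structure(list(w = w, lambda = setNames(lambda, obs$labels),
                 achieved = setNames(achieved, obs$labels),
                 targets = setNames(obs$targets, obs$labels),
                 error_model = error_model,
                 ess = 1 / sum(w^2), converged = converged),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("weight_vector: %d conformers, ESS = %.1f, model = %s%s\n",
              length(x$w), x$ess, x$error_model,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Kish effective sample size
#'
#' 1 / sum(w^2) for normalized weights: the number of conformers effectively
#' contributing after reweighting (N for uniform weights, 1 for a point
#' mass).
#'
#' @param w a `weight_vector` or numeric weights (normalized on input).
#' @return effective sample size.
#' @export
effective_sample_size <- function(w) {
  if (inherits(w, "weight_vector")) w <- w$w
  if (any(w < 0)) stop("weights must be non-negative")
  w <- w / sum(w)
  1 / sum(w^2)
}

#' Weighted ensemble average of an observable column
#'
#' @param w a `weight_vector` or numeric weights.
#' @param column numeric per-conformer values.
#' @return sum(w * column) with normalized weights.
#' @export
weighted_average <- function(w, column) {
  if (inherits(w, "weight_vector")) w <- w$w
  if (length(w) != length(column)) stop("length mismatch")
  w <- w / sum(w)
  sum(w * column)
}
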