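# NMR observables: Karplus scalar couplings, canonical chemical-shift
# coordinates, radius of gyration, pair-distance distributions, NOE
# effective distances, and the chi-square agreement measures.

#' Karplus relation for a three-bond scalar coupling
#'
#' 3J = A cos^2(phi) + B cos(phi) + C over the intervening dihedral.
#' The default coefficients (config group `karplus`) are the Davies ribose
#' H1'-H2' parameterization, under which an ideal C3'-endo ribose gives a
#' coupling below 1 Hz and an ideal C2'-endo ribose 10-12 Hz.
#'
#' @param phi dihedral angle in degrees (vectorized).
#' @param params list with A, B, C in Hz.
#' @return coupling in Hz.
#' @export
karplus_j <- function(phi, params = default_config()$karplus) {
  if (any(!is.finite(phi))) stop("phi must be finite")
  cp <- cos(phi * DEG)
  params$A * cp^2 + params$B * cp + params$C
}

#' Back-calculate 3J(H1',H2') from a conformer
#'
#' Measures the H1'-C1'-C2'-H2' dihedral of each requested residue and feeds
#' it to [karplus_j()]. Residues missing one of the four atoms get NA.
#'
#' @param conformer a `conformer`.
#' @param residues residue numbers (default: all residues present).
#' @param config pipeline configuration (Karplus coefficients).
#' @return named numeric vector of couplings in Hz.
#' @export
j_from_conformer <- function(conformer, residues = NULL,
                             config = default_config()) {
  config <- validate_config(config)
  conformer <- as_conformer(conformer)
  at <- conformer$atoms
  if (is.null(residues)) residues <- sort(unique(at$res))
  out <- setNames(rep(NA_real_, length(residues)), residues)
  for (i in seq_along(residues)) {
    r <- residues[i]
    ps <- lapply(c("H1'", "C1'", "C2'", "H2'"), function(a) atom_xyz(conformer, r, a))
    if (any(vapply(ps, is.null, logical(1)))) next
    phi <- dihedral_angle(ps[[1]], ps[[2]], ps[[3]], ps[[4]])
    if (is.na(phi)) next
    out[i] <- karplus_j(phi, config$karplus)
  }
  out
}

#' Canonical coordinates can1/can2 from ribose 13C chemical shifts
#'
#' Linear combinations of the five ribose carbon shifts that are diagnostic
#' of sugar pucker:
#' can1 = 0.179 dC1' - 0.225 dC4' - 0.0585 dC5';
#' can2 = -0.0605 (dC2' + dC3') - 0.0556 dC4' - 0.0524 dC5'.
#'
#' @param shifts data.frame with columns res, dC1p, dC2p, dC3p, dC4p, dC5p
#'   (ppm). Rows with a missing shift yield NA coordinates.
#' @return data.frame with columns res, can1, can2.
#' @export
canonical_coordinates <- function(shifts) {
  need <- c("res", "dC1p", "dC2p", "dC3p", "dC4p", "dC5p")
  miss <- setdiff(need, names(shifts))
  if (length(miss)) stop("shift table missing column(s): ",
                         paste(miss, collapse = ", "))
  can1 <- 0.179 * shifts$dC1p - 0.225 * shifts$dC4p - 0.0585 * shifts$dC5p
  can2 <- -0.0605 * (shifts$dC2p + shifts$dC3p) - 0.0556 * shifts$dC4p -
    0.0524 * shifts$dC5p
  data.frame(res = shifts$res, can1 = can1, can2 = can2)
}

#' Experimental sugar-pucker restraint class
#'
#' A residue is restrained C2'-endo iff its coupling exceeds 3 Hz AND its
#' can1 coordinate is below -6.25 ppm (strict inequalities); otherwise
#' C3'-endo.
#'
#' @param J 3J(H1',H2') in Hz (vectorized).
#' @param can1 canonical coordinate in ppm (vectorized).
#' @return character vector, "C2-endo" or "C3-endo".
#' @export
classify_pucker_experimental <- function(J, can1) {
  if (any(!is.finite(J)) || any(!is.finite(can1)))
    stop("J and can1 must be finite")
  ifelse(J > 3 & can1 < -6.25, "C2-endo", "C3-endo")
}

#' Radius of gyration
#'
#' Uniform heavy-atom weighting. For a single conformer returns Rg in
#' Angstrom. For an ensemble returns both the reweighting observable
#' <Rg^2> (the weighted average of per-conformer squared radii) and its
#' square root, plus the per-conformer values.
#'
#' @param x a `conformer` or `rna_ensemble`.
#' @param weights optional conformer weights (default: the ensemble's own,
#'   or uniform).
#' @return numeric Rg (conformer) or list(mean_rg2, rms_rg, per_conformer)
#'   (ensemble).
#' @export
radius_of_gyration <- function(x, weights = NULL) {
  if (inherits(x, "rna_ensemble")) {
    w <- .ens_weights(x, weights)
    rg <- vapply(x$conformers, radius_of_gyration, numeric(1))
    m2 <- sum(w * rg^2)
    return(list(mean_rg2 = m2, rms_rg = sqrt(m2), per_conformer = rg))
  }
  X <- heavy_xyz(as_conformer(x))
  if (nrow(X) < 1) stop("empty conformer")
  sqrt(mean(rowSums(sweep(X, 2, colMeans(X))^2)))
}

#' Pair-distance distribution P(r)
#'
#' Normalized histogram of all heavy-atom pairwise distances. Dmax is the
#' maximum distance; Rg follows from the second moment of P(r) with the
#' exact finite-N correction Rg^2 = ((N-1)/2N) <r^2>, which converges to the
#' continuum relation Rg^2 = (1/2) integral P(r) r^2 dr.
#'
#' @param conformer a `conformer`.
#' @param bin_width histogram bin width in Angstrom.
#' @return an object of class `pofr`: list with r (bin centers), p (density,
#'   integrates to 1), dmax (Angstrom), rg (Angstrom), bin_width, n_atoms.
#' @export
pair_distance_distribution <- function(conformer, bin_width = 1.0) {
  X <- heavy_xyz(as_conformer(conformer))
  n <- nrow(X)
  if (n < 2) stop("need at least two heavy atoms")
  d <- as.vector(stats::dist(X))
  dmax <- max(d)
  breaks <- seq(0, dmax + bin_width, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  p <- h$counts / (length(d) * bin_width)
  rg <- sqrt((n - 1) / (2 * n) * mean(d^2))
  structure(list(r = h$mids, p = p, dmax = dmax, rg = rg,
                 bin_width = bin_width, n_atoms = n), class = "pofr")
}

#' @export
print.pofr <- function(x, ...) {
  cat(sprintf("pofr: %d bins (width %.2f A), Dmax = %.2f A, Rg = %.2f A\n",
              length(x$r), x$bin_width, x$dmax, x$rg))
  invisible(x)
}

# ---- NOE ----------------------------------------------------------------

.noe_bins <- list(strong = c(1.8, 3.3), medium = c(2.0, 4.5), weak = c(3.3, 5.1))

#' NOE distance-restraint table
#'
#' @param res1,atom1,res2,atom2 atom identifiers of the restrained pair.
#' @param bin restraint class: "strong" (1.8-3.3 A), "medium" (2.0-4.5 A) or
#'   "weak" (3.3-5.1 A).
#' @return data.frame with columns res1, atom1, res2, atom2, bin, lower,
#'   upper, of class `noe_restraints`.
#' @export
noe_restraints <- function(res1, atom1, res2, atom2, bin) {
  bin <- match.arg(bin, names(.noe_bins), several.ok = TRUE)
  if (length(bin) == 1) bin <- rep(bin, length(res1))
  bounds <- do.call(rbind, .noe_bins[bin])
  out <- data.frame(res1 = res1, atom1 = atom1, res2 = res2, atom2 = atom2,
                    bin = bin, lower = bounds[, 1], upper = bounds[, 2])
  class(out) <- c("noe_restraints", "data.frame")
  out
}

#' Ensemble-averaged NOE effective distances
#'
#' d_eff = (sum_j w_j r_j^-6)^(-1/6): the r^-6 ensemble average matching the
#' NOE's distance dependence.
#'
#' @param ensemble an `rna_ensemble` (or single `conformer`).
#' @param restraints a `noe_restraints` table.
#' @param weights optional conformer weights.
#' @return numeric vector of effective distances (Angstrom).
#' @export
noe_backcalc <- function(ensemble, restraints, weights = NULL) {
  if (inherits(ensemble, "conformer"))
    ensemble <- rna_ensemble(list(ensemble))
  w <- .ens_weights(ensemble, weights)
  m <- nrow(restraints)
  acc <- matrix(NA_real_, length(ensemble$conformers), m)
  for (j in seq_along(ensemble$conformers)) {
    cf <- ensemble$conformers[[j]]
    for (i in seq_len(m)) {
      p1 <- atom_xyz(cf, restraints$res1[i], restraints$atom1[i])
      p2 <- atom_xyz(cf, restraints$res2[i], restraints$atom2[i])
      if (is.null(p1) || is.null(p2))
        stop("cannot resolve atom ", restraints$res1[i], "/",
             restraints$atom1[i], " or ", restraints$res2[i], "/",
             restraints$atom2[i], " in conformer ", j)
      acc[j, i] <- vnorm(p1 - p2)
    }
  }
  as.vector((t(w) %*% acc^(-6))^(-1 / 6))
}

# ---- chi-square ---------------------------------------------------------

#' Chi-square agreement between back-calculated and experimental data
#'
#' \describe{
#'   \item{J}{mean of ((Jcalc - Jexp)/sigma)^2.}
#'   \item{NOE}{mean of (violation/sigma)^2, where the violation is the
#'     distance outside the restraint bin (`exp` must carry lower/upper
#'     bounds, e.g. a `noe_restraints` table) and zero inside.}
#'   \item{SAXS}{minimum over scale c and constant offset b of the mean of
#'     ((c I_calc + b - I_exp)/sigma)^2, by closed-form weighted least
#'     squares (CRYSOL-like).}
#' }
#'
#' @param calc back-calculated values (J in Hz, distances in Angstrom, or
#'   intensities).
#' @param exp experimental values; for kind "NOE" a data.frame with lower
#'   and upper columns.
#' @param sigma per-point uncertainties (scalar or vector, > 0).
#' @param kind one of "J", "NOE", "SAXS".
#' @return the chi-square value (scalar).
#' @export
chi2 <- function(calc, exp, sigma, kind = c("J", "NOE", "SAXS")) {
  kind <- match.arg(kind)
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (kind == "NOE") {
    if (!all(c("lower", "upper") %in% names(exp)))
      stop("NOE chi2 needs lower/upper bounds in exp")
    if (length(calc) != nrow(exp)) stop("calc and exp lengths differ")
    viol <- pmax(0, calc - exp$upper, exp$lower - calc)
    return(mean((viol / sigma)^2))
  }
  if (length(calc) != length(exp)) stop("calc and exp lengths differ")
  if (kind == "J") return(mean(((calc - exp) / sigma)^2))
  # SAXS: weighted LS for scale + offset
  w <- 1 / sigma^2
  X <- cbind(calc, 1)
  WX <- X * w
  beta <- solve(crossprod(X, WX), crossprod(WX, exp))
  resid <- as.vector(X %*% beta) - exp
  mean((resid / sigma)^2)
}
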