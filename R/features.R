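# Conformer featurization (torsion circular encoding + G-vectors) and
# weighted principal component analysis.

# Base reference frame for G-vectors: origin at the centroid of the C2, C4,
# C6 ring atoms (present in all five bases), x toward C2, z along the ring
# normal, y completing the right-handed frame.
base_frame <- function(conformer, res) {
  p2 <- atom_xyz(conformer, res, "C2")
  p4 <- atom_xyz(conformer, res, "C4")
  p6 <- atom_xyz(conformer, res, "C6")
  if (is.null(p2) || is.null(p4) || is.null(p6)) return(NULL)
  o <- (p2 + p4 + p6) / 3
  x <- unitv(p2 - o)
  z <- unitv(pracma_cross(x, unitv(p4 - o)))
  y <- pracma_cross(z, x)
  list(origin = o, F = cbind(x, y, z))
}

#' G-vector features of a conformer
#'
#' For every ordered residue pair (i, j), the displacement of base j's frame
#' origin is expressed in base i's frame, scaled anisotropically (x and y by
#' `scale_xy`, z by `scale_z`, reflecting the shorter stacking range), and
#' mapped through the smooth vector function
#' G(r) = (sin(g rho) x/rho, sin(g rho) y/rho, sin(g rho) z/rho,
#'         1 + cos(g rho)) / g
#' with rho = |scaled r| and g = pi / cutoff; pairs beyond the scaled cutoff
#' contribute an exact zero 4-vector, making the feature length fixed across
#' an ensemble. The construction is invariant under rigid-body motion.
#'
#' @param conformer a `conformer`.
#' @param config pipeline configuration (`gvector` group).
#' @return named numeric vector of length 4 * n * (n - 1); residues whose
#'   base frame atoms are missing contribute zeros (with a message).
#' @export
gvector_features <- function(conformer, config = default_config()) {
  config <- validate_config(config)
  gv <- config$gvector
  conformer <- as_conformer(conformer)
  res <- sort(unique(conformer$atoms$res))
  n <- length(res)
  frames <- lapply(res, function(r) base_frame(conformer, r))
  missing <- vapply(frames, is.null, logical(1))
  if (any(missing))
    message("G-vectors: skipping residue(s) without base frame atoms: ",
            paste(res[missing], collapse = ", "))
  gam <- pi / gv$cutoff
  out <- numeric(4 * n * (n - 1))
  nms <- character(length(out))
  idx <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    nms[idx + 1:4] <- paste0("g", res[i], "_", res[j], "_", 1:4)
    if (!missing[i] && !missing[j]) {
      r <- as.vector(t(frames[[i]]$F) %*% (frames[[j]]$origin - frames[[i]]$origin))
      rs <- r / c(gv$scale_xy, gv$scale_xy, gv$scale_z)
      rho <- vnorm(rs)
      if (rho > 0 && rho < gv$cutoff) {
        out[idx + 1:4] <- c(sin(gam * rho) * rs / rho,
                            1 + cos(gam * rho)) / gam
      }
    }
    idx <- idx + 4L
  }
  names(out) <- nms
  out
}

# circular encoding of a torsion table: (sin, cos) of every angle column;
# NA torsions (chain termini) encode as (0, 0)
torsion_features <- function(torsions) {
  cols <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "chi",
            paste0("nu", 0:4))
  M <- as.matrix(torsions[, cols])
  S <- sin(M * DEG); C <- cos(M * DEG)
  S[is.na(S)] <- 0; C[is.na(C)] <- 0
  v <- c(t(cbind(S, C)))
  names(v) <- as.vector(t(outer(torsions$res, c(paste0("sin_", cols),
                                                paste0("cos_", cols)), paste0)))
  v
}

#' Feature matrix of an ensemble
#'
#' Concatenates the circular (sin, cos) encoding of all backbone, glycosidic
#' and ring torsions with the flattened G-vectors, one row per conformer.
#'
#' @param ensemble an `rna_ensemble`.
#' @param include any of "torsions", "gvectors".
#' @param config pipeline configuration.
#' @return numeric matrix n_conformers x n_features.
#' @export
feature_matrix <- function(ensemble, include = c("torsions", "gvectors"),
                           config = default_config()) {
  include <- match.arg(include, several.ok = TRUE)
  rows <- lapply(ensemble$conformers, function(cf) {
    v <- numeric(0)
    if ("torsions" %in% include)
      v <- c(v, torsion_features(compute_torsions(cf)))
    if ("gvectors" %in% include)
      v <- c(v, gvector_features(cf, config))
    v
  })
  X <- do.call(rbind, rows)
  if (any(!is.finite(X))) stop("non-finite features")
  X
}

#' Weighted principal component analysis
#'
#' Weighted mean-centering followed by the eigendecomposition of the weighted
#' Gram matrix (efficient when features outnumber conformers). Components are
#' orthonormal; explained-variance fractions sum to at most 1.
#'
#' @param X feature matrix (rows = conformers) or an `rna_ensemble` (which is
#'   featurized with [feature_matrix()] defaults).
#' @param weights observation weights (default uniform).
#' @param n_components number of components to return.
#' @param config pipeline configuration (used only when X is an ensemble).
#' @return list with `projections` (n x k), `components` (p x k, orthonormal
#'   columns), `explained_variance` (fractions, length k), `center`.
#' @export
pca_project <- function(X, weights = NULL, n_components = 2,
                        config = default_config()) {
  if (inherits(X, "rna_ensemble")) {
    weights <- if (is.null(weights)) X$weights else weights
    X <- feature_matrix(X, config = config)
  }
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 conformers")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  ctr <- as.vector(t(X) %*% w)
  Xc <- sweep(X, 2, ctr)
  Xw <- Xc * sqrt(w)
  G <- tcrossprod(Xw)
  eg <- eigen(G, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-12 & eg$values > 0
  if (!any(pos)) stop("zero-variance feature set")
  k <- min(n_components, sum(pos))
  vals <- eg$values[seq_len(k)]
  U <- eg$vectors[, seq_len(k), drop = FALSE]
  V <- crossprod(Xw, U) %*% diag(1 / sqrt(vals), k)
  # the Gram-matrix route loses orthogonality for near-degenerate
  # eigenvalues; polish with QR, keeping each component's orientation
  Q <- qr.Q(qr(V))
  sgn <- sign(colSums(Q * V))
  sgn[sgn == 0] <- 1
  V <- sweep(Q, 2, sgn, "*")
  list(projections = Xc %*% V,
       components = V,
       explained_variance = vals / sum(eg$values[pos]),
       center = ctr)
}
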