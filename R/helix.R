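# Base-pair detection and helical parameters (twist / kink).

# ring atoms used for plane fits and frames
base_ring_atoms <- function(code) {
  if (is_purine(code)) c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
  else c("N1", "C2", "N3", "C4", "C5", "C6")
}

# unit normal of a base plane by SVD; sign is arbitrary
.base_normal <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  svd(Xc)$v[, 3]
}

# donor hydrogen direction estimate (heavy atoms only): ring N-H points along
# the in-plane external bisector of its two ring neighbours; amino N-H2 gives
# two in-plane directions at +-60 degrees from the extended C-N bond.
.donor_neighbors <- list(
  N1 = c("C2", "C6"),  # purine ring NH
  N3 = c("C2", "C4"),  # pyrimidine ring NH
  N6 = "C6", N4 = "C4", N2 = "C2"
)

.donor_h_dirs <- function(donor_name, D, base_xyz, normal) {
  nb <- .donor_neighbors[[donor_name]]
  if (is.null(nb)) stop("no donor geometry known for atom ", donor_name)
  if (length(nb) == 2) {
    u <- unitv(base_xyz[nb[1], ] - D) + unitv(base_xyz[nb[2], ] - D)
    matrix(-unitv(u), nrow = 1)
  } else {
    v <- -unitv(base_xyz[nb, ] - D)
    rbind(as.vector(rotation_matrix(normal, 60) %*% v),
          as.vector(rotation_matrix(normal, -60) %*% v))
  }
}

#' Detect base pairs by hydrogen-bond geometry
#'
#' Evaluates every pair declared by the duplex specification against its
#' expected donor-acceptor pattern (Watson-Crick for A:U, G:C, I:C; wobble
#' for G:U and I:U). A pair is intact when every expected heavy-atom
#' donor-acceptor distance is at most `config$hbond$dist_cutoff` (default
#' 3.5 Angstrom) and the donor angle (180 degrees minus the deviation of the
#' estimated N-H vector from the donor-acceptor direction) is at least
#' `config$hbond$angle_min` (default 120 degrees); otherwise it is "open".
#'
#' @param conformer a `conformer`.
#' @param spec the [duplex_spec()] declaring the pairs.
#' @param config pipeline configuration.
#' @return a `base_pair_annotation`: data.frame with columns k, res_i, res_j,
#'   code_i, code_j, geometry ("WC"/"wobble"/"open") and hbond (logical).
#' @export
detect_base_pairs <- function(conformer, spec, config = default_config()) {
  config <- validate_config(config)
  conformer <- as_conformer(conformer)
  pr <- spec_pairs(spec)
  cutoff <- config$hbond$dist_cutoff
  amin <- config$hbond$angle_min
  geometry <- character(nrow(pr))
  hbond <- logical(nrow(pr))
  for (k in seq_len(nrow(pr))) {
    tpl <- pair_template(pr$code_i[k], pr$code_j[k])
    base_i <- .res_base_xyz(conformer, pr$res_i[k], pr$code_i[k])
    base_j <- .res_base_xyz(conformer, pr$res_j[k], pr$code_j[k])
    ok <- TRUE
    for (b in seq_along(tpl$bonds)) {
      a1 <- tpl$bonds[[b]][1]; a2 <- tpl$bonds[[b]][2]
      if (!(a1 %in% rownames(base_i)) || !(a2 %in% rownames(base_j))) {
        ok <- FALSE; break
      }
      p1 <- base_i[a1, ]; p2 <- base_j[a2, ]
      d <- vnorm(p1 - p2)
      if (!is.finite(d) || d > cutoff) { ok <- FALSE; break }
      if (tpl$donors[b] == 1L) {
        donor <- a1; D <- p1; A <- p2; bx <- base_i
      } else {
        donor <- a2; D <- p2; A <- p1; bx <- base_j
      }
      nrm <- .base_normal(bx[intersect(rownames(bx), base_ring_atoms("G")), ,
                              drop = FALSE])
      hdirs <- .donor_h_dirs(donor, D, bx, nrm)
      dev <- min(apply(hdirs, 1, function(h) bond_angle(D + h, D, A)))
      if (180 - dev < amin) { ok <- FALSE; break }
    }
    hbond[k] <- ok
    geometry[k] <- if (ok) tpl$geometry else "open"
  }
  out <- data.frame(k = pr$k, res_i = pr$res_i, res_j = pr$res_j,
                    code_i = pr$code_i, code_j = pr$code_j,
                    geometry = geometry, hbond = hbond)
  class(out) <- c("base_pair_annotation", "data.frame")
  out
}

.res_base_xyz <- function(conformer, res, code) {
  at <- conformer$atoms
  want <- c(base_ring_atoms(code),
            setdiff(rownames(base_template(code)), "C1'"))
  sel <- at$res == res & at$atom %in% want
  X <- as.matrix(at[sel, c("x", "y", "z")])
  rownames(X) <- at$atom[sel]
  X
}

# Base-pair reference frame: origin at the C1'-C1' midpoint, y along
# C1'(strand 2) -> C1'(strand 1), z the mean base normal (strand-2 normal
# flipped for consistency), x = y cross z; columns of the returned matrix
# are x, y, z.
.pair_frame <- function(conformer, res_i, res_j, code_i, code_j) {
  c1i <- atom_xyz(conformer, res_i, "C1'")
  c1j <- atom_xyz(conformer, res_j, "C1'")
  if (is.null(c1i) || is.null(c1j)) return(NULL)
  bi <- .res_base_xyz(conformer, res_i, code_i)
  bj <- .res_base_xyz(conformer, res_j, code_j)
  ni <- .base_normal(bi[intersect(rownames(bi), base_ring_atoms(code_i)), ])
  nj <- .base_normal(bj[intersect(rownames(bj), base_ring_atoms(code_j)), ])
  if (sum(ni * nj) < 0) nj <- -nj
  z0 <- unitv(ni + nj)
  y <- unitv(c1i - c1j)
  z <- unitv(z0 - sum(z0 * y) * y)
  x <- pracma_cross(y, z)
  list(origin = (c1i + c1j) / 2, F = cbind(x, y, z))
}

# Orient all frames consistently: the SVD base normal has an arbitrary sign,
# so z is flipped (and x = y cross z recomputed, keeping the deterministic
# C1'-C1' y convention) wherever successive normals anti-align, and the
# whole set is anchored so that z points along the rise direction. This
# makes the twist of a right-handed helix positive.
.pair_frames <- function(conformer, pairs) {
  frames <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    frames[[k]] <- .pair_frame(conformer, pairs$res_i[k], pairs$res_j[k],
                               pairs$code_i[k], pairs$code_j[k])
  }
  flip_z <- function(f) {
    f$F[, 3] <- -f$F[, 3]
    f$F[, 1] <- pracma_cross(f$F[, 2], f$F[, 3])
    f
  }
  have <- which(!vapply(frames, is.null, logical(1)))
  for (i in seq_along(have)[-1]) {
    k <- have[i]; kp <- have[i - 1]
    if (sum(frames[[k]]$F[, 3] * frames[[kp]]$F[, 3]) < 0)
      frames[[k]] <- flip_z(frames[[k]])
  }
  if (length(have) >= 2) {
    rise_dir <- frames[[have[length(have)]]]$origin - frames[[have[1]]]$origin
    zmean <- Reduce(`+`, lapply(have, function(k) frames[[k]]$F[, 3]))
    if (sum(zmean * rise_dir) < 0)
      for (k in have) frames[[k]] <- flip_z(frames[[k]])
  }
  frames
}

# rotation angle and axis of the relative rotation between two frames
.step_rotation <- function(F1, F2) {
  R <- F2 %*% t(F1)
  ct <- (sum(diag(R)) - 1) / 2
  ang <- acos(max(-1, min(1, ct))) / DEG
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (vnorm(ax) < 1e-9) ax <- F1[, 3] else ax <- unitv(ax)
  zm <- unitv(F1[, 3] + F2[, 3])
  if (sum(ax * zm) < 0) { ax <- -ax; ang <- -ang }
  list(angle = ang, axis = ax)
}

#' Helical twist and kink of a duplex conformer
#'
#' Builds a reference frame for every intact base pair (C1'-C1' long axis and
#' mean base normal) and reports, per step between consecutive intact pairs,
#' the helical twist: the rotation angle of the relative rotation between the
#' two frames, signed along the mean normal. The kink is the angle between
#' the helix axes of the two flanking stems, each axis estimated as the mean
#' per-step rotation axis within the stem.
#'
#' @param conformer a `conformer`.
#' @param pairs a `base_pair_annotation` from [detect_base_pairs()].
#' @param stem_split list of two integer vectors of pair indices (k) defining
#'   the flanking stems; default: pairs before/after the central step among
#'   intact pairs.
#' @return an object of class `helix_params`: list with `twist` (data.frame
#'   of per-step values), `mean_twist`, and `kink` (degrees, NA when a stem
#'   has fewer than two intact pairs).
#' @export
helical_parameters <- function(conformer, pairs, stem_split = NULL) {
  conformer <- as_conformer(conformer)
  stopifnot(inherits(pairs, "base_pair_annotation"))
  frames <- .pair_frames(conformer, pairs)
  intact <- which(pairs$geometry != "open" &
                    !vapply(frames, is.null, logical(1)))
  n <- nrow(pairs)
  if (is.null(stem_split)) {
    half <- floor(n / 2)
    stem_split <- list(seq_len(half), seq(half + 1, n))
  }
  steps <- data.frame(k1 = integer(), k2 = integer(), twist = numeric())
  axes <- list()
  for (i in seq_along(intact)[-1]) {
    k1 <- intact[i - 1]; k2 <- intact[i]
    if (k2 != k1 + 1) next  # twist defined only for consecutive intact pairs
    sr <- .step_rotation(frames[[k1]]$F, frames[[k2]]$F)
    steps <- rbind(steps, data.frame(k1 = k1, k2 = k2, twist = sr$angle))
    axes[[length(axes) + 1]] <- list(k = k1, axis = sr$axis)
  }
  stem_axis <- function(ks) {
    use <- Filter(function(a) (a$k %in% ks) && ((a$k + 1) %in% ks), axes)
    if (length(use) < 1) return(NULL)
    unitv(Reduce(`+`, lapply(use, function(a) a$axis)))
  }
  a1 <- stem_axis(stem_split[[1]])
  a2 <- stem_axis(stem_split[[2]])
  kink <- if (is.null(a1) || is.null(a2)) NA_real_ else
    acos(max(-1, min(1, sum(a1 * a2)))) / DEG
  structure(list(
    twist = steps,
    mean_twist = if (nrow(steps)) mean(steps$twist) else NA_real_,
    kink = kink
  ), class = "helix_params")
}

#' @export
print.helix_params <- function(x, ...) {
  cat(sprintf("helix_params: mean twist %.2f deg over %d steps, kink %s\n",
              x$mean_twist, nrow(x$twist),
              if (is.na(x$kink)) "undefined" else sprintf("%.2f deg", x$kink)))
  invisible(x)
}
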