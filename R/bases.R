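# Idealized planar base geometries in the standard base reference frame
# (origin and axes of the standard nucleobase frame used by helical-parameter
# software; x toward the major groove, y along the C1'-C1' long axis, z the
# base normal). In this frame a Watson-Crick partner is generated by the
# dyad flip (x, -y, -z). Coordinates include the glycosidic C1' anchor.
#
# Hypoxanthine (inosine's base, code "I") is guanine without the exocyclic
# N2 amine, which is why I:U adopts a G:U-like wobble geometry.

.base_xy <- function(code) {
  switch(code,
    A = rbind(
      N9 = c(-1.291, 4.498), C8 = c(0.024, 4.897), N7 = c(0.877, 3.902),
      C5 = c(0.071, 2.771), C6 = c(0.369, 1.398), N6 = c(1.611, 0.909),
      N1 = c(-0.668, 0.532), C2 = c(-1.912, 1.023), N3 = c(-2.320, 2.290),
      C4 = c(-1.267, 3.124), `C1'` = c(-2.479, 5.346)),
    G = rbind(
      N9 = c(-1.289, 4.551), C8 = c(0.023, 4.962), N7 = c(0.870, 3.969),
      C5 = c(0.071, 2.833), C6 = c(0.424, 1.460), O6 = c(1.554, 0.955),
      N1 = c(-0.700, 0.641), C2 = c(-1.999, 1.087), N2 = c(-2.949, 0.139),
      N3 = c(-2.342, 2.364), C4 = c(-1.265, 3.177), `C1'` = c(-2.477, 5.399)),
    I = rbind(
      N9 = c(-1.289, 4.551), C8 = c(0.023, 4.962), N7 = c(0.870, 3.969),
      C5 = c(0.071, 2.833), C6 = c(0.424, 1.460), O6 = c(1.554, 0.955),
      N1 = c(-0.700, 0.641), C2 = c(-1.999, 1.087),
      N3 = c(-2.342, 2.364), C4 = c(-1.265, 3.177), `C1'` = c(-2.477, 5.399)),
    C = rbind(
      N1 = c(-1.285, 4.542), C2 = c(-1.472, 3.158), O2 = c(-2.628, 2.709),
      N3 = c(-0.391, 2.344), C4 = c(0.837, 2.868), N4 = c(1.875, 2.027),
      C5 = c(1.056, 4.275), C6 = c(-0.023, 5.068), `C1'` = c(-2.477, 5.402)),
    U = rbind(
      N1 = c(-1.284, 4.500), C2 = c(-1.462, 3.131), O2 = c(-2.563, 2.608),
      N3 = c(-0.302, 2.397), C4 = c(0.989, 2.884), O4 = c(1.935, 2.094),
      C5 = c(1.089, 4.311), C6 = c(-0.024, 5.053), `C1'` = c(-2.481, 5.354)),
    stop("unknown residue code: ", code)
  )
}

base_template <- function(code) {
  xy <- .base_xy(code)
  cbind(xy, z = 0)
}

is_purine <- function(code) code %in% c("A", "G", "I")

glyco_atom <- function(code) if (is_purine(code)) "N9" else "N1"

chi_ref_atom <- function(code) if (is_purine(code)) "C4" else "C2"

# Hydrogen-bond donor/acceptor patterns per pair type, as (atom on the
# purine-like or first-listed base, atom on the partner). Wobble pairs share
# the two-bond G:U pattern; hypoxanthine lacks N2 so I:C has two bonds.
.pair_patterns <- list(
  "A:U" = list(geometry = "WC",
               bonds = list(c("N1", "N3"), c("N6", "O4")),
               donors = c(2L, 1L)), # which side donates: 1 = first base
  "G:C" = list(geometry = "WC",
               bonds = list(c("N1", "N3"), c("N2", "O2"), c("O6", "N4")),
               donors = c(1L, 1L, 2L)),
  "I:C" = list(geometry = "WC",
               bonds = list(c("N1", "N3"), c("O6", "N4")),
               donors = c(1L, 2L)),
  "G:U" = list(geometry = "wobble",
               bonds = list(c("N1", "O2"), c("O6", "N3")),
               donors = c(1L, 2L)),
  "I:U" = list(geometry = "wobble",
               bonds = list(c("N1", "O2"), c("O6", "N3")),
               donors = c(1L, 2L))
)

# Canonicalize a pair: returns list(key, swapped) where `key` indexes
# .pair_patterns and swapped = TRUE when code1 is the second-listed base.
pair_key <- function(code1, code2) {
  k1 <- paste(code1, code2, sep = ":")
  k2 <- paste(code2, code1, sep = ":")
  if (k1 %in% names(.pair_patterns)) return(list(key = k1, swapped = FALSE))
  if (k2 %in% names(.pair_patterns)) return(list(key = k2, swapped = TRUE))
  stop("unsupported base pair: ", code1, ":", code2,
       " (allowed: A:U, G:C, G:U, I:U, I:C)")
}

# Cache for lazily computed wobble placements and pair templates.
.rnaens_cache <- new.env(parent = emptyenv())

# In-plane rigid transform (2D rotation by theta degrees about the origin,
# then translation) applied to an n x 3 planar coordinate set.
.plane_transform <- function(X, tx, ty, theta) {
  th <- theta * DEG
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, byrow = TRUE)
  Xy <- X[, 1:2, drop = FALSE] %*% t(R)
  cbind(Xy[, 1] + tx, Xy[, 2] + ty, X[, 3])
}

# Wobble displacement of the pyrimidine relative to the Watson-Crick flip
# position: solved once per pair type by matching the two wobble hydrogen
# bonds to 2.85 A while keeping the C1'-C1' distance near 10.3 A.
.wobble_shift <- function(key) {
  cached <- .rnaens_cache[[paste0("wobble_", key)]]
  if (!is.null(cached)) return(cached)
  codes <- strsplit(key, ":", fixed = TRUE)[[1]]
  pur <- base_template(codes[1])
  pyr0 <- base_template(codes[2])
  flip <- cbind(pyr0[, 1], -pyr0[, 2], -pyr0[, 3])
  rownames(flip) <- rownames(pyr0)
  obj <- function(p) {
    pyr <- .plane_transform(flip, p[1], p[2], p[3])
    rownames(pyr) <- rownames(flip)
    d1 <- vnorm(pur["N1", ] - pyr["O2", ])
    d2 <- vnorm(pur["O6", ] - pyr["N3", ])
    dc <- vnorm(pur["C1'", ] - pyr["C1'", ])
    (d1 - 2.85)^2 + (d2 - 2.85)^2 + 0.05 * (dc - 10.3)^2
  }
  fit <- stats::optim(c(0, 0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  .rnaens_cache[[paste0("wobble_", key)]] <- fit$par
  fit$par
}

# Rigid transforms as list(R = 3x3, t = length-3); composition and action.
rigid <- function(R = diag(3), t = c(0, 0, 0)) list(R = R, t = t)

rigid_apply <- function(tr, X) {
  if (is.null(dim(X))) return(as.vector(tr$R %*% X) + tr$t)
  Y <- sweep(X %*% t(tr$R), 2, tr$t, "+")
  rownames(Y) <- rownames(X)
  Y
}

# tr2 after tr1:  x -> tr2(tr1(x))
rigid_compose <- function(tr2, tr1) {
  rigid(R = tr2$R %*% tr1$R, t = as.vector(tr2$R %*% tr1$t) + tr2$t)
}

.flip_x <- function() rigid(R = diag(c(1, -1, -1)))

.rigid_plane <- function(tx, ty, theta) {
  th <- theta * DEG
  R <- diag(3)
  R[1:2, 1:2] <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, byrow = TRUE)
  rigid(R = R, t = c(tx, ty, 0))
}

# Base-pair template: rigid transforms taking each base's standard frame
# into the pair reference frame (pair plane z = 0, long axis y; strand 1
# base stays near its standard orientation), plus transformed base atoms
# and the hydrogen-bond pattern (bonds reported as strand1-atom,
# strand2-atom with donor side 1 or 2).
pair_template <- function(code1, code2) {
  ck <- paste0("pair_", code1, "_", code2)
  cached <- .rnaens_cache[[ck]]
  if (!is.null(cached)) return(cached)
  pk <- pair_key(code1, code2)
  pat <- .pair_patterns[[pk$key]]
  T_first <- rigid()
  T_second <- .flip_x()
  if (pat$geometry == "wobble") {
    p <- .wobble_shift(pk$key)
    T_second <- rigid_compose(.rigid_plane(p[1], p[2], p[3]), T_second)
  }
  if (pk$swapped) {
    # flip the whole pair about the x axis so strand 1 carries code1
    T1 <- rigid_compose(.flip_x(), T_second)
    T2 <- rigid_compose(.flip_x(), T_first)
    bonds <- lapply(pat$bonds, rev)
    donors <- 3L - pat$donors
  } else {
    T1 <- T_first
    T2 <- T_second
    bonds <- pat$bonds
    donors <- pat$donors
  }
  out <- list(
    T1 = T1, T2 = T2,
    base1 = rigid_apply(T1, base_template(code1)),
    base2 = rigid_apply(T2, base_template(code2)),
    geometry = pat$geometry, bonds = bonds, donors = donors
  )
  .rnaens_cache[[ck]] <- out
  out
}
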