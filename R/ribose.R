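# Parametric ribose construction. The five-membered ring is generated by a
# Cremer-Pople-style embedding (atoms on a circle with out-of-plane
# displacements z_m proportional to q cos(phi + 4 pi m / 5)) whose two
# parameters (q, phi) are calibrated numerically so that the Altona-
# Sundaralingam analysis of the resulting ring torsions reproduces the
# requested phase P and amplitude numax. This guarantees the build -> measure
# round trip by construction.

# Ring walk order and approximate bond length of the furanose ring.
.ring_atoms <- c("O4'", "C1'", "C2'", "C3'", "C4'")

.ring_embed <- function(q, phi, r0 = 1.24, handed = -1) {
  m <- 0:4
  theta <- handed * 2 * pi * m / 5
  z <- sqrt(2 / 5) * q * cos(phi * DEG + 4 * pi * m / 5)
  X <- cbind(r0 * cos(theta), r0 * sin(theta), z)
  rownames(X) <- .ring_atoms
  X
}

.ring_nu <- function(X) {
  idx <- list(c(5, 1, 2, 3), c(1, 2, 3, 4), c(2, 3, 4, 5),
              c(3, 4, 5, 1), c(4, 5, 1, 2))
  vapply(idx, function(i) dihedral_angle(X[i[1], ], X[i[2], ], X[i[3], ], X[i[4], ]),
         numeric(1))
}

# Calibrated rigid ring template for a target (P, numax); cached.
ring_template <- function(P, numax) {
  key <- sprintf("ring_%.6f_%.6f", P, numax)
  cached <- .rnaens_cache[[key]]
  if (!is.null(cached)) return(cached)
  target <- c(P, numax)
  obj <- function(par) {
    X <- .ring_embed(exp(par[1]), par[2])
    nu <- .ring_nu(X)
    if (any(!is.finite(nu)) || all(abs(nu) < 1e-9)) return(1e6)
    ps <- pseudorotation(nu)
    dp <- wrap_angle(ps$P - target[1])
    (dp * target[2] / 60)^2 + (ps$numax - target[2])^2
  }
  best <- NULL
  for (phi0 in c(P, P + 90, P + 180, P + 270)) {
    fit <- stats::optim(c(log(numax / 100), phi0), obj, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-15))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (best$value > 1e-8)
    stop(sprintf("ring calibration failed for P=%g, numax=%g", P, numax))
  X <- .ring_embed(exp(best$par[1]), best$par[2])
  .rnaens_cache[[key]] <- X
  X
}

# Bond lengths / angles used by the nucleotide builder (Angstrom / degrees).
.nt_geom <- list(
  c1_o4 = 1.414, c1_c2 = 1.526, c1_n = 1.48,
  ang_n_c1_o4 = 108.2, ang_n_c1_c2 = 113.3,
  o2 = 1.413, o3 = 1.423, c5 = 1.510, h = 1.09,
  o5 = 1.440, ang_c4_c5_o5 = 110.2,
  p = 1.593, ang_c5_o5_p = 120.9,
  op = 1.485, ang_o5_p_op = 108.1
)

# Chirality signs frozen for beta-D-ribose; verified by the delta-torsion and
# J-coupling behaviour of the built nucleotides (see tests).
.nt_chir <- list(azimuth = +1, o3 = 1L, c5 = 2L)

# Build one nucleotide (base + ribose + backbone heavy atoms + H1'/H2') in
# the standard base reference frame. `pucker` is c(P, numax) in degrees.
build_nucleotide <- function(code, pucker = c(18, 38), chi = -158,
                             gamma = 54, beta = 180, with_phosphate = TRUE) {
  key <- sprintf("nt_%s_%.4f_%.4f_%.2f_%.2f_%.2f_%d", code, pucker[1],
                 pucker[2], chi, gamma, beta, with_phosphate)
  cached <- .rnaens_cache[[key]]
  if (!is.null(cached)) return(cached)
  g <- .nt_geom
  base <- base_template(code)
  N <- base[glyco_atom(code), ]
  Cref <- base[chi_ref_atom(code), ]
  C1 <- base["C1'", ]
  ring <- ring_template(pucker[1], pucker[2])

  # anchor targets for O4' and C2' around the C1'-N axis
  O4t <- place_atom(Cref, N, C1, g$c1_o4, g$ang_n_c1_o4, chi)
  ang_ring <- bond_angle(ring["O4'", ], ring["C1'", ], ring["C2'", ])
  th1 <- g$ang_n_c1_o4 * DEG
  th2 <- g$ang_n_c1_c2 * DEG
  cosdphi <- (cos(ang_ring * DEG) - cos(th1) * cos(th2)) / (sin(th1) * sin(th2))
  dphi <- acos(max(-1, min(1, cosdphi))) / DEG
  C2t <- place_atom(Cref, N, C1, vnorm(ring["C2'", ] - ring["C1'", ]),
                    g$ang_n_c1_c2, chi + .nt_chir$azimuth * dphi)
  # rigid fit of the calibrated ring onto the three anchors (exact: the
  # anchor triangle was generated with the ring's own internal geometry,
  # rescaled to the builder's C1'-O4' bond length)
  ringP <- ring * (g$c1_o4 / vnorm(ring["O4'", ] - ring["C1'", ]))
  fit <- kabsch(ringP[c("C1'", "O4'", "C2'"), ], rbind(C1, O4t, C2t))
  ringG <- apply_rigid(ringP, fit$R, fit$t)
  C1p <- ringG["C1'", ]; C2p <- ringG["C2'", ]; C3p <- ringG["C3'", ]
  C4p <- ringG["C4'", ]; O4p <- ringG["O4'", ]

  H1 <- C1p + g$h * tetra_fourth(O4p - C1p, C2p - C1p, N - C1p)
  # H2' is positioned so that the H1'-C1'-C2'-H2' torsion obeys the standard
  # Altona projection phi = 121.4 + 1.03 * nu1 (the convention used to relate
  # ring pucker to the experimentally interpreted coupling dihedral); O2'
  # then takes the tetrahedral direction away from H2'.
  nu1 <- dihedral_angle(O4p, C1p, C2p, C3p)
  phi_target <- 121.4 + 1.03 * nu1
  H2 <- place_atom(H1, C1p, C2p, g$h, 110.5, phi_target)
  tp2 <- tetra_pair(unitv(C1p - C2p), unitv(C3p - C2p))
  o2_side <- which.max(c(vnorm(C2p + tp2[1, ] - H2), vnorm(C2p + tp2[2, ] - H2)))
  O2p <- C2p + g$o2 * tp2[o2_side, ]
  tp3 <- tetra_pair(unitv(C2p - C3p), unitv(C4p - C3p))
  O3p <- C3p + g$o3 * tp3[.nt_chir$o3, ]
  tp4 <- tetra_pair(unitv(C3p - C4p), unitv(O4p - C4p))
  C5p <- C4p + g$c5 * tp4[.nt_chir$c5, ]
  O5p <- place_atom(C3p, C4p, C5p, g$o5, g$ang_c4_c5_o5, gamma)

  atoms <- rbind(
    `O5'` = O5p, `C5'` = C5p, `C4'` = C4p, `O4'` = O4p, `C3'` = C3p,
    `O3'` = O3p, `C2'` = C2p, `O2'` = O2p, `C1'` = C1p
  )
  if (with_phosphate) {
    Pp <- place_atom(C4p, C5p, O5p, g$p, g$ang_c5_o5_p, beta)
    OP1 <- place_atom(C5p, O5p, Pp, g$op, g$ang_o5_p_op, 51)
    OP2 <- place_atom(C5p, O5p, Pp, g$op, g$ang_o5_p_op, -173)
    atoms <- rbind(P = Pp, OP1 = OP1, OP2 = OP2, atoms)
  }
  atoms <- rbind(atoms, base, `H1'` = H1, `H2'` = H2)
  # base_template already carries C1'; drop the duplicate, keep the ribose one
  atoms <- atoms[!duplicated(rownames(atoms)), , drop = FALSE]
  .rnaens_cache[[key]] <- atoms
  atoms
}

#' Build a single parametric ribose (nucleoside) from pseudorotation values
#'
#' Constructs one nucleotide with the requested sugar pucker, including the
#' H1' and H2' protons needed for the 3J(H1',H2') scalar coupling. Used to
#' reproduce the canonical Karplus limits: a C3'-endo ribose gives a coupling
#' below 1 Hz, a C2'-endo ribose above 10 Hz.
#'
#' @param P pseudorotation phase in degrees.
#' @param numax puckering amplitude in degrees.
#' @param code residue code (A, C, G, U or I) providing the base.
#' @param config pipeline configuration; supplies the glycosidic torsion.
#' @return a `conformer` with one residue.
#' @export
build_ribose <- function(P, numax, code = "U", config = default_config()) {
  config <- validate_config(config)
  atoms <- build_nucleotide(code, pucker = c(P, numax),
                            chi = config$backbone$chi,
                            gamma = config$backbone$gamma,
                            beta = config$backbone$beta,
                            with_phosphate = FALSE)
  new_conformer(data.frame(
    res = 1L, resname = code, atom = rownames(atoms),
    x = atoms[, 1], y = atoms[, 2], z = atoms[, 3],
    strand = 1L, row.names = NULL
  ))
}
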