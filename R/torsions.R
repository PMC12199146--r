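# Sugar pseudorotation and backbone torsion extraction.

#' Pseudorotation phase and amplitude from ring torsions
#'
#' Altona-Sundaralingam analysis of the five endocyclic ribose torsions
#' nu0..nu4, with nu2 as the reference torsion:
#' tan(P) = ((nu4 + nu1) - (nu3 + nu0)) / (2 nu2 (sin 36 + sin 72)),
#' numax = nu2 / cos(P). The pucker class is assigned from configured phase
#' boundaries (defaults: C3'-endo for P in [0, 36] degrees, C2'-endo for
#' P in [144, 180] degrees, otherwise "other").
#'
#' @param nu numeric length-5 vector of ring torsions nu0..nu4 in degrees.
#' @param config pipeline configuration (see [default_config()]).
#' @return an object of class `pucker_state`: list with `P` (degrees, in
#'   [0, 360)), `numax` (degrees, > 0) and `klass`.
#' @export
pseudorotation <- function(nu, config = default_config()) {
  config <- validate_config(config)
  if (length(nu) != 5 || any(!is.finite(nu)))
    stop("nu must be five finite ring torsions (degrees)")
  if (all(abs(nu) < 1e-9))
    stop("flat ring: pseudorotation amplitude undefined")
  denom_const <- 2 * (sin(36 * DEG) + sin(72 * DEG))
  y <- (nu[5] + nu[2]) - (nu[4] + nu[1])
  x <- nu[3] * denom_const
  P <- atan2(y, x) / DEG
  P <- P %% 360
  numax <- if (abs(cos(P * DEG)) > 1e-8) {
    nu[3] / cos(P * DEG)
  } else {
    y / denom_const
  }
  if (numax < 0) {
    # amplitude is positive by convention; fold the phase
    numax <- -numax
    P <- (P + 180) %% 360
  }
  klass <- pucker_class(P, config)
  structure(list(P = P, numax = numax, klass = klass), class = "pucker_state")
}

pucker_class <- function(P, config = default_config()) {
  b <- config$pucker
  if (P >= b$c3_range[1] && P <= b$c3_range[2]) "C3-endo"
  else if (P >= b$c2_range[1] && P <= b$c2_range[2]) "C2-endo"
  else "other"
}

#' Ring torsions from pseudorotation parameters
#'
#' Inverse of [pseudorotation()]: nu_j = numax * cos(P + 144 (j - 2)) for
#' j = 0..4 (degrees).
#'
#' @param P pseudorotation phase in degrees.
#' @param numax puckering amplitude in degrees (> 0).
#' @return numeric length-5 vector nu0..nu4.
#' @export
nu_from_pseudorotation <- function(P, numax) {
  stopifnot(is.finite(P), is.finite(numax), numax > 0)
  j <- 0:4
  numax * cos((P + 144 * (j - 2)) * DEG)
}

#' @export
print.pucker_state <- function(x, ...) {
  cat(sprintf("pucker_state: P = %.2f deg, numax = %.2f deg, class = %s\n",
              x$P, x$numax, x$klass))
  invisible(x)
}

# IUPAC torsion atom quadruples. alpha/zeta/epsilon span residue boundaries
# within a strand; chi uses N9/C4 for purines and N1/C2 for pyrimidines.
.nu_quads <- list(
  nu0 = c("C4'", "O4'", "C1'", "C2'"),
  nu1 = c("O4'", "C1'", "C2'", "C3'"),
  nu2 = c("C1'", "C2'", "C3'", "C4'"),
  nu3 = c("C2'", "C3'", "C4'", "O4'"),
  nu4 = c("C3'", "C4'", "O4'", "C1'")
)

#' Backbone, glycosidic and ring torsions of a conformer
#'
#' Computes the IUPAC backbone angles alpha, beta, gamma, delta, epsilon,
#' zeta, the glycosidic angle chi and the ring torsions nu0..nu4 for every
#' residue. Angles are reported in degrees wrapped to (-180, 180]. Torsions
#' whose atoms are missing (chain termini, incomplete residues) or whose
#' geometry is degenerate are NA rather than an error.
#'
#' @param conformer a `conformer` object (see [build_ideal_duplex()]).
#' @return an object of class `torsion_set`: a data.frame with one row per
#'   residue and columns res, resname, strand, alpha..chi, nu0..nu4.
#' @export
compute_torsions <- function(conformer) {
  conformer <- as_conformer(conformer)
  at <- conformer$atoms
  res_tab <- unique(at[, c("res", "resname", "strand")])
  res_tab <- res_tab[order(res_tab$res), ]
  coord <- function(res, name) {
    i <- which(at$res == res & at$atom == name)
    if (length(i) != 1) return(NULL)
    c(at$x[i], at$y[i], at$z[i])
  }
  tors4 <- function(ps) {
    if (any(vapply(ps, is.null, logical(1)))) return(NA_real_)
    dihedral_angle(ps[[1]], ps[[2]], ps[[3]], ps[[4]])
  }
  n <- nrow(res_tab)
  out <- data.frame(res = res_tab$res, resname = res_tab$resname,
                    strand = res_tab$strand)
  cols <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "chi",
            names(.nu_quads))
  for (cc in cols) out[[cc]] <- NA_real_
  # strand-wise previous/next residue numbers (5'->3' order within strand)
  for (k in seq_len(n)) {
    r <- res_tab$res[k]
    strand <- res_tab$strand[k]
    in_strand <- res_tab$res[res_tab$strand == strand]
    prev <- if ((r - 1) %in% in_strand) r - 1 else NA
    nxt <- if ((r + 1) %in% in_strand) r + 1 else NA
    code <- res_tab$resname[k]
    out$alpha[k] <- if (!is.na(prev)) tors4(list(
      coord(prev, "O3'"), coord(r, "P"), coord(r, "O5'"), coord(r, "C5'"))) else NA
    out$beta[k] <- tors4(list(
      coord(r, "P"), coord(r, "O5'"), coord(r, "C5'"), coord(r, "C4'")))
    out$gamma[k] <- tors4(list(
      coord(r, "O5'"), coord(r, "C5'"), coord(r, "C4'"), coord(r, "C3'")))
    out$delta[k] <- tors4(list(
      coord(r, "C5'"), coord(r, "C4'"), coord(r, "C3'"), coord(r, "O3'")))
    out$epsilon[k] <- if (!is.na(nxt)) tors4(list(
      coord(r, "C4'"), coord(r, "C3'"), coord(r, "O3'"), coord(nxt, "P"))) else NA
    out$zeta[k] <- if (!is.na(nxt)) tors4(list(
      coord(r, "C3'"), coord(r, "O3'"), coord(nxt, "P"), coord(nxt, "O5'"))) else NA
    out$chi[k] <- tors4(list(
      coord(r, "O4'"), coord(r, "C1'"),
      coord(r, glyco_atom(code)), coord(r, chi_ref_atom(code))))
    for (nm in names(.nu_quads)) {
      q <- .nu_quads[[nm]]
      out[[nm]][k] <- tors4(list(coord(r, q[1]), coord(r, q[2]),
                                 coord(r, q[3]), coord(r, q[4])))
    }
  }
  class(out) <- c("torsion_set", "data.frame")
  out
}
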