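# Duplex specification and the idealized coordinate builder.

.allowed_pairs <- c("A:U", "U:A", "G:C", "C:G", "G:U", "U:G",
                    "I:U", "U:I", "I:C", "C:I")

#' Specify an antiparallel RNA duplex
#'
#' Both strands are written 5'->3'; residue i of strand 1 pairs with residue
#' n - i + 1 of strand 2. Residues are numbered consecutively: strand 1 from
#' `start1`, strand 2 from `start2` (defaults 1 and n + 1, i.e. a 20-bp
#' duplex is numbered 1..40 and the central pairs read e.g. 8:33, 9:32, ...).
#' Allowed pairs are A:U, G:C, G:U, I:U and I:C (inosine codes as "I").
#'
#' @param strand1,strand2 residue-code strings over A, C, G, U, I.
#' @param start1,start2 first residue number of each strand.
#' @return an object of class `duplex_spec`.
#' @export
duplex_spec <- function(strand1, strand2, start1 = 1L, start2 = NULL) {
  s1 <- strsplit(toupper(strand1), "")[[1]]
  s2 <- strsplit(toupper(strand2), "")[[1]]
  if (length(s1) != length(s2))
    stop("strands must have equal lengths (got ", length(s1), " and ",
         length(s2), ")")
  if (length(s1) < 1) stop("empty duplex")
  bad <- setdiff(unique(c(s1, s2)), c("A", "C", "G", "U", "I"))
  if (length(bad)) stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  n <- length(s1)
  partner <- s2[n:1]
  pairs <- paste(s1, partner, sep = ":")
  bad_pairs <- which(!pairs %in% .allowed_pairs)
  if (length(bad_pairs))
    stop("unsupported base pair(s) at position(s) ",
         paste(bad_pairs, collapse = ", "), ": ",
         paste(unique(pairs[bad_pairs]), collapse = ", "))
  if (is.null(start2)) start2 <- start1 + n
  structure(list(
    strand1 = s1, strand2 = s2, n = n,
    start1 = as.integer(start1), start2 = as.integer(start2),
    res1 = as.integer(start1 + seq_len(n) - 1),
    res2 = as.integer(start2 + seq_len(n) - 1)
  ), class = "duplex_spec")
}

#' @export
print.duplex_spec <- function(x, ...) {
  cat(sprintf("duplex_spec: %d bp\n", x$n))
  cat(" 5'-", paste(x$strand1, collapse = ""), "-3'  (", x$res1[1], "..",
      x$res1[x$n], ")\n", sep = "")
  cat(" 3'-", paste(rev(x$strand2), collapse = ""), "-5'  (", x$res2[x$n],
      "..", x$res2[1], ")\n", sep = "")
  invisible(x)
}

# residue numbers paired in a spec: pair k is (res1[k], res2[n - k + 1])
spec_pairs <- function(spec) {
  n <- spec$n
  data.frame(
    k = seq_len(n),
    res_i = spec$res1,
    res_j = spec$res2[n:1],
    code_i = spec$strand1,
    code_j = spec$strand2[n:1]
  )
}

#' Bundled 20-bp model duplexes
#'
#' Returns the duplex specification of the 20-bp model systems: the
#' hyper-edited duplex ("I") carries the central motif A8:U33, I9:U32,
#' I10:U31, U11:I30, I12:U29, C13:G28; the unedited control ("A") replaces
#' every inosine by adenosine. Only the central motif is prescribed by the
#' model system; the flanking stem sequences here are synthetic stand-ins
#' (GC-rich A-form-compatible flanks) and are configurable via `flank5` /
#' `flank3`.
#'
#' @param type "I" (hyper-edited) or "A" (unedited control).
#' @param flank5,flank3 seven-residue flank sequences of strand 1 (5' and 3'
#'   of the central motif).
#' @return a [duplex_spec()] numbered 1..20 / 21..40.
#' @export
example_duplex <- function(type = c("I", "A"), flank5 = "GGCAGCA",
                           flank3 = "GAGCUCC") {
  type <- match.arg(type)
  if (nchar(flank5) != 7 || nchar(flank3) != 7)
    stop("flanks must be 7 residues each (20-bp duplex with a 6-bp motif)")
  motif1 <- if (type == "I") "AIIUIC" else "AAAUAC"
  s1 <- paste0(flank5, motif1, flank3)
  comp <- c(A = "U", U = "A", G = "C", C = "G", I = "U")
  s1v <- strsplit(s1, "")[[1]]
  partner <- comp[s1v]
  if (type == "I") partner[11] <- "I"   # U11 pairs I30
  s2 <- paste(rev(partner), collapse = "")
  duplex_spec(s1, s2)
}

# ---- conformer ----------------------------------------------------------

# Heavy-atom complement required per residue code (plus H1'/H2'); the
# 5'-terminal residue of each strand may lack P/OP1/OP2.
.sugar_atoms <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'",
                  "O3'", "C2'", "O2'", "C1'")

required_atoms <- function(code, terminal5 = FALSE) {
  sug <- if (terminal5) setdiff(.sugar_atoms, c("P", "OP1", "OP2")) else .sugar_atoms
  c(sug, rownames(base_template(code))[rownames(base_template(code)) != "C1'"],
    "H1'", "H2'")
}

new_conformer <- function(atoms) {
  stopifnot(is.data.frame(atoms),
            all(c("res", "resname", "atom", "x", "y", "z", "strand") %in%
                  names(atoms)))
  structure(list(atoms = atoms), class = "conformer")
}

#' Coerce to / validate a conformer
#'
#' A `conformer` holds one coordinate set of a duplex: a data.frame of atoms
#' with residue index, residue code, atom name, x/y/z in Angstrom and strand
#' membership (1 or 2).
#'
#' @param x a conformer or a data.frame with the required columns.
#' @return a `conformer` object.
#' @export
as_conformer <- function(x) {
  if (inherits(x, "conformer")) return(x)
  if (is.data.frame(x)) return(new_conformer(x))
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to conformer")
}

#' Validate the atom complement of a conformer
#'
#' Checks that every residue carries the full heavy-atom complement for its
#' residue code plus the H1'/H2' protons required for the J-coupling
#' dihedral, and that all coordinates are finite.
#'
#' @param conformer a `conformer`.
#' @return TRUE invisibly; stops with an informative error otherwise.
#' @export
validate_conformer <- function(conformer) {
  at <- as_conformer(conformer)$atoms
  if (!all(is.finite(c(at$x, at$y, at$z))))
    stop("non-finite coordinates in conformer")
  for (strand in unique(at$strand)) {
    rs <- sort(unique(at$res[at$strand == strand]))
    for (r in rs) {
      sel <- at$res == r
      code <- at$resname[sel][1]
      need <- required_atoms(code, terminal5 = (r == rs[1]))
      miss <- setdiff(need, at$atom[sel])
      if (length(miss))
        stop("residue ", r, " (", code, ") missing atom(s): ",
             paste(miss, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' @export
print.conformer <- function(x, ...) {
  at <- x$atoms
  cat(sprintf("conformer: %d atoms, %d residues, %d strand(s)\n",
              nrow(at), length(unique(at$res)), length(unique(at$strand))))
  invisible(x)
}

# coordinate matrix of (a subset of) the atoms
conformer_xyz <- function(conformer, sel = NULL) {
  at <- as_conformer(conformer)$atoms
  if (!is.null(sel)) at <- at[sel(at), , drop = FALSE]
  as.matrix(at[, c("x", "y", "z")])
}

heavy_xyz <- function(conformer) {
  at <- as_conformer(conformer)$atoms
  as.matrix(at[!grepl("^H", at$atom), c("x", "y", "z")])
}

atom_xyz <- function(conformer, res, atom) {
  at <- as_conformer(conformer)$atoms
  i <- which(at$res == res & at$atom == atom)
  if (length(i) != 1) return(NULL)
  c(at$x[i], at$y[i], at$z[i])
}

# ---- builder ------------------------------------------------------------

#' Build an idealized duplex with prescribed helical parameters
#'
#' Places, for every base pair, pre-computed nucleotide geometries (base in
#' its standard reference frame plus a pseudorotation-parameterized ribose)
#' into a helical arrangement: per-pair inclination and x-displacement, then
#' a cumulative twist about and rise along the helix axis. Inter-residue
#' backbone connectivity is approximate (no chain closure); intra-residue
#' geometry, sugar pucker, and base-pair hydrogen bonding are exact by
#' construction.
#'
#' @param spec a [duplex_spec()].
#' @param rise rise per base-pair step in Angstrom.
#' @param twist helical twist in degrees; a scalar or a length n-1 vector of
#'   per-step values.
#' @param pucker optional per-residue pucker: a named list (names = residue
#'   numbers) of c(P, numax) vectors or class strings "C2-endo"/"C3-endo";
#'   unlisted residues are built C3'-endo.
#' @param config pipeline configuration (inclination, x-displacement,
#'   backbone torsions, pucker build parameters).
#' @param bend bend (kink) angle in degrees applied between the two helix
#'   halves (0 = straight).
#' @param bend_after pair index after which the bend is applied (default:
#'   the central step).
#' @param open_pairs integer vector of pair indices whose strand-1 base is
#'   displaced out of hydrogen-bonding geometry (base-pair opening).
#' @param open_shift displacement in Angstrom applied to opened bases
#'   (along the pair long axis, away from the partner; >= 2 recommended).
#' @return a `conformer`.
#' @export
build_ideal_duplex <- function(spec, rise = NULL, twist = NULL, pucker = NULL,
                               config = default_config(), bend = 0,
                               bend_after = NULL, open_pairs = integer(),
                               open_shift = 2.5) {
  config <- validate_config(config)
  if (!inherits(spec, "duplex_spec")) stop("spec must be a duplex_spec")
  if (is.null(rise)) rise <- config$helix$rise
  if (is.null(twist)) twist <- config$helix$twist
  if (rise <= 0) stop("rise must be positive")
  if (any(twist <= 0) || any(twist >= 90)) stop("twist must be in (0, 90)")
  n <- spec$n
  if (length(twist) == 1) twist <- rep(twist, max(n - 1, 0))
  if (n > 1 && length(twist) != n - 1)
    stop("twist must be scalar or length n - 1")
  if (is.null(bend_after)) bend_after <- floor(n / 2)

  pucker_of <- function(res) {
    pp <- config$pucker$c3_build
    if (!is.null(pucker)) {
      v <- pucker[[as.character(res)]]
      if (!is.null(v)) {
        if (is.character(v)) {
          pp <- if (v == "C2-endo") config$pucker$c2_build else config$pucker$c3_build
        } else pp <- v
      }
    }
    pp
  }

  incl <- rigid(R = rotation_matrix(c(1, 0, 0), config$helix$inclination))
  xdisp <- rigid(t = c(config$helix$x_disp, 0, 0))
  theta <- c(0, cumsum(twist))
  zs <- (seq_len(n) - 1) * rise
  pr <- spec_pairs(spec)
  rows <- vector("list", 2L * n)

  place_res <- function(res, code, strand, Tbase, Tpair, open) {
    terminal5 <- (strand == 1 && res == spec$res1[1]) ||
      (strand == 2 && res == spec$res2[1])
    nt <- build_nucleotide(code, pucker = pucker_of(res),
                           chi = config$backbone$chi,
                           gamma = config$backbone$gamma,
                           beta = config$backbone$beta,
                           with_phosphate = !terminal5)
    if (open) {
      bnames <- rownames(base_template(code))
      bnames <- bnames[bnames != "C1'"]
      nt[bnames, 2] <- nt[bnames, 2] + open_shift
    }
    X <- rigid_apply(Tpair, rigid_apply(Tbase, nt))
    data.frame(res = res, resname = code, atom = rownames(X),
               x = X[, 1], y = X[, 2], z = X[, 3], strand = strand,
               row.names = NULL)
  }

  for (k in seq_len(n)) {
    tpl <- pair_template(pr$code_i[k], pr$code_j[k])
    Tk <- rigid_compose(
      rigid(R = rotation_matrix(c(0, 0, 1), theta[k]), t = c(0, 0, zs[k])),
      rigid_compose(xdisp, incl)
    )
    if (bend != 0 && k > bend_after) {
      zc <- (zs[bend_after] + zs[bend_after + 1]) / 2
      axis <- as.vector(rotation_matrix(c(0, 0, 1), theta[bend_after]) %*% c(1, 0, 0))
      Rb <- rotation_matrix(axis, bend)
      Tb <- rigid(R = Rb, t = c(0, 0, zc) - as.vector(Rb %*% c(0, 0, zc)))
      Tk <- rigid_compose(Tb, Tk)
    }
    opened <- k %in% open_pairs
    rows[[k]] <- place_res(pr$res_i[k], pr$code_i[k], 1L, tpl$T1, Tk, opened)
    rows[[n + k]] <- place_res(pr$res_j[k], pr$code_j[k], 2L, tpl$T2, Tk, FALSE)
  }
  at <- do.call(rbind, rows)
  at <- at[order(at$strand, at$res), ]
  rownames(at) <- NULL
  new_conformer(at)
}
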