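# The conformer-ensemble container.

#' Construct an RNA conformer ensemble
#'
#' An `rna_ensemble` bundles a list of conformers (identical atom layout)
#' with per-conformer prior weights and, when produced by the synthetic
#' generator, a ground-truth table of every stochastic draw.
#'
#' @param conformers list of `conformer` objects.
#' @param weights prior weights (default uniform); normalized on input.
#' @param spec optional [duplex_spec()] shared by the conformers.
#' @param truth optional ground-truth record (see [generate_ensemble()]).
#' @return an object of class `rna_ensemble`.
#' @export
rna_ensemble <- function(conformers, weights = NULL, spec = NULL, truth = NULL) {
  stopifnot(is.list(conformers), length(conformers) >= 1)
  conformers <- lapply(conformers, as_conformer)
  n <- length(conformers)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n) stop("weights length must match conformer count")
  if (any(weights < 0)) stop("weights must be non-negative")
  s <- sum(weights)
  if (s <= 0) stop("weights sum to zero")
  structure(list(conformers = conformers, weights = weights / s,
                 spec = spec, truth = truth), class = "rna_ensemble")
}

.ens_weights <- function(ensemble, weights = NULL) {
  w <- if (is.null(weights)) ensemble$weights else weights
  if (length(w) != length(ensemble$conformers))
    stop("weights length must match conformer count")
  w / sum(w)
}

#' @export
print.rna_ensemble <- function(x, ...) {
  cat(sprintf("rna_ensemble: %d conformers, %d atoms each%s\n",
              length(x$conformers), nrow(x$conformers[[1]]$atoms),
              if (!is.null(x$truth)) " (with ground truth)" else ""))
  invisible(x)
}

#' Number of conformers
#' @param ensemble an `rna_ensemble`.
#' @return integer count.
#' @export
n_conformers <- function(ensemble) length(ensemble$conformers)

# stacked coordinate array (n_conf x n_atoms x 3) for identical-layout
# ensembles; errors if layouts differ.
.ens_coord_array <- function(ensemble, heavy_only = TRUE) {
  a1 <- ensemble$conformers[[1]]$atoms
  key <- paste(a1$res, a1$atom)
  keep <- if (heavy_only) !grepl("^H", a1$atom) else rep(TRUE, nrow(a1))
  n <- length(ensemble$conformers)
  out <- array(NA_real_, c(n, sum(keep), 3))
  for (j in seq_len(n)) {
    aj <- ensemble$conformers[[j]]$atoms
    if (!identical(paste(aj$res, aj$atom), key))
      stop("conformer ", j, " has a different atom layout")
    out[j, , ] <- as.matrix(aj[keep, c("x", "y", "z")])
  }
  out
}

#' Ensemble RMSD about the weighted centroid
#'
#' Each conformer is superposed (Kabsch least squares, heavy atoms) onto the
#' alignment subset of a reference, the weighted-mean coordinates define the
#' centroid, and the superposition is refined against the centroid. Reported
#' are the per-conformer heavy-atom RMSDs to the centroid and the ensemble
#' RMSD, the weighted root-mean-square of those values.
#'
#' @param ensemble an `rna_ensemble`.
#' @param align_res residue numbers used for the superposition (default: all
#'   residues).
#' @param weights optional conformer weights.
#' @return list with `per_conformer` (RMSD in Angstrom), `ensemble_rmsd`,
#'   and `centroid` (coordinate matrix).
#' @export
ensemble_rmsd <- function(ensemble, align_res = NULL, weights = NULL) {
  w <- .ens_weights(ensemble, weights)
  a1 <- ensemble$conformers[[1]]$atoms
  heavy <- !grepl("^H", a1$atom)
  if (is.null(align_res)) align_res <- unique(a1$res)
  sub <- which(a1$res[heavy] %in% align_res)
  if (length(sub) < 3) stop("alignment subset has fewer than 3 atoms")
  A <- .ens_coord_array(ensemble, heavy_only = TRUE)
  n <- dim(A)[1]
  align_to <- function(A, ref) {
    for (j in seq_len(n)) {
      fit <- kabsch(A[j, sub, ], ref[sub, ])
      A[j, , ] <- apply_rigid(A[j, , ], fit$R, fit$t)
    }
    A
  }
  ref <- A[1, , ]
  for (pass in 1:2) {
    A <- align_to(A, ref)
    ref <- apply(A * w, c(2, 3), sum)   # weighted mean (weights sum to 1)
  }
  rmsd <- vapply(seq_len(n), function(j)
    sqrt(mean(rowSums((A[j, , ] - ref)^2))), numeric(1))
  list(per_conformer = rmsd,
       ensemble_rmsd = sqrt(sum(w * rmsd^2)),
       centroid = ref)
}
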