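# Quality-threshold clustering and per-cluster ensemble summaries.

#' Quality-threshold clustering
#'
#' Deterministic clustering under a diameter bound: a candidate cluster is
#' grown around every unassigned point by repeatedly adding the point whose
#' inclusion keeps the cluster diameter within `threshold` (choosing the
#' point with the smallest maximal distance to the cluster; ties broken by
#' lower index). The candidate with the largest total weight is accepted
#' (ties: lower seed index), its points are removed, and the process repeats
#' until no candidate reaches `min_population`. Unassigned points get label
#' -1.
#'
#' @param points numeric matrix (rows = conformers), typically PCA
#'   projections.
#' @param weights per-point weights (default uniform); normalized on input.
#' @param threshold cluster diameter bound; NULL selects the
#'   `config$qt$threshold_quantile` quantile of all pairwise distances.
#' @param min_population smallest admissible cluster weight (fraction).
#' @param config pipeline configuration.
#' @return an object of class `cluster_result`: list with `labels`
#'   (-1 = unassigned), `populations` (decreasing), `centroid_index` (medoid
#'   per cluster), `threshold`.
#' @export
qt_cluster <- function(points, weights = NULL, threshold = NULL,
                       min_population = NULL, config = default_config()) {
  config <- validate_config(config)
  points <- as.matrix(points)
  n <- nrow(points)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  if (is.null(min_population)) min_population <- config$qt$min_population
  D <- as.matrix(stats::dist(points))
  if (is.null(threshold)) {
    dv <- D[upper.tri(D)]
    threshold <- unname(stats::quantile(dv, config$qt$threshold_quantile))
  }
  if (threshold <= 0) stop("threshold must be positive")
  labels <- rep(-1L, n)
  clusters <- list()
  unassigned <- rep(TRUE, n)
  # Grow the candidate cluster around `seed`: repeatedly add the point whose
  # inclusion keeps the diameter within threshold, choosing the smallest
  # maximal distance (ties: lowest index). `best_w` allows early abandoning
  # of candidates that provably cannot exceed the current best weight
  # (their attainable weight only shrinks), which leaves the accepted
  # cluster unchanged.
  grow <- function(seed, pool, best_w) {
    members <- seed
    mw <- w[seed]
    active <- pool[pool != seed]
    dmax <- D[seed, active]
    repeat {
      keep <- dmax <= threshold
      active <- active[keep]
      dmax <- dmax[keep]
      if (mw + sum(w[active]) <= best_w) return(NULL)
      if (!length(active)) break
      i <- which.min(dmax)
      nxt <- active[i]
      members <- c(members, nxt)
      mw <- mw + w[nxt]
      active <- active[-i]
      dmax <- pmax(dmax[-i], D[nxt, active])
    }
    members
  }
  repeat {
    seeds <- which(unassigned)
    if (!length(seeds)) break
    best <- NULL
    best_w <- 0
    for (s in seeds) {
      mem <- grow(s, seeds, best_w)
      if (is.null(mem)) next
      mw <- sum(w[mem])
      if (mw > best_w + 1e-15) { best <- mem; best_w <- mw }
    }
    if (is.null(best) || best_w < min_population) break
    clusters[[length(clusters) + 1]] <- best
    unassigned[best] <- FALSE
  }
  if (length(clusters)) {
    pops <- vapply(clusters, function(m) sum(w[m]), numeric(1))
    ord <- order(pops, decreasing = TRUE)
    clusters <- clusters[ord]
    pops <- pops[ord]
    for (ci in seq_along(clusters)) labels[clusters[[ci]]] <- ci
    centroid <- vapply(clusters, function(m) {
      if (length(m) == 1) return(m)
      wm <- w[m] / sum(w[m])
      m[which.min(colSums(D[m, m, drop = FALSE] * wm))]
    }, integer(1))
  } else {
    pops <- numeric(0)
    centroid <- integer(0)
  }
  structure(list(labels = labels, populations = pops,
                 centroid_index = centroid, threshold = threshold),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d cluster(s), threshold %.3g\n",
              length(x$populations), x$threshold))
  if (length(x$populations))
    cat(" populations:", paste(sprintf("%.3f", x$populations), collapse = " "),
        "\n")
  cat(sprintf(" unassigned: %d of %d\n", sum(x$labels == -1L),
              length(x$labels)))
  invisible(x)
}

#' Per-cluster observable summaries
#'
#' Computes, with within-group renormalized weights, the mean radius of
#' gyration, the mean fraction of intact base pairs (and per-pair pairing
#' populations), mean helical twist and kink, mean per-residue J couplings,
#' and optional chi-square agreement against experimental J couplings, NOE
#' restraints and a SAXS profile. The "All" row uses every conformer and
#' reproduces whole-ensemble values; an "unassigned" row covers label -1.
#'
#' @param ensemble an `rna_ensemble` with a `spec`.
#' @param clusters a `cluster_result` from [qt_cluster()].
#' @param weights optional conformer weights (default: ensemble weights).
#' @param j_exp optional data.frame (res, J, sigma) of experimental
#'   couplings.
#' @param noe optional `noe_restraints` table.
#' @param saxs optional experimental `saxs_profile` (with sigma).
#' @param config pipeline configuration.
#' @return list with `table` (one row per group) and `pairing` (per-pair
#'   intact populations, groups x pairs).
#' @export
cluster_summaries <- function(ensemble, clusters, weights = NULL,
                              j_exp = NULL, noe = NULL, saxs = NULL,
                              config = default_config()) {
  config <- validate_config(config)
  stopifnot(inherits(ensemble, "rna_ensemble"))
  if (is.null(ensemble$spec))
    stop("ensemble must carry its duplex_spec for pairing summaries")
  w <- .ens_weights(ensemble, weights)
  labels <- clusters$labels
  n <- length(ensemble$conformers)
  if (length(labels) != n) stop("labels length must match ensemble size")
  spec <- ensemble$spec
  # per-conformer ingredients (computed once)
  rg <- vapply(ensemble$conformers, radius_of_gyration, numeric(1))
  bps <- lapply(ensemble$conformers, detect_base_pairs, spec = spec,
                config = config)
  pair_mat <- t(vapply(bps, function(bp) bp$geometry != "open",
                       logical(spec$n)))
  hp <- mapply(function(cf, bp) helical_parameters(cf, bp),
               ensemble$conformers, bps, SIMPLIFY = FALSE)
  twist <- vapply(hp, function(h) h$mean_twist, numeric(1))
  kink <- vapply(hp, function(h) h$kink, numeric(1))
  res_all <- sort(unique(ensemble$conformers[[1]]$atoms$res))
  jres <- if (!is.null(j_exp)) j_exp$res else res_all
  Jmat <- t(vapply(ensemble$conformers, function(cf)
    j_from_conformer(cf, jres, config), numeric(length(jres))))
  noe_d <- if (!is.null(noe)) t(vapply(ensemble$conformers, function(cf)
    noe_backcalc(cf, noe), numeric(nrow(noe)))) else NULL
  saxs_I <- if (!is.null(saxs)) vapply(ensemble$conformers, function(cf)
    debye_profile(cf, saxs$q)$I, numeric(nrow(saxs))) else NULL

  groups <- list(All = seq_len(n))
  for (ci in seq_along(clusters$populations))
    groups[[paste0("C", ci)]] <- which(labels == ci)
  if (any(labels == -1L)) groups$unassigned <- which(labels == -1L)

  summarize <- function(idx) {
    wg <- w[idx] / sum(w[idx])
    row <- list(
      population = sum(w[idx]),
      n = length(idx),
      mean_rg = sum(wg * rg[idx]),
      mean_twist = sum(wg * twist[idx]),
      mean_kink = sum(wg * kink[idx]),
      frac_paired = sum(wg * rowMeans(pair_mat[idx, , drop = FALSE]))
    )
    if (!is.null(j_exp)) {
      jc <- as.vector(t(Jmat[idx, , drop = FALSE]) %*% wg)
      sig <- if ("sigma" %in% names(j_exp)) j_exp$sigma else config$sigma$J
      row$chi2_J <- chi2(jc, j_exp$J, sig, "J")
    }
    if (!is.null(noe_d)) {
      de <- as.vector((t(noe_d[idx, , drop = FALSE]^(-6)) %*% wg))^(-1 / 6)
      row$chi2_noe <- chi2(de, noe, config$sigma$noe, "NOE")
    }
    if (!is.null(saxs_I)) {
      Ic <- as.vector(saxs_I[, idx, drop = FALSE] %*% wg)
      row$chi2_saxs <- chi2(Ic, saxs$I, saxs$sigma, "SAXS")
    }
    row
  }
  tab <- do.call(rbind, lapply(groups, function(idx)
    as.data.frame(summarize(idx))))
  tab <- cbind(group = names(groups), tab)
  rownames(tab) <- NULL
  pairing <- do.call(rbind, lapply(groups, function(idx) {
    wg <- w[idx] / sum(w[idx])
    as.vector(t(pair_mat[idx, , drop = FALSE]) %*% wg)
  }))
  colnames(pairing) <- paste0(spec_pairs(spec)$res_i, ":",
                              spec_pairs(spec)$res_j)
  list(table = tab, pairing = pairing)
}
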