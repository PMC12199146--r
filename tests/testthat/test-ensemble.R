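# Featurization, PCA, quality-threshold clustering, summaries and
# ensemble RMSD.

test_that("G-vector features: identity, rigid invariance, cutoff zeros", {
  cf <- build_ideal_duplex(spec10())
  g1 <- gvector_features(cf)
  expect_identical(g1, gvector_features(cf))
  g2 <- gvector_features(transform_conformer(cf))
  expect_lt(max(abs(g1 - g2)), 1e-8)
  # pairs beyond the scaled cutoff are exact zero 4-vectors (residues 1 and
  # 10 sit at opposite ends of strand 1, ~25 Angstrom apart)
  expect_identical(unname(g1[paste0("g1_10_", 1:4)]), rep(0, 4))
  # nearest-neighbour pairs are inside the cutoff
  expect_gt(sum(abs(g1[paste0("g1_2_", 1:4)])), 0)
})

test_that("pca_project: dominant axis, orthonormality, reconstruction", {
  set.seed(4)
  n <- 40
  X <- cbind(rnorm(n, sd = 10), matrix(rnorm(n * 5, sd = 1e-4), n, 5))
  p <- pca_project(X, n_components = 2)
  expect_gte(p$explained_variance[1], 0.999)
  pf <- pca_project(X, n_components = 6)
  V <- pf$components
  expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-10)
  expect_lte(sum(pf$explained_variance), 1 + 1e-12)
  # full-rank reconstruction
  Xc <- sweep(X, 2, pf$center)
  expect_lt(max(abs(pf$projections %*% t(V) - Xc)), 1e-8)
  expect_error(pca_project(matrix(1, 5, 3)), "zero-variance")
})

test_that("PCA projections are equivariant under orthogonal feature maps", {
  set.seed(6)
  X <- matrix(rnorm(30 * 4), 30, 4)
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  p1 <- pca_project(X, n_components = 3)
  p2 <- pca_project(X %*% Q, n_components = 3)
  # projections agree up to per-component sign
  for (k in 1:3) {
    expect_equal(abs(p1$projections[, k]), abs(p2$projections[, k]),
                 tolerance = 1e-8)
  }
  expect_equal(p1$explained_variance, p2$explained_variance,
               tolerance = 1e-10)
})

test_that("qt_cluster recovers planted populations and is deterministic", {
  set.seed(19)
  n <- 500
  n1 <- rbinom(1, n, 0.7)
  pts <- rbind(matrix(rnorm(n1 * 2, 0, 0.5), ncol = 2),
               matrix(rnorm((n - n1) * 2, 8, 0.5), ncol = 2))
  qc <- qt_cluster(pts, threshold = 4, min_population = 0.05)
  expect_length(qc$populations, 2)
  expect_lt(abs(qc$populations[1] - 0.7), 0.05)
  expect_lt(abs(qc$populations[2] - 0.3), 0.05)
  expect_true(all(diff(qc$populations) <= 0))
  expect_lte(sum(qc$populations), 1 + 1e-12)
  # determinism
  qc2 <- qt_cluster(pts, threshold = 4, min_population = 0.05)
  expect_identical(qc$labels, qc2$labels)
  # threshold larger than the data diameter: one cluster with everything
  qall <- qt_cluster(pts, threshold = 1e6)
  expect_equal(qall$populations, 1)
  expect_true(all(qall$labels == 1L))
  # reported populations are exactly the label-wise weight sums
  w <- c(rep(2, n1), rep(1, n - n1))
  qw <- qt_cluster(pts, weights = w, threshold = 4)
  expect_equal(qw$populations[1], sum(w[qw$labels == 1L]) / sum(w),
               tolerance = 1e-12)
})

test_that("cluster_summaries: All row equals whole ensemble; mixtures resolved", {
  sp <- spec10()
  # two pure sub-populations: C3'-endo straight vs C2'-endo (central) bent
  recA <- ensemble_recipe(sp, n_conformers = 6, seed = 1)
  recB <- ensemble_recipe(sp, n_conformers = 4, seed = 2,
                          c2_fraction = setNames(rep(1, 4), c(5, 6, 15, 16)),
                          kink_mean = 40, kink_sd = 0)
  ens <- rna_ensemble(c(generate_ensemble(recA)$conformers,
                        generate_ensemble(recB)$conformers), spec = sp)
  labels <- c(rep(1L, 6), rep(2L, 4))
  cl <- structure(list(labels = labels, populations = c(0.6, 0.4),
                       centroid_index = c(1L, 7L), threshold = 1),
                  class = "cluster_result")
  jx <- data.frame(res = c(5, 6, 15, 16), J = c(1, 1, 1, 1), sigma = 0.5)
  sm <- cluster_summaries(ens, cl, j_exp = jx)
  tab <- sm$table
  all_row <- tab[tab$group == "All", ]
  # All row reproduces population-weighted cluster values (linear summaries)
  mix <- function(col) sum(tab$population[tab$group != "All"] *
                             tab[[col]][tab$group != "All"])
  expect_equal(all_row$mean_rg, mix("mean_rg"), tolerance = 1e-10)
  expect_equal(all_row$mean_twist, mix("mean_twist"), tolerance = 1e-10)
  expect_equal(all_row$frac_paired, mix("frac_paired"), tolerance = 1e-10)
  expect_equal(sum(tab$population[tab$group != "All"]), 1, tolerance = 1e-12)
  # per-cluster mean couplings: pure C3'-endo low, pure C2'-endo high
  Jmat <- t(sapply(ens$conformers, function(cf)
    j_from_conformer(cf, c(5, 6, 15, 16))))
  expect_lte(mean(Jmat[labels == 1L, ]), 1)
  expect_gte(mean(Jmat[labels == 2L, ]), 10)
  # the bent cluster shows the planted kink
  expect_equal(tab$mean_kink[tab$group == "C2"], 40, tolerance = 3)
})

test_that("single-cluster ensembles collapse All and cluster rows", {
  ens <- tiny_ensemble(n = 5)
  cl <- structure(list(labels = rep(1L, 5), populations = 1,
                       centroid_index = 1L, threshold = 1),
                  class = "cluster_result")
  sm <- cluster_summaries(ens, cl)
  tab <- sm$table
  for (col in c("mean_rg", "mean_twist", "mean_kink", "frac_paired")) {
    expect_equal(tab[[col]][tab$group == "All"],
                 tab[[col]][tab$group == "C1"])
  }
  expect_equal(unname(sm$pairing["All", ]), unname(sm$pairing["C1", ]))
})

test_that("pairing population matches the planted opening probability", {
  sp <- spec10()
  rec <- ensemble_recipe(sp, n_conformers = 150,
                         opening_prob = setNames(0.35, "5"), seed = 55)
  ens <- generate_ensemble(rec)
  cl <- structure(list(labels = rep(1L, 150), populations = 1,
                       centroid_index = 1L, threshold = 1),
                  class = "cluster_result")
  sm <- cluster_summaries(ens, cl)
  open_pop <- 1 - sm$pairing["All", "5:16"]
  expect_equal(unname(open_pop), 0.35, tolerance = 0.05)
  # detection agrees with the generator's own draws, conformer by conformer
  expect_equal(unname(open_pop), mean(ens$truth$open[, 5]), tolerance = 1e-12)
})

test_that("ensemble_rmsd: zero for identical/rotated, exact for planted shift", {
  cf <- build_ideal_duplex(spec6())
  ens0 <- rna_ensemble(list(cf, cf, cf))
  er0 <- ensemble_rmsd(ens0)
  expect_equal(er0$ensemble_rmsd, 0, tolerance = 1e-10)
  ensR <- rna_ensemble(list(cf, transform_conformer(cf)))
  expect_equal(ensemble_rmsd(ensR)$ensemble_rmsd, 0, tolerance = 1e-8)
  # planted displacement outside the aligned region
  cf2 <- cf
  mv <- cf2$atoms$res %in% c(6, 7)   # central pair of the 6-mer
  cf2$atoms$z[mv] <- cf2$atoms$z[mv] + 2
  ens2 <- rna_ensemble(list(cf, cf2), weights = c(0.5, 0.5))
  align <- c(1:2, 11:12)
  er2 <- ensemble_rmsd(ens2, align_res = align)
  # hand-computed: centroid halves the 2 A shift for the moved atoms
  at <- cf$atoms[!grepl("^H", cf$atoms$atom), ]
  n_heavy <- nrow(at)
  n_mv <- sum(at$res %in% c(6, 7))
  rmsd_hand <- sqrt(n_mv * 1^2 / n_heavy)
  expect_equal(er2$per_conformer, rep(rmsd_hand, 2), tolerance = 1e-6)
  expect_equal(er2$ensemble_rmsd, rmsd_hand, tolerance = 1e-6)
  expect_error(ensemble_rmsd(ens2, align_res = 999), "fewer than 3")
})
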