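# Karplus couplings, canonical coordinates, Rg, P(r), NOE and chi-square.

test_that("karplus_j evaluates the three-term relation", {
  p <- list(A = 9.67, B = -2.03, C = 0)
  expect_equal(karplus_j(90, c(p, C = 0)), 0)
  expect_equal(karplus_j(0, p), p$A + p$B + p$C)
  expect_equal(karplus_j(180, p), p$A - p$B + p$C)
  # idealized C3'-endo ribose: coupling at most 1 Hz
  cf3 <- build_ribose(18, 38)
  expect_lte(j_from_conformer(cf3)[[1]], 1)
  # idealized C2'-endo ribose: at least 10 Hz
  cf2 <- build_ribose(162, 38)
  expect_gte(j_from_conformer(cf2)[[1]], 10)
})

test_that("ensemble J averaging is linear in weights", {
  cf3 <- build_ribose(18, 38)
  cf2 <- build_ribose(162, 38)
  j3 <- j_from_conformer(cf3)[[1]]
  j2 <- j_from_conformer(cf2)[[1]]
  ens <- rna_ensemble(list(cf3, cf2), weights = c(0.5, 0.5))
  Jm <- vapply(ens$conformers, function(cf) j_from_conformer(cf)[[1]],
               numeric(1))
  expect_equal(weighted_average(ens$weights, Jm), (j3 + j2) / 2)
  for (f in c(0.1, 0.4, 0.9)) {
    expect_equal(weighted_average(c(1 - f, f), Jm), (1 - f) * j3 + f * j2)
  }
})

test_that("canonical coordinates implement the published linear combinations", {
  sh <- data.frame(res = 1:4,
                   dC1p = c(0, 1, 0, 92.1), dC2p = c(0, 0, 0, 75.3),
                   dC3p = c(0, 0, 0, 72.5), dC4p = c(0, 0, 1, 83.1),
                   dC5p = c(0, 0, 0, 62.9))
  cc <- canonical_coordinates(sh)
  expect_equal(cc$can1[1], 0)
  expect_equal(cc$can2[1], 0)
  expect_equal(cc$can1[2], 0.179)
  expect_equal(cc$can2[2], 0)
  expect_equal(cc$can1[3], -0.225)
  expect_equal(cc$can2[3], -0.0556)
  # linearity: doubling all shifts doubles both coordinates
  sh2 <- sh; sh2[, -1] <- sh2[, -1] * 2
  cc2 <- canonical_coordinates(sh2)
  expect_equal(cc2$can1, 2 * cc$can1)
  expect_equal(cc2$can2, 2 * cc$can2)
  # missing shift flags the residue
  sh$dC3p[4] <- NA
  expect_true(is.na(canonical_coordinates(sh)$can2[4]))
})

test_that("experimental pucker classification uses strict thresholds", {
  expect_identical(classify_pucker_experimental(5.14, -7.0), "C2-endo")
  expect_identical(classify_pucker_experimental(0.84, -7.0), "C3-endo")
  expect_identical(classify_pucker_experimental(3.0, -7.0), "C3-endo")
  expect_identical(classify_pucker_experimental(5.0, -6.25), "C3-endo")
  expect_identical(
    classify_pucker_experimental(c(5.14, 0.84), c(-7, -7)),
    c("C2-endo", "C3-endo"))
})

test_that("radius_of_gyration matches closed forms", {
  mk <- function(X) as_conformer(data.frame(
    res = 1L, resname = "U", atom = paste0("C", seq_len(nrow(X))),
    x = X[, 1], y = X[, 2], z = X[, 3], strand = 1L))
  expect_equal(radius_of_gyration(mk(matrix(c(3, 4, 5), 1))), 0)
  expect_equal(radius_of_gyration(mk(rbind(c(0, 0, 0), c(2, 0, 0)))), 1)
  # 5 collinear atoms, 1 A spacing: Rg = sqrt((N^2-1)/12) = sqrt(2)
  X5 <- cbind(0:4, 0, 0)
  expect_equal(radius_of_gyration(mk(X5)), sqrt(2))
  # ensemble form: weighted <Rg^2> and its square root
  ens <- rna_ensemble(list(mk(rbind(c(0, 0, 0), c(2, 0, 0))), mk(X5)),
                      weights = c(0.25, 0.75))
  r <- radius_of_gyration(ens)
  expect_equal(r$mean_rg2, 0.25 * 1 + 0.75 * 2)
  expect_equal(r$rms_rg, sqrt(r$mean_rg2))
})

test_that("pair_distance_distribution: Dmax, normalization, Rg consistency", {
  mk <- function(X) as_conformer(data.frame(
    res = 1L, resname = "U", atom = paste0("C", seq_len(nrow(X))),
    x = X[, 1], y = X[, 2], z = X[, 3], strand = 1L))
  two <- pair_distance_distribution(mk(rbind(c(0, 0, 0), c(0, 0, 3.2))),
                                    bin_width = 0.5)
  expect_equal(two$dmax, 3.2)
  expect_equal(sum(two$p) * two$bin_width, 1)
  expect_equal(sum(two$p[two$r > 3 & two$r < 3.5]) * two$bin_width, 1)
  expect_equal(two$rg, 1.6)  # two points at d: Rg = d/2
  tri <- pair_distance_distribution(
    mk(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))), 0.25)
  expect_equal(tri$dmax, 1)
  expect_equal(sum(tri$p[abs(tri$r - 1) < 0.25]) * tri$bin_width, 1)
  # histogram-free second moment agrees with the coordinate Rg
  cf <- build_ideal_duplex(spec10())
  pr <- pair_distance_distribution(cf, 0.5)
  expect_equal(pr$rg, radius_of_gyration(cf), tolerance = 1e-10)
})

test_that("noe_backcalc applies r^-6 ensemble averaging", {
  sp <- spec6()
  cf <- build_ideal_duplex(sp)
  rst <- noe_restraints(1, "C1'", 12, "C1'", "weak")
  d_geom <- rnaens:::vnorm(rnaens:::atom_xyz(cf, 1, "C1'") -
                             rnaens:::atom_xyz(cf, 12, "C1'"))
  expect_equal(noe_backcalc(cf, rst), d_geom)
  # one-hot weights pick that conformer
  cf2 <- transform_conformer(cf)
  cf2$atoms$x <- cf2$atoms$x * 1  # same geometry, moved rigidly
  ens <- rna_ensemble(list(cf, cf2), weights = c(0, 1))
  expect_equal(noe_backcalc(ens, rst), d_geom)
  # two distances 2 and 4 at equal weight
  mk <- function(d) as_conformer(data.frame(
    res = c(1L, 2L), resname = "U", atom = "H3",
    x = c(0, d), y = 0, z = 0, strand = 1L))
  ens2 <- rna_ensemble(list(mk(2), mk(4)))
  rst2 <- noe_restraints(1, "H3", 2, "H3", "medium")
  expect_equal(noe_backcalc(ens2, rst2),
               (0.5 * (2^-6 + 4^-6))^(-1 / 6))
  expect_error(noe_backcalc(cf, noe_restraints(1, "XX", 2, "C1'", "weak")),
               "cannot resolve")
})

test_that("chi2 conventions: J, NOE violations, SAXS scale+offset", {
  expect_equal(chi2(c(1, 2, 3), c(1, 2, 3), 0.5, "J"), 0)
  expect_equal(chi2(c(1, 2), c(2, 2), c(0.5, 1), "J"), mean(c(4, 0)))
  rst <- noe_restraints(c(1, 2), c("a", "a"), c(3, 4), c("b", "b"),
                        c("strong", "weak"))
  expect_equal(chi2(c(2.5, 4.0), rst, 0.5, "NOE"), 0)
  # one unit violation: d = upper + sigma
  expect_equal(chi2(c(3.3 + 0.5, 4.0), rst, 0.5, "NOE"), 0.5)
  expect_equal(chi2(c(1.8 - 1, 4.0), rst, 0.5, "NOE"), mean(c(4, 0)))
  # SAXS: scale invariance and exact zero at calc == exp
  I <- exp(-seq(0, 2, 0.1))
  expect_equal(chi2(I, I, 0.01, "SAXS"), 0)
  expect_equal(chi2(2 * I, I, 0.01, "SAXS"), 0)
  expect_equal(chi2(2 * I + 5, I, 0.01, "SAXS"), 0)
  expect_gt(chi2(I^2, I, 0.01, "SAXS"), 0)
  expect_error(chi2(I, I, 0, "SAXS"), "sigma")
  # invariance under joint relabeling
  set.seed(3)
  ord <- sample(length(I))
  Ic <- I + rnorm(length(I), 0, 0.05)
  expect_equal(chi2(Ic, I, 0.05, "SAXS"), chi2(Ic[ord], I[ord], 0.05, "SAXS"))
})
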