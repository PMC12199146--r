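# Duplex building, torsions, pseudorotation, base-pair detection and
# helical parameters.

test_that("pseudorotation round-trips and classifies by phase boundaries", {
  cases <- list(c(18, 38), c(162, 38), c(90, 40), c(300, 35), c(0.5, 42))
  for (pc in cases) {
    nu <- nu_from_pseudorotation(pc[1], pc[2])
    ps <- pseudorotation(nu)
    expect_equal(ps$P, pc[1], tolerance = 1e-8)
    expect_equal(ps$numax, pc[2], tolerance = 1e-8)
  }
  expect_identical(pseudorotation(nu_from_pseudorotation(18, 38))$klass,
                   "C3-endo")
  expect_identical(pseudorotation(nu_from_pseudorotation(162, 38))$klass,
                   "C2-endo")
  expect_identical(pseudorotation(nu_from_pseudorotation(90, 38))$klass,
                   "other")
  expect_error(pseudorotation(c(0, 0, 0, 0, 0)), "flat ring")
})

test_that("pseudorotation depends only on torsions (rigid-motion invariant)", {
  cf <- build_ribose(18, 38)
  cf2 <- transform_conformer(cf)
  ring <- c("nu0", "nu1", "nu2", "nu3", "nu4")
  t1 <- as.numeric(compute_torsions(cf)[1, ring])
  t2 <- as.numeric(compute_torsions(cf2)[1, ring])
  expect_equal(t1, t2, tolerance = 1e-8)
  expect_equal(pseudorotation(t1)$P, pseudorotation(t2)$P, tolerance = 1e-8)
})

test_that("dihedral_angle handles degenerate and planar quadruples", {
  # collinear -> undefined
  expect_true(is.na(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                   c(3, 1, 0))))
  # planar cis -> 0
  expect_equal(dihedral_angle(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0),
                              c(0, 1, 0)), 0)
  # trans -> 180 (wrapped into (-180, 180])
  expect_equal(dihedral_angle(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0),
                              c(0, -1, 0)), 180)
})

test_that("duplex_spec validates strands and pairings", {
  expect_error(duplex_spec("GCA", "GC"), "equal lengths")
  expect_error(duplex_spec("GXA", "UGC"), "unknown residue code")
  expect_error(duplex_spec("AAA", "AAA"), "unsupported base pair")
  sp <- spec20_I()
  pr <- rnaens:::spec_pairs(sp)
  # central motif numbering matches the 1..40 convention
  expect_equal(pr$res_i[8:13], 8:13)
  expect_equal(pr$res_j[8:13], 33:28)
  expect_equal(paste0(pr$code_i[8:13], pr$code_j[8:13]),
               c("AU", "IU", "IU", "UI", "IU", "CG"))
})

test_that("build -> measure round trip recovers twist and pucker", {
  sp <- spec20_A()
  cf <- build_ideal_duplex(sp, rise = 2.81, twist = 32.7)
  expect_silent(validate_conformer(cf))
  bp <- detect_base_pairs(cf, sp)
  hp <- helical_parameters(cf, bp)
  expect_equal(hp$mean_twist, 32.7, tolerance = 0.5)
  expect_lt(hp$kink, 2)
  tor <- compute_torsions(cf)
  # all riboses C3'-endo: delta in range, ring phase at the build target
  expect_true(all(tor$delta > 70 & tor$delta < 110))
  P <- apply(as.matrix(tor[, paste0("nu", 0:4)]), 1,
             function(nu) pseudorotation(nu)$P)
  expect_true(all(abs(P - 18) < 1.5))
  # independent check of per-step twist: rotation of C1'-C1' vectors about z
  c1 <- function(r) rnaens:::atom_xyz(cf, r, "C1'")
  v <- sapply(1:20, function(k) c1(k) - c1(41 - k))
  ang <- atan2(v[2, ], v[1, ]) * 180 / pi
  steps <- diff(ang) %% 360
  expect_equal(mean(steps), 32.7, tolerance = 0.5)
})

test_that("per-step twist vectors and bends are recovered", {
  sp <- spec10()
  tw <- rep(c(29, 36), length.out = 9)
  cf <- build_ideal_duplex(sp, twist = tw)
  hp <- helical_parameters(cf, detect_base_pairs(cf, sp))
  expect_equal(hp$twist$twist, tw, tolerance = 0.5)
  cfb <- build_ideal_duplex(sp, bend = 30)
  hpb <- helical_parameters(cfb, detect_base_pairs(cfb, sp))
  expect_equal(hpb$kink, 30, tolerance = 3)
})

test_that("a 1-bp duplex is degenerate but valid", {
  sp <- duplex_spec("G", "C")
  cf <- build_ideal_duplex(sp)
  expect_silent(validate_conformer(cf))
  bp <- detect_base_pairs(cf, sp)
  expect_identical(bp$geometry, "WC")
  hp <- helical_parameters(cf, bp, stem_split = list(1L, integer(0)))
  expect_equal(nrow(hp$twist), 0)
  expect_true(is.na(hp$kink))
})

test_that("kink is undefined with fewer than two intact pairs per stem", {
  sp <- spec6()
  cf <- build_ideal_duplex(sp)
  bp <- detect_base_pairs(cf, sp)
  hp <- helical_parameters(cf, bp, stem_split = list(1:5, 6L))
  expect_true(is.na(hp$kink))
})

test_that("built C2'-endo residues produce large couplings (Davies)", {
  sp <- spec20_A()
  cf <- build_ideal_duplex(sp, pucker = list(`10` = "C2-endo"))
  J <- j_from_conformer(cf, c(9, 10, 11))
  expect_gte(unname(J["10"]), 10)
  expect_lte(unname(J["9"]), 1)
  expect_lte(unname(J["11"]), 1)
})

test_that("detect_base_pairs finds WC and wobble geometry, flags opening", {
  sp <- spec20_I()
  cf <- build_ideal_duplex(sp)
  bp <- detect_base_pairs(cf, sp)
  expect_true(all(bp$geometry != "open"))
  expect_identical(bp$geometry[9], "wobble")   # I9:U32
  expect_identical(bp$geometry[11], "wobble")  # U11:I30
  expect_identical(bp$geometry[8], "WC")       # A8:U33
  cfo <- build_ideal_duplex(sp, open_pairs = 9)
  bpo <- detect_base_pairs(cfo, sp)
  expect_identical(bpo$geometry[9], "open")
  expect_false(bpo$hbond[9])
  expect_true(all(bpo$geometry[-9] != "open"))
})

test_that("detect_base_pairs is monotone in the distance cutoff", {
  sp <- spec10()
  rec <- ensemble_recipe(sp, n_conformers = 8, opening_prob = 0.3,
                         noise_sd = 0.1, seed = 42)
  ens <- generate_ensemble(rec)
  cfgs <- lapply(c(3.5, 3.0, 2.6), function(cut) {
    cfg <- default_config(); cfg$hbond$dist_cutoff <- cut; cfg
  })
  for (cf in ens$conformers) {
    paired <- lapply(cfgs, function(cfg)
      detect_base_pairs(cf, sp, cfg)$geometry != "open")
    # shrinking the cutoff never converts open -> paired
    expect_true(all(paired[[2]] <= paired[[1]]))
    expect_true(all(paired[[3]] <= paired[[2]]))
  }
})

test_that("compute_torsions reports per-residue holes, not failures", {
  sp <- spec6()
  cf <- build_ideal_duplex(sp)
  # remove one atom: that residue's affected torsions are NA, others intact
  cf$atoms <- cf$atoms[!(cf$atoms$res == 3 & cf$atoms$atom == "C2'"), ]
  tor <- compute_torsions(cf)
  expect_true(is.na(tor$nu1[tor$res == 3]))
  expect_false(anyNA(tor$delta[tor$res != 3]))
  # 5'-terminal alpha/zeta are NA by construction (no upstream phosphate)
  expect_true(is.na(tor$alpha[tor$res == 1]))
})
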