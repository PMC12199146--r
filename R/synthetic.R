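# Seeded synthetic data generators: conformer ensembles with planted
# ground truth, CLEANEX build-up curves, and noisy SAXS profiles. Every
# generator is a pure function of its seed (the global RNG state is saved
# and restored).

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Recipe for a synthetic conformer ensemble
#'
#' States the generative model of the synthetic duplex ensemble: per residue
#' an independent Bernoulli draw between C2'-endo and C3'-endo sugar pucker,
#' per pair an independent Bernoulli base-pair opening (realized as a rigid
#' base displacement that breaks the hydrogen-bond geometry), Gaussian
#' jitter on the per-step helical twist, a Gaussian central bend (kink), and
#' isotropic Gaussian coordinate noise.
#'
#' @param spec a [duplex_spec()].
#' @param n_conformers ensemble size (>= 1).
#' @param c2_fraction per-residue probability of the C2'-endo state: scalar
#'   or named vector (names = residue numbers; unnamed residues get 0).
#' @param opening_prob per-pair opening probability: scalar or named vector
#'   (names = pair index k).
#' @param twist_jitter_sd standard deviation of per-step twist jitter
#'   (degrees).
#' @param kink_mean,kink_sd central bend distribution (degrees).
#' @param noise_sd isotropic coordinate noise (Angstrom).
#' @param seed integer RNG seed.
#' @return an object of class `ensemble_recipe`.
#' @export
ensemble_recipe <- function(spec, n_conformers = 100, c2_fraction = 0,
                            opening_prob = 0, twist_jitter_sd = 0,
                            kink_mean = 0, kink_sd = 0, noise_sd = 0,
                            seed = 1L) {
  stopifnot(inherits(spec, "duplex_spec"), n_conformers >= 1)
  all_res <- c(spec$res1, spec$res2)
  c2 <- setNames(rep(0, length(all_res)), all_res)
  if (length(c2_fraction) == 1 && is.null(names(c2_fraction))) {
    c2[] <- c2_fraction
  } else {
    c2[names(c2_fraction)] <- c2_fraction
  }
  op <- setNames(rep(0, spec$n), seq_len(spec$n))
  if (length(opening_prob) == 1 && is.null(names(opening_prob))) {
    op[] <- opening_prob
  } else {
    op[names(opening_prob)] <- opening_prob
  }
  if (any(c2 < 0 | c2 > 1) || any(op < 0 | op > 1))
    stop("probabilities must be in [0, 1]")
  if (twist_jitter_sd < 0 || kink_sd < 0 || noise_sd < 0)
    stop("spreads must be non-negative")
  structure(list(spec = spec, n_conformers = as.integer(n_conformers),
                 c2_fraction = c2, opening_prob = op,
                 twist_jitter_sd = twist_jitter_sd,
                 kink_mean = kink_mean, kink_sd = kink_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ensemble_recipe")
}

#' Generate a synthetic conformer ensemble with planted ground truth
#'
#' Draws every conformer independently according to the recipe and records
#' each stochastic draw, so that downstream stages (reweighting, clustering,
#' pair detection, Guinier fits) can be tested against planted truth.
#'
#' @param recipe an [ensemble_recipe()].
#' @param config pipeline configuration.
#' @return an `rna_ensemble` whose `truth` field holds: `pucker` (n x
#'   residues logical matrix, TRUE = C2'-endo), `open` (n x pairs logical),
#'   `bend` (n), `twist` (n x steps).
#' @export
generate_ensemble <- function(recipe, config = default_config()) {
  stopifnot(inherits(recipe, "ensemble_recipe"))
  config <- validate_config(config)
  spec <- recipe$spec
  n <- recipe$n_conformers
  nres <- 2 * spec$n
  nsteps <- max(spec$n - 1, 0)
  .with_seed(recipe$seed, {
    pucker_draw <- matrix(
      stats::runif(n * nres) < rep(recipe$c2_fraction, each = n),
      n, nres, dimnames = list(NULL, names(recipe$c2_fraction)))
    open_draw <- matrix(
      stats::runif(n * spec$n) < rep(recipe$opening_prob, each = n),
      n, spec$n)
    bend <- if (recipe$kink_sd > 0 || recipe$kink_mean != 0)
      stats::rnorm(n, recipe$kink_mean, recipe$kink_sd) else rep(0, n)
    twists <- matrix(config$helix$twist, n, nsteps) +
      if (recipe$twist_jitter_sd > 0)
        matrix(stats::rnorm(n * nsteps, 0, recipe$twist_jitter_sd), n, nsteps)
      else 0
    twists[] <- pmin(pmax(twists, 1), 89)  # keep inside the builder's domain
    conformers <- vector("list", n)
    for (j in seq_len(n)) {
      pucker <- lapply(seq_len(nres), function(i)
        if (pucker_draw[j, i]) "C2-endo" else "C3-endo")
      names(pucker) <- colnames(pucker_draw)
      cf <- build_ideal_duplex(
        spec,
        twist = if (nsteps) twists[j, ] else config$helix$twist,
        pucker = pucker, config = config,
        bend = bend[j],
        open_pairs = which(open_draw[j, ])
      )
      if (recipe$noise_sd > 0) {
        na <- nrow(cf$atoms)
        cf$atoms$x <- cf$atoms$x + stats::rnorm(na, 0, recipe$noise_sd)
        cf$atoms$y <- cf$atoms$y + stats::rnorm(na, 0, recipe$noise_sd)
        cf$atoms$z <- cf$atoms$z + stats::rnorm(na, 0, recipe$noise_sd)
      }
      conformers[[j]] <- cf
    }
    rna_ensemble(conformers, spec = spec,
                 truth = list(pucker = pucker_draw, open = open_draw,
                              bend = bend, twist = twists,
                              recipe = recipe))
  })
}

#' Simulate a CLEANEX-PM build-up curve
#'
#' Model values from [cleanex_model()] plus i.i.d. Gaussian noise.
#'
#' @param kex,R1A,R1W model rates (1/s).
#' @param tau mixing times in seconds (default: the measurement schedule
#'   5, 10, 30, 40, 60, 80, 100 ms).
#' @param noise_sd Gaussian noise standard deviation on the ratio.
#' @param seed RNG seed.
#' @param variant model variant, see [cleanex_model()].
#' @return a [cleanex_curve()] with sigma recorded per point.
#' @export
simulate_cleanex <- function(kex, R1A, R1W,
                             tau = c(5, 10, 30, 40, 60, 80, 100) / 1000,
                             noise_sd = 0, seed = 1L,
                             variant = c("as-printed", "conventional")) {
  variant <- match.arg(variant)
  mu <- cleanex_model(tau, kex, R1A, R1W, variant)
  .with_seed(seed, {
    y <- mu + if (noise_sd > 0) stats::rnorm(length(tau), 0, noise_sd) else 0
    cleanex_curve(tau, y, sigma = if (noise_sd > 0) noise_sd else NA_real_)
  })
}

#' Simulate a noisy SAXS profile
#'
#' Debye back-calculation plus heteroscedastic Gaussian noise with
#' sigma(q) = a + b * I(q).
#'
#' @param x a `conformer` or `rna_ensemble`.
#' @param q scattering-vector grid in inverse Angstrom.
#' @param noise c(a, b) of the noise model (both >= 0, not both 0 for a
#'   noisy profile).
#' @param seed RNG seed.
#' @return a `saxs_profile` with sigma recorded.
#' @export
simulate_saxs <- function(x, q, noise = c(0, 0.01), seed = 1L) {
  if (length(noise) != 2 || any(noise < 0))
    stop("noise must be c(a, b) with a, b >= 0")
  prof <- debye_profile(x, q)
  sig <- noise[1] + noise[2] * prof$I
  .with_seed(seed, {
    I <- prof$I + if (any(sig > 0)) stats::rnorm(length(q), 0, sig) else 0
    saxs_profile(q, I, sigma = ifelse(sig > 0, sig, NA_real_))
  })
}
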