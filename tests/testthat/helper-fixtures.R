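# Shared fixtures: small duplexes and ensembles built in code.

rc_strand <- function(s) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

spec6 <- function() duplex_spec("GCAUGC", rc_strand("GCAUGC"))

spec10 <- function() duplex_spec("GGCAUAUGCC", rc_strand("GGCAUAUGCC"))

spec20_A <- function() example_duplex("A")
spec20_I <- function() example_duplex("I")

# a small fast ensemble for container-level tests
tiny_ensemble <- function(n = 6, seed = 11, ...) {
  generate_ensemble(ensemble_recipe(spec6(), n_conformers = n, seed = seed,
                                    ...))
}

# rigidly transform a conformer (rotation axis/angle + translation)
transform_conformer <- function(cf, axis = c(1, 2, 3), angle = 63,
                                shift = c(5, -3, 2)) {
  R <- rnaens:::rotation_matrix(axis, angle)
  X <- as.matrix(cf$atoms[, c("x", "y", "z")]) %*% t(R)
  cf$atoms$x <- X[, 1] + shift[1]
  cf$atoms$y <- X[, 2] + shift[2]
  cf$atoms$z <- X[, 3] + shift[3]
  cf
}
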