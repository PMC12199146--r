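#' Default pipeline configuration
#'
#' Central registry of every tunable constant in the package. All defaults
#' are documented in the methods vignette; functions take a `config` argument
#' so that no numeric convention is buried in code.
#'
#' Key groups:
#' \describe{
#'   \item{karplus}{Davies coefficients (Hz) for 3J(H1',H2') = A cos^2(phi) +
#'     B cos(phi) + C over the H1'-C1'-C2'-H2' dihedral.}
#'   \item{pucker}{Pseudorotation class boundaries in degrees: C3'-endo for
#'     P in [0, 36], C2'-endo for P in [144, 180], otherwise "other"; and the
#'     (P, numax) used when building each class.}
#'   \item{helix}{Idealized A-form parameters: rise (Angstrom), twist,
#'     inclination and x-displacement (degrees / Angstrom).}
#'   \item{backbone}{Exocyclic torsions (degrees) used by the nucleotide
#'     builder: glycosidic chi (anti), gamma (O5'-C5'-C4'-C3'),
#'     beta (P-O5'-C5'-C4').}
#'   \item{hbond}{Base-pair hydrogen-bond criteria: heavy-atom donor-acceptor
#'     distance cutoff (Angstrom) and minimum donor angle (degrees).}
#'   \item{sigma}{Default experimental uncertainties when data provide none:
#'     J couplings (Hz), NOE distances (Angstrom), and the fractional sigma
#'     applied to the prior <Rg^2> in maximum-entropy reweighting.}
#'   \item{gvector}{eRMSD-style G-vector parameters: anisotropic scaling of
#'     the base-base displacement (Angstrom) and the scaled cutoff.}
#'   \item{qt}{Quality-threshold clustering defaults: number of principal
#'     components, threshold quantile of pairwise distances when no absolute
#'     threshold is given, and minimum cluster population.}
#'   \item{maxent}{Error model ("gaussian" or "exact") and optimizer
#'     gradient tolerance.}
#'   \item{units}{`q_unit` of SAXS input grids, "A^-1" or "nm^-1".}
#' }
#'
#' @return a named list of configuration groups.
#' @export
default_config <- function() {
  list(
    karplus = list(A = 9.67, B = -2.03, C = 0.0),
    pucker = list(
      c3_range = c(0, 36), c2_range = c(144, 180),
      c3_build = c(P = 18, numax = 38),
      c2_build = c(P = 162, numax = 38)
    ),
    helix = list(rise = 2.81, twist = 32.7, inclination = 16.0, x_disp = -4.4),
    backbone = list(chi = -158, gamma = 54, beta = 180),
    hbond = list(dist_cutoff = 3.5, angle_min = 120),
    sigma = list(J = 0.5, noe = 0.5, rg2_frac = 0.05),
    gvector = list(scale_xy = 5.0, scale_z = 3.0, cutoff = 2.4),
    qt = list(n_components = 2, threshold_quantile = 0.10, min_population = 0.05),
    maxent = list(error_model = "gaussian", grad_tol = 1e-8),
    units = list(q_unit = "A^-1"),
    residue_aliases = c(I = "I", HPU = "I", INO = "I", RA = "A", RC = "C",
                        RG = "G", RU = "U", ADE = "A", CYT = "C", GUA = "G",
                        URA = "U", URI = "U")
  )
}

#' Validate a pipeline configuration
#'
#' Checks types, ranges and completeness of a configuration list; called by
#' every entry point that accepts `config`.
#'
#' @param config a list as returned by [default_config()]; missing groups are
#'   filled from the defaults.
#' @return the completed, validated configuration (invisibly usable).
#' @export
validate_config <- function(config = default_config()) {
  def <- default_config()
  if (!is.list(config)) stop("config must be a list")
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) stop("unknown config group(s): ", paste(unknown, collapse = ", "))
  for (g in names(def)) {
    if (is.null(config[[g]])) {
      config[[g]] <- def[[g]]
    } else if (g != "residue_aliases") {
      miss <- setdiff(names(def[[g]]), names(config[[g]]))
      config[[g]][miss] <- def[[g]][miss]
    }
  }
  with(config, {
    stopifnot(
      is.finite(karplus$A), is.finite(karplus$B), is.finite(karplus$C),
      karplus$A > 0,
      helix$rise > 0, helix$twist > 0, helix$twist < 90,
      hbond$dist_cutoff > 0, hbond$angle_min >= 0, hbond$angle_min <= 180,
      sigma$J > 0, sigma$noe > 0, sigma$rg2_frac > 0,
      gvector$scale_xy > 0, gvector$scale_z > 0, gvector$cutoff > 0,
      qt$n_components >= 1,
      qt$threshold_quantile > 0, qt$threshold_quantile < 1,
      qt$min_population >= 0, qt$min_population <= 1,
      maxent$error_model %in% c("gaussian", "exact"),
      maxent$grad_tol > 0,
      units$q_unit %in% c("A^-1", "nm^-1")
    )
  })
  config
}

#' Read a configuration file
#'
#' JSON is the native format (always available); YAML is accepted when the
#' optional yaml package is installed.
#'
#' @param path path to a .json or .yaml/.yml configuration file.
#' @return a validated configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML config requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_config(raw)
}

# Stable hash of a configuration (provenance logging). Uses the md5 of the
# canonical JSON serialization.
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
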