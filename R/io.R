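# File formats: multi-model PDB (one MODEL per conformer), CSV tables for
# observables, restraints, curves and weights. All readers tolerate CRLF
# line endings and flexible whitespace; malformed records are reported with
# their line numbers.

#' Write a conformer or ensemble as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per conformer; strand 1 is chain A, strand 2 chain
#' B. Residue codes are written as-is (inosine as "I"); atom names are
#' emitted in standard PDB alignment.
#'
#' @param x a `conformer` or `rna_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  ens <- if (inherits(x, "rna_ensemble")) x else rna_ensemble(list(as_conformer(x)))
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(ens$conformers)) {
    at <- ens$conformers[[m]]$atoms
    writeLines(sprintf("MODEL     %4d", m), con)
    chain <- c("A", "B")[at$strand]
    name4 <- vapply(at$atom, function(a) {
      if (nchar(a) >= 4) substr(a, 1, 4) else sprintf(" %-3s", a)
    }, character(1))
    elem <- toupper(substr(gsub("[0-9']", "", at$atom), 1, 1))
    lines <- sprintf(
      "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)), name4, substr(at$resname, 1, 3), chain, at$res,
      at$x, at$y, at$z, 1, 0, elem)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file as an ensemble
#'
#' Parses ATOM/HETATM records; each MODEL becomes one conformer (a file
#' without MODEL records yields a single conformer). Residue names are
#' mapped through `config$residue_aliases` (e.g. "HPU"/"INO" -> "I"); atom
#' names are preserved verbatim. Chains map to strands in order of first
#' appearance.
#'
#' @param path PDB file.
#' @param config pipeline configuration (residue alias map).
#' @return an `rna_ensemble`.
#' @export
read_pdb <- function(path, config = default_config()) {
  config <- validate_config(config)
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  rec <- substr(lines, 1, 6)
  models <- list()
  cur <- NULL
  lineno <- 0
  flush_model <- function(cur) {
    if (!is.null(cur) && length(cur$res)) {
      models[[length(models) + 1]] <<- as.data.frame(cur)
    }
  }
  cur <- list(res = integer(), resname = character(), atom = character(),
              x = numeric(), y = numeric(), z = numeric(),
              chain = character())
  empty <- cur
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (r == "MODEL ") {
      flush_model(cur)
      cur <- empty
    } else if (startsWith(r, "ATOM") || r == "HETATM") {
      l <- lines[i]
      if (nchar(l) < 54)
        stop("malformed ATOM record at line ", i, ": too short")
      xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38),
                                           substr(l, 39, 46),
                                           substr(l, 47, 54))))
      resno <- suppressWarnings(as.integer(substr(l, 23, 26)))
      if (any(is.na(xyz)) || is.na(resno))
        stop("malformed ATOM record at line ", i, ": unparsable fields")
      cur$res <- c(cur$res, resno)
      cur$resname <- c(cur$resname, trimws(substr(l, 18, 20)))
      cur$atom <- c(cur$atom, trimws(substr(l, 13, 16)))
      cur$x <- c(cur$x, xyz[1]); cur$y <- c(cur$y, xyz[2])
      cur$z <- c(cur$z, xyz[3])
      cur$chain <- c(cur$chain, substr(l, 22, 22))
    }
  }
  flush_model(cur)
  if (!length(models)) stop("no ATOM records found in ", path)
  alias <- config$residue_aliases
  conformers <- lapply(models, function(df) {
    rn <- df$resname
    mapped <- alias[rn]
    df$resname <- ifelse(is.na(mapped), rn, mapped)
    chains <- unique(df$chain)
    df$strand <- match(df$chain, chains)
    df$chain <- NULL
    new_conformer(df)
  })
  rna_ensemble(conformers)
}

# ---- tables -------------------------------------------------------------

# tolerant delimited reader: comma or whitespace separated, CRLF-safe
.read_table_any <- function(path, col_names) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("empty table: ", path)
  sep <- if (grepl(",", lines[1])) "," else ""
  df <- utils::read.table(text = paste0(paste(lines, collapse = "\n"), "\n"),
                          header = .has_header(lines[1]),
                          sep = sep, strip.white = TRUE, quote = "",
                          stringsAsFactors = FALSE)
  if (!.has_header(lines[1])) {
    if (ncol(df) < length(col_names))
      stop(path, ": expected at least ", length(col_names), " columns (",
           paste(col_names, collapse = ", "), "), found ", ncol(df))
    names(df)[seq_along(col_names)] <- col_names
  }
  df
}

.has_header <- function(line) {
  fields <- strsplit(trimws(line), "[,[:space:]]+")[[1]]
  any(is.na(suppressWarnings(as.numeric(fields))))
}

#' Read a SAXS profile from a three-column text file
#'
#' Accepts comma- or whitespace-separated q, I, sigma columns (with or
#' without a header). A file without an uncertainty column is rejected with
#' an explicit format error, since fitting requires sigma.
#'
#' @param path input file.
#' @param q_unit unit of the q column.
#' @return a `saxs_profile`.
#' @export
read_saxs <- function(path, q_unit = c("A^-1", "nm^-1")) {
  q_unit <- match.arg(q_unit)
  df <- .read_table_any(path, c("q", "I", "sigma"))
  if (ncol(df) < 3 || !"sigma" %in% names(df) && ncol(df) == 2)
    stop("SAXS file ", path,
         " lacks the sigma column (need three columns: q, I, sigma)")
  nm <- names(df)
  qc <- if ("q" %in% nm) df$q else df[[1]]
  Ic <- if ("I" %in% nm) df$I else df[[2]]
  sc <- if ("sigma" %in% nm) df$sigma else df[[3]]
  saxs_profile(qc, Ic, sc, q_unit = q_unit)
}

#' Write a SAXS profile
#' @param profile a `saxs_profile`.
#' @param path output CSV file (columns q, I, sigma).
#' @return `path`, invisibly.
#' @export
write_saxs <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Read experimental J couplings (CSV: res, J[, sigma])
#' @param path input file.
#' @return data.frame with res, J and sigma columns (sigma NA when absent).
#' @export
read_couplings <- function(path) {
  df <- .read_table_any(path, c("res", "J"))
  if (!all(c("res", "J") %in% names(df)))
    stop("coupling table needs columns res, J")
  if (!"sigma" %in% names(df)) df$sigma <- NA_real_
  df[, c("res", "J", "sigma")]
}

#' Read NOE restraints (CSV: res1, atom1, res2, atom2, bin)
#' @param path input file.
#' @return a `noe_restraints` table.
#' @export
read_noe <- function(path) {
  df <- .read_table_any(path, c("res1", "atom1", "res2", "atom2", "bin"))
  need <- c("res1", "atom1", "res2", "atom2", "bin")
  if (!all(need %in% names(df)))
    stop("NOE table needs columns ", paste(need, collapse = ", "))
  bad <- which(!df$bin %in% names(.noe_bins))
  if (length(bad))
    stop("unknown NOE bin at row(s) ", paste(bad, collapse = ", "),
         " (allowed: ", paste(names(.noe_bins), collapse = ", "), ")")
  noe_restraints(df$res1, df$atom1, df$res2, df$atom2, df$bin)
}

#' Read a CLEANEX build-up curve (CSV: tau_s, ratio[, sigma])
#' @param path input file.
#' @return a `cleanex_curve`.
#' @export
read_cleanex <- function(path) {
  df <- .read_table_any(path, c("tau_s", "ratio"))
  nm <- names(df)
  tau <- if ("tau_s" %in% nm) df$tau_s else df[[1]]
  ratio <- if ("ratio" %in% nm) df$ratio else df[[2]]
  sigma <- if ("sigma" %in% nm) df$sigma else NA_real_
  cleanex_curve(tau, ratio, sigma)
}

#' Write / read an observable matrix as CSV
#'
#' The matrix round-trips with conformer rows and labelled observable
#' columns; targets and sigma are stored in two trailing rows keyed by the
#' first column.
#'
#' @param obs an [observable_matrix()].
#' @param path CSV path.
#' @return `path` / the restored `observable_matrix`.
#' @export
write_observable_matrix <- function(obs, path) {
  df <- data.frame(row = c(seq_len(nrow(obs$values)), ".target", ".sigma"))
  for (j in seq_along(obs$labels))
    df[[obs$labels[j]]] <- c(obs$values[, j], obs$targets[j], obs$sigma[j])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observable_matrix
#' @export
read_observable_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  key <- as.character(df[[1]])
  it <- match(".target", key)
  is <- match(".sigma", key)
  if (is.na(it) || is.na(is))
    stop("observable matrix file lacks .target/.sigma rows: ", path)
  vals <- as.matrix(df[-c(it, is), -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- NULL
  observable_matrix(vals,
                    targets = as.numeric(df[it, -1]),
                    sigma = as.numeric(df[is, -1]),
                    labels = names(df)[-1])
}

#' Write reweighting results as CSV
#'
#' Two files: `<stem>_weights.csv` (conformer, prior, weight) and
#' `<stem>_lambda.csv` (observable, lambda, target, achieved).
#'
#' @param wv a `weight_vector` from [reweight()].
#' @param stem output path stem.
#' @param prior prior weights recorded alongside (default uniform).
#' @return character vector of the two paths, invisibly.
#' @export
write_weights <- function(wv, stem, prior = NULL) {
  n <- length(wv$w)
  if (is.null(prior)) prior <- rep(1 / n, n)
  p1 <- paste0(stem, "_weights.csv")
  p2 <- paste0(stem, "_lambda.csv")
  utils::write.csv(data.frame(conformer = seq_len(n), prior = prior,
                              weight = wv$w), p1, row.names = FALSE)
  utils::write.csv(data.frame(observable = names(wv$lambda),
                              lambda = as.numeric(wv$lambda),
                              target = as.numeric(wv$targets),
                              achieved = as.numeric(wv$achieved)),
                   p2, row.names = FALSE)
  invisible(c(p1, p2))
}
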