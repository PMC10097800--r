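#' Write a stress field to a delimited text file
#'
#' Emulates a flow-solver export: a format-version line, metadata lines
#' (label, flow rate in m^3/s), then one CSV row per finite volume with
#' `cell_id,volume,tau_eff` in SI units. Numbers are written with 17
#' significant digits, so a write/read round trip is lossless.
#'
#' @param field A [stress_field].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "stress_field"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# hemofield v1",
               sprintf("# label: %s", field$label),
               sprintf("# Q_m3_per_s: %.17g", field$Q),
               "cell_id,volume,tau_eff"), con)
  writeLines(sprintf("%d,%.17g,%.17g", seq_along(field$tau),
                     field$volumes, field$tau), con)
  invisible(path)
}

#' Read a stress field from a delimited text file
#'
#' Accepts the two declared schemas: `cell_id,volume,tau_eff` (stresses
#' precomputed by the exporter, the default path) or
#' `cell_id,volume,sij_sq_mean,eps_mod` (raw RANS kinematics, requiring
#' the fluid's `mu` and `rho` to assemble the effective stress). Rejects
#' unknown format versions, malformed or non-finite rows, and negative
#' volumes or stresses, reporting the offending line number.
#'
#' @param path Input file path.
#' @param Q Flow rate in m^3/s; overrides the file metadata when given.
#' @param mu,rho Fluid viscosity (Pa s) and density (kg/m^3); required for
#'   the kinematics schema.
#' @param label Field label; overrides the file metadata when given.
#' @return A [stress_field].
#' @export
read_field <- function(path, Q = NULL, mu = NULL, rho = NULL, label = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("field file '%s' does not exist", path), call. = FALSE)
  }
  lines <- readLines(path)
  if (length(lines) == 0L || !identical(lines[1], "# hemofield v1")) {
    stop(sprintf("'%s': unknown or missing format version (expected '# hemofield v1' on line 1)",
                 path), call. = FALSE)
  }
  meta <- list()
  i <- 2L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    m <- regmatches(lines[i], regexec("^#\\s*([A-Za-z0-9_]+):\\s*(.*)$", lines[i]))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
    i <- i + 1L
  }
  if (i > length(lines)) stop(sprintf("'%s': no data section", path), call. = FALSE)
  header <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
  schema_tau <- c("cell_id", "volume", "tau_eff")
  schema_kin <- c("cell_id", "volume", "sij_sq_mean", "eps_mod")
  if (identical(header, schema_tau)) {
    kin <- FALSE
  } else if (identical(header, schema_kin)) {
    kin <- TRUE
    if (is.null(mu) || is.null(rho)) {
      stop(sprintf("'%s': kinematics schema requires `mu` and `rho`", path),
           call. = FALSE)
    }
  } else {
    stop(sprintf("'%s' line %d: unrecognized header '%s'", path, i, lines[i]),
         call. = FALSE)
  }
  data_lines <- lines[-seq_len(i)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) == 0L) {
    stop(sprintf("'%s': empty data section", path), call. = FALSE)
  }
  parts <- strsplit(data_lines, ",", fixed = TRUE)
  ncols <- length(header)
  for (j in seq_along(parts)) {
    ln <- i + j
    if (length(parts[[j]]) != ncols) {
      stop(sprintf("'%s' line %d: expected %d fields, got %d", path, ln,
                   ncols, length(parts[[j]])), call. = FALSE)
    }
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = ncols,
                byrow = TRUE)
  bad <- which(!stats::complete.cases(mat) | !is.finite(rowSums(mat)))
  if (length(bad)) {
    stop(sprintf("'%s' line %d: non-numeric or non-finite value", path,
                 i + bad[1]), call. = FALSE)
  }
  vol <- mat[, 2]
  if (any(vol <= 0)) {
    stop(sprintf("'%s' line %d: non-positive cell volume", path,
                 i + which(vol <= 0)[1]), call. = FALSE)
  }
  if (kin) {
    if (any(mat[, 3] < 0) || any(mat[, 4] < 0)) {
      bad <- which(mat[, 3] < 0 | mat[, 4] < 0)[1]
      stop(sprintf("'%s' line %d: negative sij_sq_mean or eps_mod", path,
                   i + bad), call. = FALSE)
    }
    tau <- sqrt(2 * mu^2 * mat[, 3] + rho * mu * mat[, 4])
  } else {
    tau <- mat[, 3]
    if (any(tau < 0)) {
      stop(sprintf("'%s' line %d: negative stress", path,
                   i + which(tau < 0)[1]), call. = FALSE)
    }
  }
  if (is.null(Q)) {
    if (is.null(meta$Q_m3_per_s)) {
      stop(sprintf("'%s': flow rate missing (no Q_m3_per_s metadata and no `Q` argument)",
                   path), call. = FALSE)
    }
    Q <- as.numeric(meta$Q_m3_per_s)
  }
  if (is.null(label)) label <- if (!is.null(meta$label)) meta$label else "field"
  stress_field(vol, tau, Q, label)
}

#' Write a constant repository to CSV
#'
#' Columns `lnC,C,alpha,beta,eta,r,Fn` under a format-version header; both
#' ln C and C are stored so plotting and solver use are each one read away.
#' Deterministic formatting (17 significant digits) makes equal
#' repositories byte-identical on disk.
#'
#' @param tab A `constant_repository` data.frame (see [repository_table()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_repository <- function(tab, path) {
  stopifnot(all(c("lnC", "C", "alpha", "beta", "eta", "r", "Fn") %in%
                  names(tab)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# hemorepo v1", "lnC,C,alpha,beta,eta,r,Fn"), con)
  writeLines(sprintf("%.17g,%.17g,%.17g,%.17g,%.17g,%.17g,%.17g",
                     tab$lnC, tab$C, tab$alpha, tab$beta, tab$eta, tab$r,
                     tab$Fn), con)
  invisible(path)
}

#' Read a constant repository from CSV
#'
#' @param path File written by [write_repository()].
#' @return `data.frame` with columns `lnC,C,alpha,beta,eta,r,Fn`.
#' @export
read_repository <- function(path) {
  lines <- readLines(path, n = 1L)
  if (!identical(lines, "# hemorepo v1")) {
    stop(sprintf("'%s': unknown or missing format version", path),
         call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("lnC", "C", "alpha", "beta", "eta", "r", "Fn")
  if (!all(need %in% names(df))) {
    stop(sprintf("'%s': missing repository columns", path), call. = FALSE)
  }
  df
}

#' Load the packaged experimental fixtures
#'
#' Returns the six built-in constant sets and the twelve experimental
#' operating points (three nozzle, five pump, four capillary-tube flows)
#' with their printed flow rates, central MIH values and uncertainties.
#' The operating-point records carry **no stress fields** (`field = NULL`,
#' flagged by `has_field`): the CFD exports behind the published numbers
#' are not distributable, so these records support fitness arithmetic on
#' user-supplied or synthetic fields only.
#'
#' @return List with `constant_sets` (named list of [constant_set]),
#'   `operating_points` (list of [op_record], no fields),
#'   `operating_point_table` (the raw fixture `data.frame` including fluid
#'   properties) and `reference_fitness` (see [reference_fitness_table()]).
#' @export
load_paper_fixtures <- function() {
  path <- system.file("extdata", "operating_points.csv", package = "hemopso",
                      mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  records <- lapply(seq_len(nrow(df)), function(i) {
    rec <- op_record(df$label[i], df$mih_exp[i], df$mih_unc[i],
                     field = NULL, group = df$group[i])
    rec$flow_lmin <- df$flow_lmin[i]
    rec$has_field <- FALSE
    rec
  })
  names(records) <- df$label
  list(constant_sets = builtin_constant_sets(),
       operating_points = records,
       operating_point_table = df,
       reference_fitness = reference_fitness_table())
}

#' Published fitness scores of the named constant sets
#'
#' Reference fixture: mean dead-band error eta, modified correlation r,
#' overall fitness Fn, number of operating points inside their uncertainty
#' bands (NiB, of 12) and unmodified Pearson correlations (all points and
#' per test case) as published for the six named constant sets, evaluated
#' on CFD stress fields that are not reconstructible at desk scale.
#'
#' @return `data.frame` with one row per constant set.
#' @export
reference_fitness_table <- function() {
  data.frame(
    set   = c("FT-M", "FT-L", "GW", "HO", "ZT", "FZ"),
    eta   = c(0.34, 0.32, 0.86, 0.58, 0.75, 0.57),
    r     = c(0.32, 0.53, 0.53, 0.62, 0.55, 0.64),
    NiB   = c(7, 7, 0, 2, 0, 2),
    Fn    = c(0.33, 0.43, 0.69, 0.60, 0.65, 0.61),
    R_all = c(0.68, 0.47, 0.47, 0.38, 0.45, 0.36),
    R_ct  = c(0.99, 0.90, 0.92, 0.90, 0.90, 0.90),
    R_nozzle = c(0.99, 0.99, 0.99, 0.91, 0.98, 0.88),
    R_pump   = c(0.40, 0.47, 0.44, 0.43, 0.44, 0.43),
    stringsAsFactors = FALSE
  )
}
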