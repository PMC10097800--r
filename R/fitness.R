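#' Experimental operating-point record
#'
#' One device/flow-rate combination with its measured hemolysis: the
#' central experimental MIH, a symmetric uncertainty half-width, and the
#' resulting dead-band bounds. The lower bound is clamped at zero when the
#' uncertainty exceeds the central value (e.g. the 6LGC nozzle point
#' 0.02 +/- 0.13), so there any non-negative prediction below the upper
#' bound is in-bounds. Optionally carries the stress field that a numerical
#' prediction for this point must be computed on.
#'
#' @param label Identifier, e.g. `"ct4500"`.
#' @param mih_exp Central experimental MIH (> 0).
#' @param mih_unc Symmetric uncertainty half-width (>= 0).
#' @param field Optional [stress_field] for this operating point.
#' @param group Optional test-case group label (e.g. `"nozzle"`, `"pump"`,
#'   `"ct"`) used for subset correlation diagnostics.
#' @return An object of class `op_record`.
#' @export
op_record <- function(label, mih_exp, mih_unc, field = NULL, group = NA_character_) {
  check_scalar_number(mih_exp, "mih_exp", positive = TRUE)
  check_scalar_number(mih_unc, "mih_unc", nonneg = TRUE)
  if (!is.null(field)) stopifnot(inherits(field, "stress_field"))
  structure(list(label = as.character(label), mih_exp = mih_exp,
                 mih_unc = mih_unc,
                 mih_exp_min = max(0, mih_exp - mih_unc),
                 mih_exp_max = mih_exp + mih_unc,
                 field = field, group = as.character(group)),
            class = "op_record")
}

#' @export
print.op_record <- function(x, ...) {
  cat(sprintf("<op_record> %s: MIH_exp = %g +/- %g [%g, %g]%s%s\n",
              x$label, x$mih_exp, x$mih_unc, x$mih_exp_min, x$mih_exp_max,
              if (!is.na(x$group)) paste0(", group ", x$group) else "",
              if (is.null(x$field)) ", no field" else ""))
  invisible(x)
}

#' Dead-band prediction error for one operating point
#'
#' The per-point objective contribution:
#' \deqn{\xi = \left|\frac{1}{|\ln(MIH_{num}/MIH_{exp})| + 1} - 1\right|}
#' when the prediction falls outside the experimental uncertainty band, and
#' 0 inside it (bounds inclusive). The log-ratio always uses the central
#' experimental value. The error is bounded: it tends to 1 as the ratio
#' goes to 0 or infinity, and a prediction of exactly 0 outside the band
#' scores the limit value 1.
#'
#' @param mih_num Predicted MIH values (vectorized, >= 0; `Inf` allowed as
#'   the limit).
#' @param rec An [op_record], or a number taken as the central `mih_exp`
#'   with zero uncertainty.
#' @param mih_unc Uncertainty half-width when `rec` is given as a number.
#' @return Error values in [0, 1].
#' @export
#' @examples
#' xi_error(0.29, op_record("5LSC", 0.29, 0.25)) # in-band: 0
#' xi_error(7.0, op_record("6LGC", 0.02, 0.13))  # ~0.854
xi_error <- function(mih_num, rec, mih_unc = 0) {
  if (!inherits(rec, "op_record")) {
    rec <- op_record("ad-hoc", rec, mih_unc)
  }
  if (any(is.na(mih_num)) || any(mih_num < 0)) {
    stop("`mih_num` must be >= 0", call. = FALSE)
  }
  xi_error_log(ifelse(mih_num > 0, log(mih_num), -Inf), rec)
}

# log-domain variant used by the optimizer: ln_mih may be -Inf (MIH = 0)
# or +Inf; band check and log-ratio computed without leaving log space.
xi_error_log <- function(ln_mih, rec) {
  ln_lo <- if (rec$mih_exp_min > 0) log(rec$mih_exp_min) else -Inf
  ln_hi <- log(rec$mih_exp_max)
  in_band <- ln_mih >= ln_lo & ln_mih <= ln_hi
  a <- abs(ln_mih - log(rec$mih_exp))
  xi <- ifelse(is.finite(a), abs(1 / (a + 1) - 1), 1)
  ifelse(in_band, 0, xi)
}

#' Mean dead-band error over operating points
#'
#' eta = mean(xi_i): the first optimization objective, a bounded
#' representation of the relative mean error over all N operating points.
#'
#' @param xi Vector of per-point errors (non-empty).
#' @return Mean error eta in [0, 1].
#' @export
mean_error <- function(xi) {
  if (length(xi) == 0L) stop("`xi` must be non-empty", call. = FALSE)
  mean(xi)
}

#' Modified correlation objective
#'
#' r = |Pearson(A, B) - 1| with the sample (N-1) normalization: 0 for a
#' perfect positive correlation, 2 for a perfect negative one. The second
#' optimization objective, with A the predicted and B the experimental MIH
#' values. A degenerate sample (zero standard deviation in either input)
#' returns the worst value 2 with a warning rather than failing, so a
#' running optimization can continue past a constant-prediction particle.
#'
#' @param A,B Equal-length numeric vectors, length >= 2.
#' @return r in [0, 2].
#' @export
#' @examples
#' modified_correlation(1:5, 1:5)   # 0
#' modified_correlation(1:3, 3:1)   # 2
modified_correlation <- function(A, B) {
  if (length(A) != length(B) || length(A) < 2L) {
    stop("`A` and `B` must have equal length >= 2", call. = FALSE)
  }
  if (stats::sd(A) == 0 || stats::sd(B) == 0) {
    warning("zero variance in correlation input; returning worst value 2")
    return(2)
  }
  abs(stats::cor(A, B) - 1)
}

#' Overall scalar fitness
#'
#' F_n = (eta + r)/2, the scalar used to rank Pareto-repository particles;
#' 0 reflects a perfect match between predicted and measured hemolysis.
#'
#' @param eta Mean dead-band error (>= 0).
#' @param r Modified correlation (>= 0).
#' @return F_n.
#' @export
overall_fitness <- function(eta, r) {
  stopifnot(all(eta >= 0), all(r >= 0))
  (eta + r) / 2
}

#' Evaluate constant sets against experimental operating points
#'
#' For each constant set, predicts MIH on every record's stress field via
#' the discrete volume integral, then assembles the full fitness report:
#' per-point errors xi, mean error eta, modified correlation r (predicted
#' vs central experimental MIH), overall fitness F_n, the number of points
#' inside their uncertainty bands (NiB), and unmodified Pearson
#' correlations per test-case group (NA for groups with fewer than two
#' points or degenerate variance).
#'
#' @param sets List of [constant_set] objects (or one).
#' @param records List of [op_record] objects, each carrying a field.
#' @return `data.frame` (class `fitness_report`) with one row per set and
#'   columns `set`, `eta`, `r`, `Fn`, `NiB`, `R_all` plus one `R_<group>`
#'   column per group; the per-point error matrix is in attribute `"xi"`
#'   and the predicted MIH matrix in attribute `"mih"` (sets x records).
#' @export
evaluate_fitness <- function(sets, records) {
  if (inherits(sets, "constant_set")) sets <- list(sets)
  if (inherits(records, "op_record")) records <- list(records)
  stopifnot(length(sets) >= 1L, length(records) >= 1L)
  for (rec in records) {
    if (is.null(rec$field)) {
      stop(sprintf("record '%s' has no stress field attached", rec$label),
           call. = FALSE)
    }
  }
  pres <- lapply(records, function(r) mih_precompute(r$field))
  nset <- length(sets); nrec <- length(records)
  ln_mih <- matrix(NA_real_, nset, nrec,
                   dimnames = list(vapply(sets, `[[`, character(1), "name"),
                                   vapply(records, `[[`, character(1), "label")))
  for (si in seq_len(nset)) {
    k <- sets[[si]]
    for (ri in seq_len(nrec)) {
      ln_mih[si, ri] <- mih_log_from_pre(pres[[ri]], k$C, k$alpha, k$beta)
    }
  }
  xi <- ln_mih
  for (ri in seq_len(nrec)) {
    xi[, ri] <- xi_error_log(ln_mih[, ri], records[[ri]])
  }
  B <- vapply(records, `[[`, numeric(1), "mih_exp")
  groups <- vapply(records, `[[`, character(1), "group")
  r_mod <- numeric(nset); Rall <- numeric(nset)
  for (si in seq_len(nset)) {
    A <- exp(ln_mih[si, ])
    r_mod[si] <- if (nrec >= 2L) {
      suppressWarnings(modified_correlation(A, B))
    } else 2
    Rall[si] <- safe_pearson(A, B)
  }
  eta <- unname(rowMeans(xi))
  out <- data.frame(set = rownames(ln_mih), eta = eta, r = r_mod,
                    Fn = overall_fitness(eta, r_mod),
                    NiB = unname(as.integer(rowSums(xi == 0))), R_all = Rall,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (g in unique(groups[!is.na(groups)])) {
    idx <- which(groups == g)
    out[[paste0("R_", g)]] <- vapply(seq_len(nset), function(si) {
      safe_pearson(exp(ln_mih[si, idx]), B[idx])
    }, numeric(1))
  }
  attr(out, "xi") <- xi
  attr(out, "mih") <- exp(ln_mih)
  class(out) <- c("fitness_report", "data.frame")
  out
}

safe_pearson <- function(A, B) {
  if (length(A) < 2L || stats::sd(A) == 0 || stats::sd(B) == 0 ||
      any(!is.finite(A))) {
    return(NA_real_)
  }
  stats::cor(A, B)
}
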