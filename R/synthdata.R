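#' Lognormal synthetic stress field
#'
#' Emulates the right-skewed stress distribution of a device flow export:
#' per-cell stresses are lognormal(mu, sd^2) and the cell volumes are equal
#' shares of the total volume. A pure function of its seed and parameters:
#' the caller's RNG state is left untouched.
#'
#' @param n_cells Number of cells (>= 1).
#' @param mu_log_tau Mean of ln(tau) (tau in Pa).
#' @param sd_log_tau Standard deviation of ln(tau) (>= 0; 0 gives a
#'   uniform-stress field).
#' @param total_volume Total field volume, m^3 (> 0).
#' @param Q Flow rate, m^3/s (> 0).
#' @param seed RNG seed.
#' @param label Field label.
#' @return A [stress_field].
#' @export
gen_lognormal_field <- function(n_cells, mu_log_tau, sd_log_tau,
                                total_volume, Q, seed = 1L,
                                label = "lognormal") {
  stopifnot(n_cells >= 1, sd_log_tau >= 0)
  check_scalar_number(total_volume, "total_volume", positive = TRUE)
  check_scalar_number(Q, "Q", positive = TRUE)
  tau <- with_seed(seed, exp(stats::rnorm(n_cells, mu_log_tau, sd_log_tau)))
  stress_field(rep(total_volume / n_cells, n_cells), tau, Q, label)
}

#' Specification of a synthetic parameter-recovery study
#'
#' States the world a synthetic experiment lives in: the true constant set
#' that generated the data, the stress fields of the operating points, the
#' relative half-width of the experimental uncertainty bands and the
#' lognormal measurement noise on the central values.
#'
#' @param true_constants A [constant_set]; ground truth.
#' @param fields List of [stress_field] objects, one per operating point.
#' @param uncertainty_fraction Relative half-width of the bands (>= 0).
#' @param noise_sd_log SD of the multiplicative lognormal noise on MIH_exp
#'   (>= 0; MIH is positive and spans decades, so noise is multiplicative).
#' @param seed RNG seed for the noise draws.
#' @return An object of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(true_constants, fields,
                                 uncertainty_fraction = 0.1,
                                 noise_sd_log = 0, seed = 1L) {
  stopifnot(inherits(true_constants, "constant_set"),
            length(fields) >= 1L,
            all(vapply(fields, inherits, logical(1), "stress_field")),
            uncertainty_fraction >= 0, noise_sd_log >= 0)
  structure(list(true_constants = true_constants, fields = fields,
                 uncertainty_fraction = uncertainty_fraction,
                 noise_sd_log = noise_sd_log, seed = seed),
            class = "synthetic_study_spec")
}

#' Generate synthetic experimental records from a study spec
#'
#' For each field, the central experimental MIH is the true model's volume-
#' integral prediction times a lognormal noise factor, and the band
#' half-width is `uncertainty_fraction` of the central value. With zero
#' noise the truth lies inside every band, so the true constant set scores
#' eta = 0 with all points in bounds — the closed-loop recovery oracle.
#'
#' @param spec A [synthetic_study_spec].
#' @return List of [op_record] objects with fields attached.
#' @export
gen_experiment <- function(spec) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  n <- length(spec$fields)
  noise <- with_seed(spec$seed,
                     exp(stats::rnorm(n, 0, spec$noise_sd_log)))
  lapply(seq_len(n), function(i) {
    f <- spec$fields[[i]]
    mih <- mih_volume_integral(f, spec$true_constants) * noise[i]
    op_record(f$label, mih, spec$uncertainty_fraction * mih,
              field = f, group = "synthetic")
  })
}

#' Rescale a stress field to hit a target MIH
#'
#' Multiplies all stresses by f = (MIH_target / MIH_current)^(1/alpha);
#' by the homogeneity MIH(f tau) = f^alpha MIH(tau), the scaled field
#' yields exactly the target under the given constant set. Inverse-design
#' helper for constructing fields with prescribed hemolysis.
#'
#' @param field A [stress_field] with at least one positive stress.
#' @param k A [constant_set].
#' @param mih_target Target MIH (> 0).
#' @return The rescaled [stress_field].
#' @export
scale_field_to_target <- function(field, k, mih_target) {
  stopifnot(inherits(field, "stress_field"), inherits(k, "constant_set"))
  check_scalar_number(mih_target, "mih_target", positive = TRUE)
  if (all(field$tau == 0)) {
    stop("field has no positive stresses; cannot rescale", call. = FALSE)
  }
  ln_cur <- mih_volume_integral(field, k, log = TRUE)
  ln_f <- (log(mih_target) - ln_cur) / k$alpha
  stress_field(field$volumes, field$tau * exp(ln_f), field$Q, field$label)
}

#' Blasius friction factor for turbulent pipe flow
#'
#' lambda = 0.316 / Re^0.25, the smooth-pipe correlation used to validate
#' capillary-tube pressure losses.
#'
#' @param Re Reynolds number (> 0, vectorized).
#' @return Friction factor lambda.
#' @export
#' @examples
#' blasius_friction(1e4) # 0.0316
blasius_friction <- function(Re) {
  if (any(!is.finite(Re)) || any(Re <= 0)) {
    stop("`Re` must be finite and > 0", call. = FALSE)
  }
  0.316 / Re^0.25
}

#' Relative deviation of a simulated from an experimental value
#'
#' 100 * (sim - exp) / exp, in percent.
#'
#' @param sim_value Simulated value.
#' @param exp_value Experimental reference (nonzero).
#' @return Percent deviation.
#' @export
relative_deviation <- function(sim_value, exp_value) {
  if (any(exp_value == 0)) stop("`exp_value` must be nonzero", call. = FALSE)
  100 * (sim_value - exp_value) / exp_value
}
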