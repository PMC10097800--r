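#' Power-law constant set (C, alpha, beta)
#'
#' A stress-based hemolysis model is the empirical power law
#' \deqn{H(\tau_s, t) = C \tau_s^{\alpha} t^{\beta},}
#' where `H` is the released-to-total hemoglobin ratio, `tau_s` an
#' equivalent scalar stress in Pa and `t` the exposure time in s. A
#' `constant_set` bundles one (C, alpha, beta) triple with a provenance
#' label; it is the decision variable of the swarm optimizer.
#'
#' Units: C carries Pa^-alpha s^-beta so that H is dimensionless; alpha and
#' beta are dimensionless exponents.
#'
#' @param name Short label, e.g. `"HO"`.
#' @param C Power-law prefactor, must be > 0.
#' @param alpha Stress exponent, must be > 0.
#' @param beta Time exponent, must be > 0.
#' @return An object of class `constant_set`.
#' @export
#' @examples
#' constant_set("HO", 1.8e-8, 1.991, 0.765)
constant_set <- function(name, C, alpha, beta) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  check_scalar_number(C, "C", positive = TRUE)
  check_scalar_number(alpha, "alpha", positive = TRUE)
  check_scalar_number(beta, "beta", positive = TRUE)
  structure(list(name = name, C = C, alpha = alpha, beta = beta),
            class = "constant_set")
}

#' @export
print.constant_set <- function(x, ...) {
  cat(sprintf("<constant_set> %s: C = %.4g, alpha = %.4f, beta = %.4f\n",
              x$name, x$C, x$alpha, x$beta))
  invisible(x)
}

#' Built-in power-law constant sets
#'
#' The four literature sets (GW Giersiepen-Wurzinger, HO Heuser-Opitz,
#' ZT Zhang-Taskin, FZ Fraser-Zhang) plus the two swarm-optimized sets
#' FT-M (mathematical search domain; numerically extreme, unusable inside
#' flow solvers due to floating-point limits) and FT-L (literature search
#' domain). Values are frozen fixtures.
#'
#' @return Named list of [constant_set] objects.
#' @export
#' @examples
#' builtin_constant_sets()[["HO"]]
builtin_constant_sets <- function() {
  sets <- list(
    constant_set("GW",   3.62e-7,  2.416,   0.785),
    constant_set("HO",   1.8e-8,   1.991,   0.765),
    constant_set("ZT",   1.228e-7, 1.9918,  0.6606),
    constant_set("FZ",   1.745e-8, 1.963,   0.7762),
    constant_set("FT-M", 4.256e-24, 10.2860, 2.8073),
    constant_set("FT-L", 1.000e-9, 1.8277,  0.5392)
  )
  stats::setNames(sets, vapply(sets, `[[`, character(1), "name"))
}

#' Look up a built-in constant set by name
#'
#' @param name One of `"GW"`, `"HO"`, `"ZT"`, `"FZ"`, `"FT-M"`, `"FT-L"`.
#' @return A [constant_set].
#' @export
get_constant_set <- function(name) {
  sets <- builtin_constant_sets()
  if (!name %in% names(sets)) {
    stop(sprintf("unknown constant set '%s'; available: %s", name,
                 paste(names(sets), collapse = ", ")), call. = FALSE)
  }
  sets[[name]]
}

#' Read constant sets from a delimited config file
#'
#' Expects a comma-delimited text file with header columns
#' `name,C,alpha,beta` (extra columns ignored).
#'
#' @param path File path.
#' @return Named list of [constant_set] objects.
#' @export
read_constant_sets <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "C", "alpha", "beta")
  if (!all(need %in% names(df))) {
    stop(sprintf("constant-set file '%s' must have columns %s", path,
                 paste(need, collapse = ",")), call. = FALSE)
  }
  sets <- lapply(seq_len(nrow(df)), function(i) {
    constant_set(df$name[i], df$C[i], df$alpha[i], df$beta[i])
  })
  stats::setNames(sets, df$name)
}

#' Evaluate the power-law hemolysis model
#'
#' Computes H = C tau^alpha t^beta. The product is evaluated in the log
#' domain whenever tau and t are positive so that extreme constants (C down
#' to 1e-30, alpha up to 20) neither underflow nor overflow prematurely.
#' Zero stress or zero exposure time gives H = 0.
#'
#' @param tau Equivalent scalar stress in Pa (vectorized, >= 0).
#' @param t Exposure time in s (vectorized, >= 0).
#' @param k A [constant_set].
#' @return Hemolysis ratio H (dimensionless, >= 0).
#' @export
#' @examples
#' power_law_H(100, 1, get_constant_set("GW"))
power_law_H <- function(tau, t, k) {
  stopifnot(inherits(k, "constant_set"))
  if (any(!is.finite(tau)) || any(tau < 0)) {
    stop("`tau` must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and >= 0", call. = FALSE)
  }
  n <- max(length(tau), length(t))
  tau <- rep_len(tau, n)
  t <- rep_len(t, n)
  H <- numeric(n)
  pos <- tau > 0 & t > 0
  H[pos] <- exp(log(k$C) + k$alpha * log(tau[pos]) + k$beta * log(t[pos]))
  H
}

#' Linearize a hemolysis value
#'
#' H_L = H^(1/beta). The linearized value is what the Eulerian transport
#' formulation advects and what the discrete volume integral accumulates;
#' raising it back by beta recovers H.
#'
#' @param H Hemolysis ratio (>= 0, vectorized).
#' @param beta Time exponent (> 0).
#' @return H_L (dimensionless, >= 0).
#' @export
linearize <- function(H, beta) {
  check_scalar_number(beta, "beta", positive = TRUE)
  if (any(!is.finite(H)) || any(H < 0)) {
    stop("`H` must be finite and >= 0", call. = FALSE)
  }
  out <- numeric(length(H))
  pos <- H > 0
  out[pos] <- exp(log(H[pos]) / beta)
  out
}

#' Convert a linearized hemolysis value to the MIH scale
#'
#' MIH = H_L^beta * 1e6, the modified index of hemolysis.
#'
#' @param H_L Linearized hemolysis value (>= 0, vectorized).
#' @param beta Time exponent (> 0).
#' @return MIH (dimensionless, >= 0).
#' @export
delinearize_to_MIH <- function(H_L, beta) {
  check_scalar_number(beta, "beta", positive = TRUE)
  if (any(!is.finite(H_L)) || any(H_L < 0)) {
    stop("`H_L` must be finite and >= 0", call. = FALSE)
  }
  out <- numeric(length(H_L))
  pos <- H_L > 0
  out[pos] <- exp(beta * log(H_L[pos]) + log(1e6))
  out
}

#' Experimental modified index of hemolysis
#'
#' ASTM F1841-97 style index for a closed test loop:
#' \deqn{MIH_{exp} = \frac{\Delta fHb}{Hb} \frac{V}{\Delta t\, Q}
#'       (1 - H_{ct}) \cdot 10^6.}
#'
#' @param delta_fHb Increase of plasma-free hemoglobin over the run, mg/dl
#'   (>= 0).
#' @param Hb Total blood hemoglobin concentration, mg/dl (> 0).
#' @param delta_t Total circuit time, s (> 0).
#' @param V Circuit blood volume, m^3 (> 0).
#' @param Q Flow rate, m^3/s (> 0).
#' @param Hct Hematocrit as a fraction in [0, 1).
#' @return MIH_exp (dimensionless).
#' @export
#' @examples
#' mih_experimental(10, 12000, 3600, 1e-3, 1e-4, 0.36)
mih_experimental <- function(delta_fHb, Hb, delta_t, V, Q, Hct) {
  check_scalar_number(delta_fHb, "delta_fHb", nonneg = TRUE)
  check_scalar_number(Hb, "Hb", positive = TRUE)
  check_scalar_number(delta_t, "delta_t", positive = TRUE)
  check_scalar_number(V, "V", positive = TRUE)
  check_scalar_number(Q, "Q", positive = TRUE)
  check_scalar_number(Hct, "Hct", nonneg = TRUE)
  if (Hct >= 1) stop("`Hct` must be in [0, 1)", call. = FALSE)
  (delta_fHb / Hb) * (V / (delta_t * Q)) * (1 - Hct) * 1e6
}
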