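#' Convert a flow rate from l/min to m^3/s
#'
#' Experimental operating points are reported in litres per minute; all
#' internal stress-field arithmetic is SI. 1 l/min = 1/60000 m^3/s.
#'
#' @param q_lmin Flow rate in l/min.
#' @return Flow rate in m^3/s.
#' @export
#' @examples
#' flow_lmin_to_m3s(6) # 1e-4 m^3/s
flow_lmin_to_m3s <- function(q_lmin) {
  stopifnot(is.numeric(q_lmin))
  q_lmin / 60000
}

#' Round half away from zero at a fixed number of decimals
#'
#' Decimal half-up rounding as used when comparing against printed table
#' values; `base::round()` rounds half to even and is additionally at the
#' mercy of binary representation (e.g. 0.425 is stored slightly below
#' 0.425). A tiny representation tolerance (1e-9) is added before taking
#' the floor so that values intended as exact decimal halves round up.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# log(sum(exp(x))) without overflow; x may contain -Inf (ignored mass).
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m) # all -Inf or an Inf dominates
  m + log(sum(exp(x - m)))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generators are pure functions of their seed argument.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# shared input checks -------------------------------------------------------

check_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0 (got %g)", name, x), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be >= 0 (got %g)", name, x), call. = FALSE)
  }
  invisible(x)
}
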