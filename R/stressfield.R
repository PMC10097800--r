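#' Discretized stress field for one operating point
#'
#' One record per finite volume with its cell volume (m^3) and effective
#' scalar stress (Pa), plus the operating point's flow rate. This is the
#' solver-export data model: a flow simulation writes (Delta V_k, tau_k)
#' pairs once, and all downstream hemolysis evaluation happens without the
#' solver. Cell order carries no meaning.
#'
#' @param volumes Cell volumes Delta V_k in m^3 (all > 0).
#' @param tau Effective scalar stresses tau_s,eff per cell in Pa (all >= 0).
#' @param Q Flow rate in m^3/s (> 0).
#' @param label Operating-point identifier string.
#' @return An object of class `stress_field`.
#' @export
stress_field <- function(volumes, tau, Q, label = "field") {
  if (!is.numeric(volumes) || length(volumes) < 1L) {
    stop("`volumes` must be a non-empty numeric vector", call. = FALSE)
  }
  if (!is.numeric(tau) || length(tau) != length(volumes)) {
    stop("`tau` must be numeric with the same length as `volumes`",
         call. = FALSE)
  }
  if (any(!is.finite(volumes)) || any(volumes <= 0)) {
    stop("all cell volumes must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(tau)) || any(tau < 0)) {
    stop("all stresses must be finite and >= 0", call. = FALSE)
  }
  check_scalar_number(Q, "Q", positive = TRUE)
  structure(list(volumes = as.numeric(volumes), tau = as.numeric(tau),
                 Q = Q, label = as.character(label)),
            class = "stress_field")
}

#' @export
print.stress_field <- function(x, ...) {
  cat(sprintf(
    "<stress_field> '%s': %d cells, V = %.4g m^3, Q = %.4g m^3/s, tau in [%.4g, %.4g] Pa\n",
    x$label, length(x$tau), sum(x$volumes), x$Q, min(x$tau), max(x$tau)))
  invisible(x)
}

#' Strain-rate tensor from a velocity gradient
#'
#' S_ij = (du_i/dx_j + du_j/dx_i) / 2, the symmetric part of the velocity
#' gradient; it describes the rate of deformation of a fluid element.
#'
#' @param grad_u 3x3 velocity-gradient matrix, entries du_i/dx_j in 1/s.
#' @return Symmetric 3x3 strain-rate matrix in 1/s.
#' @export
strain_rate_tensor <- function(grad_u) {
  if (!is.matrix(grad_u) || !all(dim(grad_u) == c(3L, 3L)) ||
      !is.numeric(grad_u)) {
    stop("`grad_u` must be a numeric 3x3 matrix", call. = FALSE)
  }
  (grad_u + t(grad_u)) / 2
}

#' Scalar equivalent stress from the strain-rate tensor
#'
#' tau_s = mu * sqrt(2 S_ij S_ij), the scalar reduction of the viscous
#' stress tensor via the second invariant of the strain-rate tensor. For a
#' simple shear of rate gamma it recovers the Newtonian shear stress
#' mu * gamma.
#'
#' @param S Symmetric 3x3 strain-rate matrix in 1/s.
#' @param mu Dynamic viscosity in Pa s (> 0).
#' @return Scalar stress in Pa.
#' @export
scalar_equivalent_stress <- function(S, mu) {
  if (!is.matrix(S) || !all(dim(S) == c(3L, 3L))) {
    stop("`S` must be a 3x3 matrix", call. = FALSE)
  }
  check_scalar_number(mu, "mu", positive = TRUE)
  mu * sqrt(2 * sum(S * S))
}

#' Per-cell kinematic quantities for stress computation
#'
#' Container for the RANS export path: either the full velocity-gradient
#' tensor or the time-averaged contraction `mean(S_ij S_ij)` plus the
#' modeled turbulent dissipation rate.
#'
#' @param mu Dynamic viscosity, Pa s (> 0).
#' @param rho Density, kg/m^3 (> 0).
#' @param grad_u Optional 3x3 velocity-gradient matrix, 1/s.
#' @param sij_sq_mean Optional time-averaged S_ij S_ij contraction, 1/s^2
#'   (>= 0). Computed from `grad_u` when absent.
#' @param eps_mod Modeled turbulent dissipation rate, m^2/s^3 (>= 0).
#' @return An object of class `cell_kinematics`.
#' @export
cell_kinematics <- function(mu, rho, grad_u = NULL, sij_sq_mean = NULL,
                            eps_mod = 0) {
  check_scalar_number(mu, "mu", positive = TRUE)
  check_scalar_number(rho, "rho", positive = TRUE)
  check_scalar_number(eps_mod, "eps_mod", nonneg = TRUE)
  if (is.null(grad_u) && is.null(sij_sq_mean)) {
    stop("one of `grad_u` or `sij_sq_mean` is required", call. = FALSE)
  }
  if (!is.null(sij_sq_mean)) {
    check_scalar_number(sij_sq_mean, "sij_sq_mean", nonneg = TRUE)
  }
  structure(list(mu = mu, rho = rho, grad_u = grad_u,
                 sij_sq_mean = sij_sq_mean, eps_mod = eps_mod),
            class = "cell_kinematics")
}

#' Effective equivalent stress with turbulent augmentation
#'
#' tau_s,eff = sqrt(2 mu^2 mean(S_ij S_ij) + rho mu eps_mod): the scalar
#' equivalent stress of the time-averaged strain field augmented by the
#' non-resolved turbulent contribution via the modeled dissipation rate.
#' With `eps_mod = 0` it reduces to [scalar_equivalent_stress] on the mean
#' field.
#'
#' @param kin A [cell_kinematics] object.
#' @return Effective scalar stress in Pa.
#' @export
effective_stress <- function(kin) {
  stopifnot(inherits(kin, "cell_kinematics"))
  ss <- kin$sij_sq_mean
  if (is.null(ss)) {
    S <- strain_rate_tensor(kin$grad_u)
    ss <- sum(S * S)
  }
  sqrt(2 * kin$mu^2 * ss + kin$rho * kin$mu * kin$eps_mod)
}

#' Analytic Hagen-Poiseuille stress field
#'
#' Discretizes laminar pipe flow into `n_radial` annular cells. The shear
#' stress grows linearly with radius, tau(r) = tau_w r / R with wall shear
#' stress tau_w = 4 mu Q / (pi R^3); cell k sits at radius
#' r_k = (k - 1/2) dr and has the exact annular volume, so the cell volumes
#' sum to pi R^2 L. This is the closed-form stand-in for capillary-tube
#' geometries and the convergence oracle for the discrete MIH integral.
#'
#' @param R Pipe radius, m (> 0).
#' @param L Pipe length, m (> 0).
#' @param Q Flow rate, m^3/s (> 0).
#' @param mu Dynamic viscosity, Pa s (> 0).
#' @param n_radial Number of annular cells (>= 1).
#' @param label Field label.
#' @return A [stress_field].
#' @export
#' @examples
#' f <- poiseuille_field(1e-3, 0.07, flow_lmin_to_m3s(0.42), 2e-3, 100)
poiseuille_field <- function(R, L, Q, mu, n_radial, label = "poiseuille") {
  check_scalar_number(R, "R", positive = TRUE)
  check_scalar_number(L, "L", positive = TRUE)
  check_scalar_number(Q, "Q", positive = TRUE)
  check_scalar_number(mu, "mu", positive = TRUE)
  if (!is.numeric(n_radial) || length(n_radial) != 1L || n_radial < 1) {
    stop("`n_radial` must be a single integer >= 1", call. = FALSE)
  }
  n <- as.integer(n_radial)
  tau_w <- 4 * mu * Q / (pi * R^3)
  dr <- R / n
  r <- (seq_len(n) - 0.5) * dr
  vol <- pi * ((r + dr / 2)^2 - (r - dr / 2)^2) * L
  stress_field(vol, tau_w * r / R, Q, label)
}
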