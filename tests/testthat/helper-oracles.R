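# Independent oracles and small fixture builders shared across test files.
# Oracles deliberately avoid the package's log-sum-exp code path: they use
# plain base-10 logarithm arithmetic or naive sums, so agreement is a real
# cross-check rather than the same formula twice.

# power law in log10 arithmetic: H = 10^(log10 C + alpha log10 tau + beta log10 t)
oracle_power_law <- function(C, alpha, beta, tau, t) {
  10^(log10(C) + alpha * log10(tau) + beta * log10(t))
}

# naive discrete volume integral (no LSE); fine for moderate constants
oracle_mih_field <- function(volumes, tau, Q, C, alpha, beta) {
  hl <- (1 / Q) * C^(1 / beta) * sum(tau^(alpha / beta) * volumes)
  hl^beta * 1e6
}

# closed-form MIH of the discretized Poiseuille profile's continuum limit
oracle_mih_poiseuille <- function(R, L, Q, mu, C, alpha, beta) {
  tau_w <- 4 * mu * Q / (pi * R^3)
  ab <- alpha / beta
  hl <- (1 / Q) * C^(1 / beta) * 2 * pi * L * tau_w^ab * R^2 / (ab + 2)
  hl^beta * 1e6
}

# single-cell plug-flow field with uniform stress and residence time V/Q
make_uniform_field <- function(tau, t_res, Q = 1e-6, n_cells = 1L,
                               label = "uniform") {
  stress_field(rep(t_res * Q / n_cells, n_cells), rep(tau, n_cells), Q, label)
}

# random 3D rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Qm <- qr.Q(qr_)
  if (det(Qm) < 0) Qm[, 1] <- -Qm[, 1]
  Qm
}

# the two well-separated uniform-stress operating points (HO ground truth)
# used by the multi-modality oracle tests: a capillary-like low-stress /
# long-exposure point and a pump-gap-like high-stress / short-exposure point
make_two_op_world <- function(band_fraction = 0.05) {
  ho <- get_constant_set("HO")
  op1 <- list(tau = 10, t_res = 2, mih = mih_uniform(10, 2, ho))
  op2 <- list(tau = 500, t_res = 0.005, mih = mih_uniform(500, 0.005, ho))
  f1 <- make_uniform_field(op1$tau, op1$t_res, label = "op1")
  f2 <- make_uniform_field(op2$tau, op2$t_res, label = "op2")
  list(op1 = op1, op2 = op2,
       records = list(
         op_record("op1", op1$mih, band_fraction * op1$mih, field = f1),
         op_record("op2", op2$mih, band_fraction * op2$mih, field = f2)))
}

# four lognormal device-like fields spanning the stress decades of the
# experimental test cases; the synthetic parameter-recovery world
make_recovery_fields <- function(n_cells = 10000) {
  list(
    gen_lognormal_field(n_cells, log(5), 0.8, 2e-6, flow_lmin_to_m3s(0.3),
                        seed = 101, label = "ct-like"),
    gen_lognormal_field(n_cells, log(30), 1.0, 1e-6, flow_lmin_to_m3s(5),
                        seed = 102, label = "nozzle-like"),
    gen_lognormal_field(n_cells, log(80), 1.2, 5e-7, flow_lmin_to_m3s(4.5),
                        seed = 103, label = "pump-like"),
    gen_lognormal_field(n_cells, log(200), 1.0, 2e-7, flow_lmin_to_m3s(7),
                        seed = 104, label = "pump-hi"))
}
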