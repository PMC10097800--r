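test_that("uniform fields collapse to the closed-form power law", {
  # a uniform field with residence time t = V/Q must reproduce
  # 1e6 * C * tau^alpha * t^beta for every fixture constant set
  for (k in builtin_constant_sets()) {
    for (cells in c(1L, 7L)) {
      f <- make_uniform_field(tau = 100, t_res = 1, Q = 1e-6,
                              n_cells = cells)
      expect_equal(mih_volume_integral(f, k),
                   mih_uniform(100, 1, k), tolerance = 1e-12,
                   label = sprintf("%s/%d cells", k$name, cells))
    }
  }
  gw <- get_constant_set("GW")
  f <- make_uniform_field(100, 1)
  expect_equal(mih_volume_integral(f, gw), 2.459e4, tolerance = 1e-3)
  # and against the naive-arithmetic oracle for moderate constants
  expect_equal(mih_volume_integral(f, gw),
               oracle_mih_field(f$volumes, f$tau, f$Q, gw$C, gw$alpha,
                                gw$beta), tolerance = 1e-10)
})

test_that("zero-stress cells contribute nothing; empty stress gives zero", {
  ho <- get_constant_set("HO")
  f_all0 <- stress_field(rep(1e-9, 5), rep(0, 5), 1e-6)
  expect_identical(mih_volume_integral(f_all0, ho), 0)
  f_mixed <- stress_field(c(1e-9, 1e-9, 1e-9), c(50, 0, 0), 1e-6)
  f_pos <- stress_field(1e-9, 50, 1e-6)
  expect_equal(mih_volume_integral(f_mixed, ho),
               mih_volume_integral(f_pos, ho), tolerance = 1e-14)
})

test_that("Poiseuille discretization converges to the radial integral", {
  R <- 1e-3; L <- 0.07; mu <- 2.0e-3
  Q <- flow_lmin_to_m3s(0.42)
  ho <- get_constant_set("HO")
  closed <- oracle_mih_poiseuille(R, L, Q, mu, ho$C, ho$alpha, ho$beta)
  coarse <- mih_volume_integral(poiseuille_field(R, L, Q, mu, 10), ho)
  fine <- mih_volume_integral(poiseuille_field(R, L, Q, mu, 400), ho)
  expect_equal(fine, closed, tolerance = 5e-3)
  expect_lt(abs(fine - closed), abs(coarse - closed))
})

test_that("homogeneity: scaling stresses or volumes scales MIH by power laws", {
  set.seed(31)
  f <- gen_lognormal_field(500, log(20), 1, 1e-6, 1e-5, seed = 5)
  domains <- list(c(1e-30, 0.1, 0.1), c(1e-5, 20, 20),
                  c(1e-9, 1.5, 0.5), c(1e-7, 2.5, 1.0))
  ks <- c(builtin_constant_sets(),
          lapply(seq_along(domains), function(i) {
            d <- domains[[i]]
            constant_set(paste0("edge", i), d[1], d[2], d[3])
          }))
  for (k in ks) {
    base_ln <- mih_volume_integral(f, k, log = TRUE)
    for (fac in c(0.5, 3, 10)) {
      f_tau <- stress_field(f$volumes, f$tau * fac, f$Q, f$label)
      expect_equal(mih_volume_integral(f_tau, k, log = TRUE) - base_ln,
                   k$alpha * log(fac), tolerance = 1e-9,
                   label = sprintf("tau scaling %s x%g", k$name, fac))
      f_vol <- stress_field(f$volumes * fac, f$tau, f$Q, f$label)
      expect_equal(mih_volume_integral(f_vol, k, log = TRUE) - base_ln,
                   k$beta * log(fac), tolerance = 1e-9,
                   label = sprintf("volume scaling %s x%g", k$name, fac))
    }
  }
})

test_that("no overflow for extreme constants on extreme stress ranges", {
  f <- stress_field(rep(1e-8, 4), c(1e-6, 1e-2, 1e2, 1e6), 1e-6)
  for (k in list(constant_set("lo", 1e-30, 0.1, 0.1),
                 constant_set("hi", 1e-5, 20, 20),
                 constant_set("mix", 1e-30, 20, 0.1),
                 get_constant_set("FT-M"))) {
    ln <- mih_volume_integral(f, k, log = TRUE)
    expect_true(is.finite(ln), label = k$name)
  }
})

test_that("cell order never changes the result", {
  set.seed(41)
  f <- gen_lognormal_field(2000, log(10), 1.5, 1e-6, 1e-5, seed = 8)
  ho <- get_constant_set("HO")
  base <- mih_volume_integral(f, ho)
  for (i in 1:5) {
    p <- sample.int(length(f$tau))
    fp <- stress_field(f$volumes[p], f$tau[p], f$Q)
    expect_equal(mih_volume_integral(fp, ho), base, tolerance = 1e-12)
  }
})

test_that("mih_batch matches element-wise evaluation and exact ratios", {
  ho <- get_constant_set("HO")
  gw <- get_constant_set("GW")
  f1 <- gen_lognormal_field(200, log(10), 1, 1e-6, 1e-5, seed = 2, label = "a")
  f2 <- make_uniform_field(80, 0.5, label = "b")
  tab <- mih_batch(list(f1, f2), list(ho, gw))
  expect_equal(nrow(tab), 4)
  expect_equal(tab$MIH_num[tab$label == "a" & tab$set == "HO"],
               mih_volume_integral(f1, ho), tolerance = 1e-14)
  expect_equal(tab$MIH_num[tab$label == "b" & tab$set == "GW"],
               mih_volume_integral(f2, gw), tolerance = 1e-14)
  # two sets differing only in C: MIH ratio is exactly C1/C2
  k1 <- constant_set("c1", 2e-8, 1.991, 0.765)
  k2 <- constant_set("c2", 1e-8, 1.991, 0.765)
  tab2 <- mih_batch(list(f1), list(k1, k2))
  expect_equal(tab2$MIH_num[1] / tab2$MIH_num[2], 2, tolerance = 1e-12)
  expect_error(mih_batch(list(), list(ho)), "non-empty")
})

test_that("batch throughput is adequate for optimizer workloads", {
  # 1000 sets x 1 field of 1e4 cells in well under a minute
  f <- gen_lognormal_field(10000, log(20), 1, 1e-6, 1e-5, seed = 3)
  sets <- lapply(1:1000, function(i) {
    constant_set(paste0("s", i), 10^(-9 + (i %% 5)), 1.5 + (i %% 7) / 10,
                 0.5 + (i %% 4) / 10)
  })
  elapsed <- system.time(tab <- mih_batch(list(f), sets))[["elapsed"]]
  expect_equal(nrow(tab), 1000)
  expect_lt(elapsed, 30)
})
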