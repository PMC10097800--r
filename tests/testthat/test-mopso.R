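test_that("constriction factors follow the closed form", {
  cf <- constriction(2.01)
  expect_equal(cf$omega, 1 / (1.01 + sqrt(2.01^2 - 4.02)), tolerance = 1e-12)
  expect_equal(cf$omega, 0.86823, tolerance = 1e-5)
  expect_equal(cf$c, 1.74514, tolerance = 1e-5)
  cf2 <- constriction(2.5)
  expect_equal(cf2$omega, 1 / (1.5 + sqrt(1.25)), tolerance = 1e-12)
  expect_equal(cf2$omega, 0.381966, tolerance = 1e-6)
  expect_equal(cf2$c, 0.954915, tolerance = 1e-6)
  # phi -> 2+ pushes omega -> 1
  expect_equal(constriction(2 + 1e-12)$omega, 1, tolerance = 1e-5)
  expect_error(constriction(2), "> 2")
})

test_that("dominance is component-wise with at least one strict", {
  expect_true(dominates(c(0.1, 0.1), c(0.2, 0.2)))
  expect_true(dominates(c(0.1, 0.2), c(0.1, 0.3)))
  expect_false(dominates(c(0.1, 0.3), c(0.3, 0.1)))
  expect_false(dominates(c(0.3, 0.1), c(0.1, 0.3)))
  expect_false(dominates(c(0.2, 0.2), c(0.2, 0.2)))
})

test_that("velocity/position update: inertia, attraction, clamping", {
  cf <- constriction(2.01)
  set.seed(61)
  # x = p = g: pure inertial decay regardless of the random draws
  upd <- velocity_position_update(c(1, 1, 1), c(0.5, -0.2, 0), c(1, 1, 1),
                                  c(1, 1, 1), cf$omega, cf$c,
                                  rep(-10, 3), rep(10, 3))
  expect_equal(upd$v, cf$omega * c(0.5, -0.2, 0), tolerance = 1e-12)
  expect_equal(upd$x, c(1, 1, 1) + upd$v, tolerance = 1e-12)
  # v = 0, x = p: motion is toward the leader
  for (i in 1:20) {
    upd <- velocity_position_update(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0),
                                    c(2, -3, 1), cf$omega, cf$c,
                                    rep(-10, 3), rep(10, 3))
    expect_true(all(upd$x * c(2, -3, 1) >= 0)) # same direction per component
    expect_true(all(abs(upd$x) <= cf$c * abs(c(2, -3, 1)) + 1e-12))
  }
  # overshoot past the upper bound clamps position, keeps velocity
  upd <- velocity_position_update(c(9.5, 0, 0), c(5, 0, 0), c(9.5, 0, 0),
                                  c(9.5, 0, 0), cf$omega, cf$c,
                                  rep(-10, 3), rep(10, 3))
  expect_equal(upd$x[1], 10)
  expect_equal(upd$v[1], cf$omega * 5, tolerance = 1e-12)
})

test_that("grid assigns extremes to opposite corner bins", {
  objs <- rbind(c(0, 0), c(1, 1))
  cells <- grid_update(objs, 10)
  expect_length(unique(cells), 2)
  # first entry in the first row/col block, second in the last
  expect_equal(cells[1], 1L)
  expect_equal(cells[2], 100L)
  # single entry: one valid cell, no error
  expect_length(grid_update(rbind(c(0.3, 0.4)), 50), 1)
})

test_that("leader roulette prefers sparse hypercubes at the stated rate", {
  # two occupied cells with occupancies 1 and 9: the sparse cell must be
  # chosen with probability 0.9 (weights 1 vs 1/9)
  pos <- matrix(0, 10, 3)
  obj <- rbind(c(0.05, 0.05),
               cbind(runif(9, 0.9, 0.95), runif(9, 0.9, 0.95)))
  rep_ <- list(pos = pos, obj = obj)
  set.seed(71)
  draws <- replicate(1e4, select_leader(rep_, 2))
  p_sparse <- mean(draws == 1L)
  expect_equal(p_sparse, 0.9, tolerance = 0.025)
  expect_error(select_leader(list(pos = matrix(0, 0, 3),
                                  obj = matrix(0, 0, 2)), 5), "empty")
  # singleton repository always leads
  expect_identical(select_leader(list(pos = matrix(0, 1, 3),
                                      obj = matrix(0.5, 1, 2)), 5), 1L)
})

test_that("repository insertion maintains mutual non-dominance and capacity", {
  empty <- list(pos = matrix(numeric(0), 0, 2), obj = matrix(numeric(0), 0, 2))
  r1 <- repository_insert(empty, c(1, 1), c(0.5, 0.5), nr = 5, ng = 5)
  expect_equal(nrow(r1$obj), 1)
  # dominated candidate rejected
  r2 <- repository_insert(r1, c(2, 2), c(0.6, 0.6), nr = 5, ng = 5)
  expect_equal(nrow(r2$obj), 1)
  # dominating candidate replaces everything it dominates
  r3 <- repository_insert(r1, c(3, 3), c(0.1, 0.1), nr = 5, ng = 5)
  expect_equal(nrow(r3$obj), 1)
  expect_equal(r3$obj[1, ], c(0.1, 0.1))
  # mutually non-dominated candidates accumulate
  r4 <- repository_insert(r3, c(4, 4), c(0.05, 0.3), nr = 5, ng = 5)
  r4 <- repository_insert(r4, c(5, 5), c(0.3, 0.05), nr = 5, ng = 5)
  expect_equal(nrow(r4$obj), 3)
  # pairwise non-dominance holds
  for (i in seq_len(nrow(r4$obj))) {
    for (j in seq_len(nrow(r4$obj))) {
      if (i != j) expect_false(dominates(r4$obj[i, ], r4$obj[j, ]))
    }
  }
  # at capacity, a non-dominated insertion keeps size at capacity
  set.seed(81)
  rcap <- empty
  for (i in 1:50) {
    t <- i / 51
    rcap <- repository_insert(rcap, c(t, t), c(t, 1 - t), nr = 10, ng = 4)
  }
  expect_lte(nrow(rcap$obj), 10)
  expect_equal(nrow(rcap$obj), 10)
})

test_that("pbest update: dominance decides, ties split 50/50", {
  cur <- list(pos = c(1, 1, 1), obj = c(0.1, 0.1))
  old <- list(pos = c(0, 0, 0), obj = c(0.2, 0.2))
  expect_equal(pbest_update(cur$pos, cur$obj, old$pos, old$obj)$pos, cur$pos)
  expect_equal(pbest_update(old$pos, old$obj, cur$pos, cur$obj)$pos, cur$pos)
  set.seed(91)
  picks <- replicate(1e4, {
    pbest_update(c(1, 1, 1), c(0.1, 0.3), c(0, 0, 0), c(0.3, 0.1))$pos[1]
  })
  expect_equal(mean(picks == 1), 0.5, tolerance = 0.05)
})

test_that("mopso_run converges on a single-optimum bowl", {
  # phi = 2.01 sits at the edge of second-moment stability, so the tail
  # convergence is slow: ~1e-2 after 200 iterations, 1e-3 needs ~400
  x0 <- c(0.3, -1.2, 2.5)
  bowl <- function(x) rep(sum((x - x0)^2), 2)
  rep200 <- mopso_run(bowl, lb = rep(-5, 3), ub = rep(5, 3), np = 50,
                      nr = 50, tmax = 200, seed = 3)
  best200 <- rep200$pos[which.min(rep200$obj[, 1]), ]
  expect_lt(sqrt(sum((best200 - x0)^2)), 0.05)
  rep400 <- mopso_run(bowl, lb = rep(-5, 3), ub = rep(5, 3), np = 50,
                      nr = 50, tmax = 400, seed = 3)
  best400 <- rep400$pos[which.min(rep400$obj[, 1]), ]
  expect_lt(sqrt(sum((best400 - x0)^2)), 0.02)
  expect_lt(min(rep400$obj[, 1]), min(rep200$obj[, 1]))
})

test_that("mopso_run respects bounds, non-dominance, and the seed", {
  fn <- function(x) c(x[1]^2 + 0.1 * x[2]^2, (x[1] - 1)^2 + 0.1 * x[3]^2)
  run1 <- mopso_run(fn, lb = rep(-2, 3), ub = rep(2, 3), np = 20, nr = 30,
                    tmax = 40, seed = 17)
  run2 <- mopso_run(fn, lb = rep(-2, 3), ub = rep(2, 3), np = 20, nr = 30,
                    tmax = 40, seed = 17)
  expect_identical(run1$pos, run2$pos)
  expect_identical(run1$obj, run2$obj)
  expect_true(all(run1$pos >= -2 & run1$pos <= 2))
  n <- nrow(run1$obj)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) expect_false(dominates(run1$obj[i, ], run1$obj[j, ]))
    }
  }
  # a different seed gives a different trajectory
  run3 <- mopso_run(fn, lb = rep(-2, 3), ub = rep(2, 3), np = 20, nr = 30,
                    tmax = 40, seed = 18)
  expect_false(identical(run1$pos, run3$pos))
  # non-finite objectives are reported with context
  expect_error(
    mopso_run(function(x) c(NA_real_, 1), lb = -1, ub = 1, np = 2, nr = 5,
              tmax = 2, seed = 1),
    "non-finite")
})

test_that("domain bounds carry the two published search boxes", {
  m <- domain_bounds("mathematical")
  expect_equal(unname(m$lb), c(1e-30, 0.1, 0.1))
  expect_equal(unname(m$ub), c(1e-5, 20, 20))
  l <- domain_bounds("literature")
  expect_equal(unname(l$lb), c(1e-9, 1.5, 0.5))
  expect_equal(unname(l$ub), c(1e-7, 2.5, 1.0))
  expect_error(domain_bounds("bogus"))
})

test_that("repository_table round-trips positions into constants", {
  w <- make_two_op_world()
  tab <- optimize_constants(w$records, domain = "literature", np = 20,
                            nr = 50, tmax = 30, seed = 5)
  expect_s3_class(tab, "constant_repository")
  expect_equal(tab$C, exp(tab$lnC), tolerance = 1e-12)
  expect_equal(tab$Fn, (tab$eta + tab$r) / 2, tolerance = 1e-12)
  expect_true(all(diff(tab$Fn) >= 0))
  b <- domain_bounds("literature")
  expect_true(all(tab$C >= b$lb[1] & tab$C <= b$ub[1]))
  expect_true(all(tab$alpha >= b$lb[2] & tab$alpha <= b$ub[2]))
  expect_true(all(tab$beta >= b$lb[3] & tab$beta <= b$ub[3]))
})
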