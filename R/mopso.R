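#' Constriction coefficient and merged learning factor
#'
#' Clerc-Kennedy constriction guaranteeing swarm convergence:
#' omega = 1 / (phi - 1 + sqrt(phi^2 - 2 phi)) and c = omega * phi, with
#' the cognitive and social learning factors merged into the single c.
#'
#' @param phi Constriction parameter, must be > 2.
#' @return List with `omega` (inertia weight) and `c` (learning factor).
#' @export
#' @examples
#' constriction(2.01)
constriction <- function(phi) {
  check_scalar_number(phi, "phi")
  if (phi <= 2) stop("`phi` must be > 2", call. = FALSE)
  omega <- 1 / (phi - 1 + sqrt(phi^2 - 2 * phi))
  list(omega = omega, c = omega * phi)
}

#' Pareto dominance (minimization)
#'
#' `a` dominates `b` iff a <= b in every objective and a < b in at least
#' one. Equal objective vectors do not dominate each other.
#'
#' @param a,b Numeric objective vectors of equal length.
#' @return Logical.
#' @export
dominates <- function(a, b) {
  stopifnot(length(a) == length(b))
  all(a <= b) && any(a < b)
}

#' One constriction-factor velocity and position update
#'
#' v' = omega v + c r1 (p - x) + c r2 (g - x), x' = x + v', with r1 and r2
#' drawn per component from the current RNG stream. Components pushed
#' outside the box are forced back onto the violated bound; the velocity is
#' maintained (no reflection, no damping).
#'
#' @param x,v Current position and velocity vectors.
#' @param p Personal-best position.
#' @param g Leader (global-best) position.
#' @param omega,cc Constriction inertia weight and learning factor, see
#'   [constriction()].
#' @param lb,ub Lower/upper bounds of the search box.
#' @return List with updated `x` and `v`.
#' @export
velocity_position_update <- function(x, v, p, g, omega, cc, lb, ub) {
  d <- length(x)
  r1 <- stats::runif(d)
  r2 <- stats::runif(d)
  v <- omega * v + cc * r1 * (p - x) + cc * r2 * (g - x)
  x <- x + v
  x <- pmin(pmax(x, lb), ub)
  list(x = x, v = v)
}

#' Assign hypercube-grid cells in objective space
#'
#' The objective space spanned by the current repository (min/max per
#' objective, inflated by 1% padding on each side) is divided into `ng`
#' equal bins per dimension; each row gets its flattened cell index. The
#' grid adapts every iteration as the front shrinks.
#'
#' @param objs Numeric matrix, one row per repository entry, one column per
#'   objective.
#' @param ng Number of bins per objective dimension.
#' @return Integer vector of flattened cell indices.
#' @export
grid_update <- function(objs, ng) {
  stopifnot(is.matrix(objs), nrow(objs) >= 1L, ng >= 1L)
  nd <- ncol(objs)
  idx <- matrix(1L, nrow(objs), nd)
  for (j in seq_len(nd)) {
    lo <- min(objs[, j]); hi <- max(objs[, j])
    pad <- 0.01 * (hi - lo)
    if (pad == 0) pad <- max(abs(hi) * 1e-9, 1e-12)
    lo <- lo - pad; hi <- hi + pad
    b <- floor((objs[, j] - lo) / (hi - lo) * ng) + 1
    idx[, j] <- pmin.int(pmax.int(b, 1L), as.integer(ng))
  }
  cell <- idx[, 1L]
  if (nd > 1L) {
    for (j in 2L:nd) cell <- (cell - 1L) * as.integer(ng) + idx[, j]
  }
  as.integer(cell)
}

#' Roulette-wheel leader selection from the repository
#'
#' A hypercube is chosen with probability proportional to 1/occupancy over
#' the occupied cells (sparse regions of the front lead more often), then a
#' uniformly random member of that cell is returned.
#'
#' @param rep A `pareto_repository` (see [mopso_run()]) or a list with
#'   matrices `pos` and `obj`.
#' @param ng Bins per objective dimension for the grid.
#' @return Row index of the selected leader in the repository.
#' @export
select_leader <- function(rep, ng) {
  n <- nrow(rep$obj)
  if (is.null(n) || n == 0L) stop("repository is empty", call. = FALSE)
  if (n == 1L) return(1L)
  cells <- grid_update(rep$obj, ng)
  occ <- table(cells)
  ids <- as.integer(names(occ))
  w <- 1 / as.numeric(occ)
  chosen <- ids[sample.int(length(ids), 1L, prob = w)]
  members <- which(cells == chosen)
  members[sample.int(length(members), 1L)]
}

#' Insert a candidate into a Pareto repository
#'
#' The candidate enters iff no current entry dominates it; entries it
#' dominates are removed. If the repository then exceeds its capacity, a
#' uniformly random entry from a maximally populated hypercube is removed
#' until the size is back at capacity, keeping the stored front evenly
#' spread.
#'
#' @param rep List with `pos` (n x d) and `obj` (n x m) matrices.
#' @param pos Candidate position (length d).
#' @param obj Candidate objectives (length m).
#' @param nr Repository capacity.
#' @param ng Bins per objective dimension (for pruning).
#' @return Updated repository list.
#' @export
repository_insert <- function(rep, pos, obj, nr, ng) {
  n <- nrow(rep$obj)
  if (n > 0L) {
    le <- rep$obj <= matrix(obj, n, length(obj), byrow = TRUE)
    lt <- rep$obj < matrix(obj, n, length(obj), byrow = TRUE)
    dominated_by_entry <- rowSums(le) == ncol(rep$obj) & rowSums(lt) > 0
    if (any(dominated_by_entry)) return(rep)
    # entry i is dominated by the candidate iff obj <= entry (all), < (any):
    ge <- rep$obj >= matrix(obj, n, length(obj), byrow = TRUE)
    gt <- rep$obj > matrix(obj, n, length(obj), byrow = TRUE)
    entry_dominated <- rowSums(ge) == ncol(rep$obj) & rowSums(gt) > 0
    if (any(entry_dominated)) {
      keep <- !entry_dominated
      rep$pos <- rep$pos[keep, , drop = FALSE]
      rep$obj <- rep$obj[keep, , drop = FALSE]
    }
  }
  rep$pos <- rbind(rep$pos, pos)
  rep$obj <- rbind(rep$obj, obj)
  while (nrow(rep$obj) > nr) {
    cells <- grid_update(rep$obj, ng)
    occ <- table(cells)
    worst_cells <- as.integer(names(occ)[occ == max(occ)])
    cell <- if (length(worst_cells) == 1L) worst_cells else
      worst_cells[sample.int(length(worst_cells), 1L)]
    members <- which(cells == cell)
    victim <- members[sample.int(length(members), 1L)]
    rep$pos <- rep$pos[-victim, , drop = FALSE]
    rep$obj <- rep$obj[-victim, , drop = FALSE]
  }
  rep
}

#' Personal-best update
#'
#' The personal best is replaced when the current position dominates it,
#' kept when it dominates the current position, and replaced with
#' probability 1/2 (from the RNG stream) when the two are mutually
#' non-dominated.
#'
#' @param pos,obj Current position and objectives.
#' @param pbest_pos,pbest_obj Stored personal best.
#' @return List with (possibly replaced) `pos` and `obj`.
#' @export
pbest_update <- function(pos, obj, pbest_pos, pbest_obj) {
  if (dominates(obj, pbest_obj)) {
    list(pos = pos, obj = obj)
  } else if (dominates(pbest_obj, obj)) {
    list(pos = pbest_pos, obj = pbest_obj)
  } else if (stats::runif(1) < 0.5) {
    list(pos = pos, obj = obj)
  } else {
    list(pos = pbest_pos, obj = pbest_obj)
  }
}

#' Multi-objective particle swarm optimization
#'
#' Full MOPSO loop: particles are initialized uniformly at random inside
#' the search box with velocities uniform in +/-(ub - lb); each iteration
#' evaluates the swarm, inserts candidates into the Pareto repository,
#' rebuilds the adaptive hypercube grid, selects a roulette-wheel leader
#' per particle, updates personal bests and applies the constriction
#' velocity/position update with boundary clamping. No mutation operator is
#' applied; the only stochastic inputs are the initialization, the per-
#' component r1/r2 draws, leader selection, personal-best tie-breaks and
#' capacity pruning. A fixed `seed` makes the run bit-reproducible.
#'
#' @param objective_fn Function mapping a position vector to a numeric
#'   vector of objectives (minimization). Must return finite values.
#' @param lb,ub Numeric bound vectors of the search box (equal length,
#'   `lb < ub` component-wise).
#' @param np Number of particles.
#' @param nr Repository capacity.
#' @param tmax Number of iterations.
#' @param phi Constriction parameter (> 2).
#' @param ng Hypercube bins per objective dimension.
#' @param seed RNG seed; `NULL` uses the current RNG stream.
#' @param verbose Log progress every 10 iterations.
#' @return A `pareto_repository`: list with `pos` (entries x d), `obj`
#'   (entries x m) and the run settings in `config`.
#' @export
mopso_run <- function(objective_fn, lb, ub, np = 100, nr = 1000,
                      tmax = 1000, phi = 2.01, ng = 50, seed = NULL,
                      verbose = FALSE) {
  stopifnot(is.function(objective_fn), length(lb) == length(ub),
            all(lb < ub), np >= 1, nr >= 1, tmax >= 1, ng >= 1)
  with_seed(seed, {
    d <- length(lb)
    cf <- constriction(phi)
    span <- ub - lb
    eval_obj <- function(x, t) {
      f <- objective_fn(x)
      if (any(!is.finite(f))) {
        stop(sprintf(
          "objective returned non-finite values at iteration %d for position (%s)",
          t, paste(signif(x, 6), collapse = ", ")), call. = FALSE)
      }
      f
    }
    X <- matrix(stats::runif(np * d, rep(lb, each = np), rep(ub, each = np)),
                np, d)
    V <- matrix(stats::runif(np * d, rep(-span, each = np),
                             rep(span, each = np)), np, d)
    f1 <- eval_obj(X[1, ], 0L)
    m <- length(f1)
    F0 <- rbind(f1, t(vapply(seq_len(np)[-1], function(i) eval_obj(X[i, ], 0L),
                             numeric(m))), deparse.level = 0)
    if (np == 1L) F0 <- matrix(f1, 1L, m)
    rep_ <- list(pos = matrix(numeric(0), 0, d),
                 obj = matrix(numeric(0), 0, m))
    for (i in seq_len(np)) {
      rep_ <- repository_insert(rep_, X[i, ], F0[i, ], nr, ng)
    }
    Pb <- X
    Pf <- F0
    for (t in seq_len(tmax)) {
      # objective-space phase: leaders for the whole swarm come from the
      # same repository state, then the swarm moves and is re-evaluated
      Fi <- matrix(NA_real_, np, m)
      for (i in seq_len(np)) {
        li <- select_leader(rep_, ng)
        g <- rep_$pos[li, ]
        upd <- velocity_position_update(X[i, ], V[i, ], Pb[i, ], g,
                                        cf$omega, cf$c, lb, ub)
        X[i, ] <- upd$x
        V[i, ] <- upd$v
        Fi[i, ] <- eval_obj(X[i, ], t)
      }
      for (i in seq_len(np)) {
        pb <- pbest_update(X[i, ], Fi[i, ], Pb[i, ], Pf[i, ])
        Pb[i, ] <- pb$pos
        Pf[i, ] <- pb$obj
        rep_ <- repository_insert(rep_, X[i, ], Fi[i, ], nr, ng)
      }
      if (verbose && t %% 10 == 0) {
        message(sprintf("iter %4d: repository %4d, best mean objective %.5f",
                        t, nrow(rep_$obj), min(rowMeans(rep_$obj))))
      }
    }
    structure(list(pos = rep_$pos, obj = rep_$obj,
                   config = list(np = np, nr = nr, tmax = tmax, phi = phi,
                                 ng = ng, seed = seed, lb = lb, ub = ub)),
              class = "pareto_repository")
  })
}

#' @export
print.pareto_repository <- function(x, ...) {
  cat(sprintf("<pareto_repository> %d entries, %d objectives, %d dims\n",
              nrow(x$obj), ncol(x$obj), ncol(x$pos)))
  invisible(x)
}

#' Search-domain bounds for the constant optimization
#'
#' The two published search boxes on (C, alpha, beta): the wide
#' "mathematical" range `LB = (1e-30, 0.1, 0.1)`, `UB = (1e-5, 20, 20)`,
#' and the narrow "literature" range `LB = (1e-9, 1.5, 0.5)`,
#' `UB = (1e-7, 2.5, 1.0)` spanning the published constant sets.
#'
#' @param domain `"mathematical"` or `"literature"`.
#' @return List with `lb` and `ub` on the (C, alpha, beta) scale.
#' @export
domain_bounds <- function(domain = c("mathematical", "literature")) {
  domain <- match.arg(domain)
  if (domain == "mathematical") {
    list(lb = c(C = 1e-30, alpha = 0.1, beta = 0.1),
         ub = c(C = 1e-5, alpha = 20.0, beta = 20.0))
  } else {
    list(lb = c(C = 1e-9, alpha = 1.5, beta = 0.5),
         ub = c(C = 1e-7, alpha = 2.5, beta = 1.0))
  }
}

#' Optimize power-law constants against experimental records
#'
#' Runs the MOPSO over (ln C, alpha, beta) — C spans 25 orders of magnitude
#' in the mathematical domain, so the search operates on its logarithm —
#' with the dead-band mean error eta and the modified correlation r as the
#' two minimization objectives computed from the records' stress fields.
#'
#' @param records List of [op_record] objects with fields attached.
#' @param domain Search domain, see [domain_bounds()]; ignored when `lb`
#'   and `ub` are given.
#' @param np,nr,tmax,phi,ng,seed,verbose Swarm settings, see [mopso_run()].
#'   Defaults are the published run configuration.
#' @param lb,ub Optional explicit bounds on the (C, alpha, beta) scale.
#' @return A `constant_repository`: data.frame with columns `lnC`, `C`,
#'   `alpha`, `beta`, `eta`, `r`, `Fn`, plus the raw `pareto_repository`
#'   in attribute `"repository"`.
#' @export
optimize_constants <- function(records, domain = "mathematical",
                               np = 100, nr = 1000, tmax = 1000,
                               phi = 2.01, ng = 50, seed = NULL,
                               verbose = FALSE, lb = NULL, ub = NULL) {
  if (inherits(records, "op_record")) records <- list(records)
  if (is.null(lb) || is.null(ub)) {
    b <- domain_bounds(domain)
    lb <- b$lb
    ub <- b$ub
  }
  fn <- make_fitness_objective(records)
  rep_ <- mopso_run(fn, c(log(lb[1]), lb[2], lb[3]),
                    c(log(ub[1]), ub[2], ub[3]),
                    np = np, nr = nr, tmax = tmax, phi = phi, ng = ng,
                    seed = seed, verbose = verbose)
  repository_table(rep_)
}

# Objective closure (eta, r) over positions (lnC, alpha, beta); field logs
# precomputed once so a single evaluation costs a few vector ops per record.
make_fitness_objective <- function(records) {
  for (rec in records) {
    if (is.null(rec$field)) {
      stop(sprintf("record '%s' has no stress field attached", rec$label),
           call. = FALSE)
    }
  }
  pres <- lapply(records, function(r) mih_precompute(r$field))
  B <- vapply(records, `[[`, numeric(1), "mih_exp")
  nrec <- length(records)
  function(x) {
    C <- exp(x[1]); alpha <- x[2]; beta <- x[3]
    ln_mih <- vapply(pres, mih_log_from_pre, numeric(1),
                     C = C, alpha = alpha, beta = beta)
    xi <- vapply(seq_len(nrec), function(i) {
      xi_error_log(ln_mih[i], records[[i]])
    }, numeric(1))
    A <- exp(ln_mih)
    r <- if (nrec >= 2L && all(is.finite(A))) {
      suppressWarnings(modified_correlation(A, B))
    } else 2
    c(mean(xi), r)
  }
}

#' Flatten a Pareto repository into a constant-set table
#'
#' @param rep A `pareto_repository` from a (ln C, alpha, beta) run with
#'   objectives (eta, r).
#' @return `data.frame` with columns `lnC,C,alpha,beta,eta,r,Fn`, sorted by
#'   `Fn`.
#' @export
repository_table <- function(rep) {
  stopifnot(inherits(rep, "pareto_repository"), ncol(rep$pos) == 3L,
            ncol(rep$obj) == 2L)
  df <- data.frame(lnC = rep$pos[, 1], C = exp(rep$pos[, 1]),
                   alpha = rep$pos[, 2], beta = rep$pos[, 3],
                   eta = rep$obj[, 1], r = rep$obj[, 2],
                   Fn = overall_fitness(rep$obj[, 1], rep$obj[, 2]),
                   row.names = NULL)
  df <- df[order(df$Fn), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "repository") <- rep
  class(df) <- c("constant_repository", "data.frame")
  df
}
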