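#' 3D line in (ln C, alpha, beta) space
#'
#' Centroid plus unit direction; points on the line are
#' centroid + s * direction. The direction sign is fixed by convention:
#' the ln C component is made negative (matching the published line); when
#' it vanishes, the largest-magnitude component is made positive.
#'
#' @param centroid Length-3 numeric vector (ln C, alpha, beta).
#' @param direction Length-3 numeric vector; normalized internally.
#' @return An object of class `line3d`.
#' @export
line3d <- function(centroid, direction) {
  stopifnot(is.numeric(centroid), length(centroid) == 3L,
            is.numeric(direction), length(direction) == 3L)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("`direction` must be nonzero", call. = FALSE)
  d <- direction / nrm
  if (abs(d[1]) > 1e-12) {
    if (d[1] > 0) d <- -d
  } else if (d[which.max(abs(d))] < 0) {
    d <- -d
  }
  structure(list(centroid = as.numeric(centroid), direction = d),
            class = "line3d")
}

#' @export
print.line3d <- function(x, ...) {
  cat(sprintf(
    "<line3d> centroid (%.4f, %.4f, %.4f) + s * (%.4f, %.4f, %.4f)\n",
    x$centroid[1], x$centroid[2], x$centroid[3],
    x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Evaluate a line at parameter values
#'
#' @param line A [line3d].
#' @param s Numeric vector of parameter values.
#' @return Matrix with one row per `s`, columns (ln C, alpha, beta).
#' @export
line_point <- function(line, s) {
  stopifnot(inherits(line, "line3d"))
  t(vapply(s, function(si) line$centroid + si * line$direction, numeric(3)))
}

#' Published near-optimal constant line
#'
#' The reference principal-component line along which the best optimized
#' constant sets align: centroid (-25.6767, 3.2650, 0.9065), direction
#' (-0.9638, 0.2584, 0.0652) in (ln C, alpha, beta). Frozen fixture; the
#' repository behind it (CFD stress fields) is not reconstructible at desk
#' scale.
#'
#' @return A [line3d].
#' @export
ft_line <- function() {
  line3d(c(-25.6767, 3.2650, 0.9065), c(-0.9638, 0.2584, 0.0652))
}

#' Fit the principal-component line through good repository particles
#'
#' Keeps the points with fitness strictly below `threshold` (default 0.5,
#' the published cutoff for "good" particles), then takes their mean as
#' centroid and the leading principal axis of their covariance as
#' direction. Because near-optimal constant sets align along a line rather
#' than clustering at a point, this one-dimensional summary is the compact
#' description of the solution structure.
#'
#' @param points Matrix or data.frame with three columns (ln C, alpha,
#'   beta), one row per particle.
#' @param fitness Optional vector of F_n values, one per row.
#' @param threshold Keep rows with `fitness < threshold`; ignored when
#'   `fitness` is `NULL`.
#' @return A [line3d] with attribute `"n_points"`.
#' @export
fit_line <- function(points, fitness = NULL, threshold = 0.5) {
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3L) stop("`points` must have 3 columns", call. = FALSE)
  if (!is.null(fitness)) {
    stopifnot(length(fitness) == nrow(pts))
    pts <- pts[fitness < threshold, , drop = FALSE]
  }
  if (nrow(pts) < 2L) {
    stop("need at least 2 points below the fitness threshold", call. = FALSE)
  }
  ctr <- colMeans(pts)
  pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  out <- line3d(ctr, pc$rotation[, 1])
  attr(out, "n_points") <- nrow(pts)
  out
}

#' Fit the constant line from a repository table
#'
#' Convenience wrapper applying [fit_line()] to the `(lnC, alpha, beta)`
#' columns of a [repository_table()] result with its `Fn` column.
#'
#' @param tab A `constant_repository` data.frame.
#' @param threshold F_n cutoff, default 0.5.
#' @return A [line3d].
#' @export
fit_constant_line <- function(tab, threshold = 0.5) {
  stopifnot(all(c("lnC", "alpha", "beta", "Fn") %in% names(tab)))
  fit_line(cbind(tab$lnC, tab$alpha, tab$beta), tab$Fn, threshold)
}

#' Orthogonal distance from a point to a line
#'
#' @param point Length-3 vector (ln C, alpha, beta).
#' @param line A [line3d].
#' @return Euclidean distance of the point from the line.
#' @export
point_line_distance <- function(point, line) {
  stopifnot(inherits(line, "line3d"), length(point) == 3L)
  v <- as.numeric(point) - line$centroid
  perp <- v - sum(v * line$direction) * line$direction
  sqrt(sum(perp^2))
}

#' Analytic zero-error line for two uniform-stress operating points
#'
#' For a plug flow with uniform stress tau and residence time t_res, the
#' constant sets reproducing a target MIH exactly form the plane
#' ln C + alpha ln(tau) + beta ln(t_res) = ln(MIH * 1e-6) in
#' (ln C, alpha, beta) space. Two distinct operating points intersect in a
#' line whose direction is the normalized cross product of the plane
#' normals (1, ln tau_i, ln t_i) — the analytic oracle for the multi-modal
#' solution structure the swarm recovers numerically.
#'
#' @param op1,op2 Lists with elements `tau` (Pa), `t_res` (s) and `mih`
#'   (target MIH, > 0).
#' @return A [line3d]; errors when the two planes are parallel (identical
#'   (tau, t_res) up to scaling of the normals).
#' @export
analytic_solution_line <- function(op1, op2) {
  pl <- function(op) {
    check_scalar_number(op$tau, "tau", positive = TRUE)
    check_scalar_number(op$t_res, "t_res", positive = TRUE)
    check_scalar_number(op$mih, "mih", positive = TRUE)
    list(n = c(1, log(op$tau), log(op$t_res)), b = log(op$mih * 1e-6))
  }
  p1 <- pl(op1); p2 <- pl(op2)
  d <- c(p1$n[2] * p2$n[3] - p1$n[3] * p2$n[2],
         p1$n[3] * p2$n[1] - p1$n[1] * p2$n[3],
         p1$n[1] * p2$n[2] - p1$n[2] * p2$n[1])
  if (sqrt(sum(d^2)) < 1e-12 * sqrt(sum(p1$n^2)) * sqrt(sum(p2$n^2))) {
    stop("degenerate: the two operating points define parallel planes",
         call. = FALSE)
  }
  # minimum-norm point satisfying both plane equations
  A <- rbind(p1$n, p2$n)
  b <- c(p1$b, p2$b)
  x0 <- drop(t(A) %*% solve(A %*% t(A), b))
  line3d(x0, d)
}
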