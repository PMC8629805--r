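#' Trajectory container for simulated or tracked motion data
#'
#' Per-timestep positions, headings and velocities of `n` agents, stored as
#' `T x n` matrices (`T = steps + 1`, including the initial state).
#'
#' @param x,y,theta,vx,vy `T x n` matrices.
#' @param L box size (`NA` for open space).
#' @param periodic whether positions wrap modulo `L`.
#' @param dt timestep.
#' @param params named list of model parameters.
#' @param seed RNG seed used to generate the trajectory.
#' @param labels optional group label per agent.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(x, y, theta, vx, vy, L = NA, periodic = FALSE,
                       dt = 1, params = list(), seed = NULL, labels = NULL) {
  stopifnot(all(dim(x) == dim(y)), all(dim(x) == dim(theta)))
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("trajectory contains non-finite positions")
  }
  structure(
    list(x = x, y = y, theta = theta, vx = vx, vy = vy,
         n = ncol(x), steps = nrow(x) - 1L, L = L, periodic = periodic,
         dt = dt, params = params, seed = seed, labels = labels),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory:", x$n, "agents,", x$steps, "steps, dt =", x$dt,
      if (x$periodic) sprintf("(periodic box L = %g)", x$L) else "(open space)",
      "\n")
  invisible(x)
}

#' @export
plot.trajectory <- function(x, t = nrow(x$x), arrow_scale = 3, ...) {
  cols <- if (is.null(x$labels)) "black" else x$labels + 1
  graphics::plot(x$x[t, ], x$y[t, ], pch = 16, col = cols,
                 xlab = "x", ylab = "y", asp = 1, ...)
  graphics::arrows(x$x[t, ], x$y[t, ],
                   x$x[t, ] + arrow_scale * x$vx[t, ] * x$dt,
                   x$y[t, ] + arrow_scale * x$vy[t, ] * x$dt,
                   length = 0.03, col = cols)
  invisible(x)
}

#' Polarization (mean alignment) of a trajectory
#'
#' The magnitude of the mean unit-velocity vector across agents: 1 when all
#' agents head the same way, near 0 for isotropic headings (of order
#' `n^{-1/2}` for independent agents).
#'
#' @param traj a [trajectory()].
#' @param t time index (row); `NULL` for the full series.
#' @return scalar in `[0, 1]`, or a vector over time when `t` is `NULL`.
#' @export
polarization <- function(traj, t = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  pol_row <- function(tt) {
    sp <- sqrt(traj$vx[tt, ]^2 + traj$vy[tt, ]^2)
    sp[sp == 0] <- 1
    sqrt(mean(traj$vx[tt, ] / sp)^2 + mean(traj$vy[tt, ] / sp)^2)
  }
  if (!is.null(t)) return(pol_row(t))
  vapply(seq_len(nrow(traj$vx)), pol_row, numeric(1))
}

#' Time-averaged polarization and its temporal standard deviation
#'
#' @param traj a [trajectory()].
#' @param burn_in initial steps to discard.
#' @return list with `mean`, `sd`, and the `series`.
#' @export
polarization_stats <- function(traj, burn_in = 0) {
  series <- polarization(traj)
  if (burn_in > 0) series <- series[-seq_len(burn_in)]
  list(mean = mean(series), sd = stats::sd(series), series = series)
}

#' Velocity observation matrix from a trajectory
#'
#' Stacks the planar velocity components of every agent into a `T x 2n`
#' observation matrix (element `i` owning columns `vx_i, vy_i`), optionally
#' discarding a burn-in and truncating to an analysis window.
#'
#' @param traj a [trajectory()].
#' @param burn_in initial steps to discard.
#' @param window number of steps to keep after the burn-in (`NULL` = all).
#' @return an [observation_matrix()] with `k_i = 2` per agent.
#' @export
trajectory_observations <- function(traj, burn_in = 0, window = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  rows <- seq_len(nrow(traj$vx))
  if (burn_in > 0) rows <- rows[-seq_len(burn_in)]
  if (!is.null(window)) rows <- rows[seq_len(min(window, length(rows)))]
  if (length(rows) < 3) stop("analysis window too short")
  vals <- matrix(0, length(rows), 2 * traj$n)
  for (i in seq_len(traj$n)) {
    vals[, 2 * i - 1] <- traj$vx[rows, i]
    vals[, 2 * i] <- traj$vy[rows, i]
  }
  colnames(vals) <- as.vector(rbind(paste0("vx", seq_len(traj$n)),
                                    paste0("vy", seq_len(traj$n))))
  observation_matrix(vals, element_map_blocks(traj$n, 2),
                     units = "velocity")
}

#' Heading observation matrix from a trajectory
#'
#' Scalar-element alternative to [trajectory_observations()]: one heading
#' column per agent. Headings are circular, so all columns are rotated by
#' the global circular mean heading and wrapped to `(-pi, pi]` before use;
#' this places the wrap cut where the heading density is lowest (a single
#' common rotation, which preserves the relative structure across agents).
#'
#' @inheritParams trajectory_observations
#' @return an [observation_matrix()] with `k_i = 1` per agent.
#' @export
trajectory_heading_observations <- function(traj, burn_in = 0, window = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  rows <- seq_len(nrow(traj$theta))
  if (burn_in > 0) rows <- rows[-seq_len(burn_in)]
  if (!is.null(window)) rows <- rows[seq_len(min(window, length(rows)))]
  th <- traj$theta[rows, , drop = FALSE]
  mu <- atan2(mean(sin(th)), mean(cos(th)))
  vals <- ((th - mu + pi) %% (2 * pi)) - pi
  colnames(vals) <- paste0("theta", seq_len(traj$n))
  observation_matrix(vals, units = "radians")
}

#' Write / read a trajectory as tidy CSV plus a JSON parameter sidecar
#'
#' Columns: `t, id, x, y, vx, vy, theta`; agent ids are 0-based.
#'
#' @param traj a [trajectory()].
#' @param path CSV file path (sidecar at `paste0(path, ".json")`).
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns the trajectory.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  Tn <- nrow(traj$x)
  df <- data.frame(
    t = rep(seq_len(Tn) - 1L, traj$n),
    id = rep(seq_len(traj$n) - 1L, each = Tn),
    x = as.vector(traj$x), y = as.vector(traj$y),
    vx = as.vector(traj$vx), vy = as.vector(traj$vy),
    theta = as.vector(traj$theta)
  )
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- list(L = traj$L, periodic = traj$periodic, dt = traj$dt,
                  params = traj$params, seed = traj$seed,
                  labels = traj$labels, n = traj$n, steps = traj$steps)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- sc$n
  Tn <- sc$steps + 1L
  shape <- function(col) matrix(df[[col]], nrow = Tn, ncol = n)
  trajectory(shape("x"), shape("y"), shape("theta"), shape("vx"),
             shape("vy"), L = if (is.null(sc$L)) NA else sc$L,
             periodic = isTRUE(sc$periodic), dt = sc$dt,
             params = as.list(sc$params), seed = sc$seed,
             labels = sc$labels)
}
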