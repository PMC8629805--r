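#' System redundancy of a trajectory window
#'
#' Convenience wrapper: velocities over an analysis window ->
#' rank-Gaussianize -> Gaussian model -> relative redundancy of the full
#' system.
#'
#' @param traj a [trajectory()].
#' @param burn_in steps discarded before the window.
#' @param window window length in steps (`NULL` = rest of the run).
#' @param alpha quantization offset, nats per variate.
#' @param headings use scalar headings instead of 2-D velocities.
#' @return scalar redundancy lower bound in `[0, 1)`.
#' @export
system_redundancy <- function(traj, burn_in = 0, window = NULL,
                              alpha = bits_to_nats(4), headings = FALSE) {
  obs <- if (headings) {
    trajectory_heading_observations(traj, burn_in, window)
  } else {
    trajectory_observations(traj, burn_in, window)
  }
  model <- estimate_gaussian_model(rank_gaussianize(obs), alpha = alpha)
  gaussian_relative_redundancy(model, seq_len(model$n))
}

#' Redundancy-versus-noise sweep for the Vicsek model
#'
#' For every noise level in `eta_grid` and every replicate: simulate, discard
#' the burn-in, build the velocity observation matrix over the analysis
#' window, rank-Gaussianize, and record the system redundancy bound, the
#' time-averaged polarization and its temporal standard deviation. Each
#' (noise, replicate) cell contributes one redundancy sample; replicate `k`
#' uses the same derived seed at every noise level, so comparisons across
#' noise are paired.
#'
#' Elements are scalar headings by default. In the coherently ordered state
#' an agent's two velocity components are deterministic functions of its
#' (nearly constant) heading and become exactly collinear after rank
#' transformation, which degenerates the velocity-based Gaussian bound;
#' headings avoid this. Set `headings = FALSE` for the 2-D velocity variant.
#'
#' @param eta_grid noise levels to scan.
#' @param n,L,d,c Vicsek parameters (defaults `n = 50`, `d = 0.2`, `L = 1`,
#'   `c = 0.03`).
#' @param burn_in steps run to reach steady state before measuring.
#' @param window measurement window, steps.
#' @param replicates simulations per noise level.
#' @param alpha quantization offset, nats per variate.
#' @param seed RNG seed; replicate `k` uses `seed + k` at every noise level.
#' @param mode_link_threshold distance in redundancy units within which modes
#'   at adjacent noise levels are linked.
#' @return object of class `sweep_result`: `eta`, `redundancy` (replicates x
#'   noise matrix), `polarization_mean`, `polarization_sd` (same shape),
#'   `modes` (per noise level), `mode_links`.
#' @export
redundancy_vs_noise_sweep <- function(eta_grid, n = 50, L = 1, d = 0.2,
                                      c = 0.03, burn_in = 500, window = 1000,
                                      replicates = 3,
                                      alpha = bits_to_nats(4), seed = 1,
                                      mode_link_threshold = 0.05,
                                      headings = TRUE) {
  ne <- length(eta_grid)
  red <- pm <- ps <- matrix(NA_real_, replicates, ne,
                            dimnames = list(NULL, paste0("eta", eta_grid)))
  for (e in seq_len(ne)) {
    for (k in seq_len(replicates)) {
      traj <- vicsek_simulate(n = n, L = L, d = d, eta = eta_grid[e], c = c,
                              steps = burn_in + window, seed = seed + k)
      red[k, e] <- system_redundancy(traj, burn_in = burn_in, window = window,
                                     alpha = alpha, headings = headings)
      st <- polarization_stats(traj, burn_in = burn_in)
      pm[k, e] <- st$mean
      ps[k, e] <- st$sd
    }
  }
  modes <- lapply(seq_len(ne), function(e) density_modes(red[, e]))
  links <- link_modes(modes, eta_grid, mode_link_threshold)
  structure(
    list(eta = eta_grid, redundancy = red, polarization_mean = pm,
         polarization_sd = ps, modes = modes, mode_links = links,
         replicates = replicates,
         settings = list(n = n, L = L, d = d, c = c, burn_in = burn_in,
                         window = window, alpha = alpha, seed = seed)),
    class = "sweep_result"
  )
}

#' Modes of a sample by kernel density estimation
#'
#' Gaussian KDE with Silverman's bandwidth rule; modes are local maxima of
#' the density whose height is at least `density_floor` times the global
#' maximum (suppressing spurious shoulders).
#'
#' @param x numeric sample (nonempty).
#' @param bw bandwidth or selection rule, passed to [stats::density()].
#' @param density_floor minimum height relative to the global maximum.
#' @return numeric vector of mode locations.
#' @export
density_modes <- function(x, bw = "nrd0", density_floor = 0.2) {
  if (length(x) == 0) stop("empty sample: no modes to estimate")
  if (length(x) == 1 || max(x) - min(x) == 0) return(unique(x)[1])
  den <- stats::density(x, bw = bw)
  y <- den$y
  k <- length(y)
  is_max <- c(FALSE, y[2:(k - 1)] > y[1:(k - 2)] & y[2:(k - 1)] > y[3:k], FALSE)
  floor_ok <- y >= density_floor * max(y)
  den$x[is_max & floor_ok]
}

#' Estimate and link redundancy-distribution modes across noise levels
#'
#' @param samples list of numeric samples, one per noise level.
#' @param eta_grid the noise levels (for labeling the links).
#' @param link_threshold maximum distance (redundancy units) for modes at
#'   adjacent noise levels to be linked into one branch.
#' @param ... passed to [density_modes()].
#' @return list with per-level `modes` and a data frame of `links`.
#' @export
estimate_modes <- function(samples, eta_grid = seq_along(samples),
                           link_threshold = 0.05, ...) {
  modes <- lapply(samples, density_modes, ...)
  list(modes = modes, links = link_modes(modes, eta_grid, link_threshold))
}

link_modes <- function(modes, eta_grid, threshold) {
  links <- NULL
  for (e in seq_len(length(modes) - 1)) {
    for (a in modes[[e]]) {
      for (b in modes[[e + 1]]) {
        if (abs(a - b) <= threshold) {
          links <- rbind(links, data.frame(
            eta_from = eta_grid[e], eta_to = eta_grid[e + 1],
            mode_from = a, mode_to = b))
        }
      }
    }
  }
  if (is.null(links)) {
    links <- data.frame(eta_from = numeric(0), eta_to = numeric(0),
                        mode_from = numeric(0), mode_to = numeric(0))
  }
  links
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Redundancy-vs-noise sweep:", length(x$eta), "noise levels x",
      x$replicates, "replicates\n")
  df <- data.frame(eta = x$eta,
                   mean_redundancy = colMeans(x$redundancy),
                   mean_polarization = colMeans(x$polarization_mean),
                   n_modes = vapply(x$modes, length, integer(1)))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::matplot(x$eta, t(x$redundancy), pch = 16, col = "grey40",
                    xlab = expression(eta), ylab = "redundancy", log = "x", ...)
  for (e in seq_along(x$eta)) {
    graphics::points(rep(x$eta[e], length(x$modes[[e]])), x$modes[[e]],
                     col = "purple", pch = 17)
  }
  graphics::plot(x$eta, colMeans(x$polarization_mean), type = "b", col = "red",
                 xlab = expression(eta), ylab = "mean alignment", log = "x",
                 ylim = c(0, 1))
  invisible(x)
}

#' Serialize a sweep result to CSV (samples) and JSON (settings and modes)
#'
#' @param x a `sweep_result`.
#' @param path base path: samples go to `paste0(path, ".csv")`, the rest to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(x, path) {
  stopifnot(inherits(x, "sweep_result"))
  long <- data.frame(
    eta = rep(x$eta, each = x$replicates),
    replicate = rep(seq_len(x$replicates), length(x$eta)),
    redundancy = as.vector(x$redundancy),
    polarization_mean = as.vector(x$polarization_mean),
    polarization_sd = as.vector(x$polarization_sd)
  )
  utils::write.csv(long, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(eta = x$eta, modes = x$modes, mode_links = x$mode_links,
         replicates = x$replicates, settings = x$settings),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
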