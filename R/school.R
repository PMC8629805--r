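#' Zone-based schooling model (attraction, alignment, repulsion)
#'
#' Self-propelled agents at constant speed in open 2-D space. Each step,
#' agent `i` computes a desired direction from three social zones:
#' short-range repulsion (away from neighbors closer than `r_rep`, which
#' overrides everything else), alignment with the headings of neighbors
#' within `r_align`, and attraction toward neighbors within `r_att` (each
#' attracting neighbor weighted by its relative distance `dist / r_att`, so
#' agents drifting toward the edge of the group turn back harder). The
#' heading relaxes toward the desired direction at rate `kappa` and receives
#' additive angular noise with standard deviation `eta * sqrt(dt)` per step.
#' The defaults produce a single cohesive, polarized group at the noise
#' levels used throughout the package (`eta` = 0.15 and 0.2); cohesion
#' (no agent further than `5 * r_att` from the centroid after burn-in) and
#' polarization (time-averaged > 0.8) self-checks are recorded in the
#' returned parameters.
#'
#' @param n number of agents (`>= 2`).
#' @param eta angular noise scale (radians per sqrt(time unit)).
#' @param params optional overrides of the model defaults
#'   (`r_rep = 0.2`, `r_align = 1`, `r_att = 2`, `speed = 1`, `dt = 0.1`,
#'   `kappa = 5`, `w_align = 1`, `w_att = 0.5`).
#' @param steps number of update steps.
#' @param seed RNG seed.
#' @param self_check_burn_in steps discarded before the cohesion and
#'   polarization self-checks (`NULL` skips the checks).
#' @return a [trajectory()]; `$params$self_check` records the check outcome.
#' @export
school_simulate <- function(n, eta = 0.2, params = list(), steps = 1500,
                            seed = NULL, self_check_burn_in = 500) {
  if (n < 2) stop("n must be >= 2")
  defaults <- list(r_rep = 0.2, r_align = 1.0, r_att = 2.0, speed = 1.0,
                   dt = 0.1, kappa = 5.0, w_align = 1.0, w_att = 0.5,
                   init_radius = 0.75, init_heading_sd = 0.2)
  p <- utils::modifyList(defaults, params)
  if (!is.null(seed)) set.seed(seed)
  Tn <- steps + 1L
  X <- Y <- TH <- VX <- VY <- matrix(0, Tn, n)
  # start as a compact disk with a roughly shared heading
  ang <- stats::runif(n, 0, 2 * pi)
  rad <- p$init_radius * sqrt(stats::runif(n))
  px <- rad * cos(ang)
  py <- rad * sin(ang)
  th0 <- stats::runif(1, -pi, pi)
  th <- th0 + stats::rnorm(n, sd = p$init_heading_sd)
  noise_sd <- eta * sqrt(p$dt)
  for (t in seq_len(Tn)) {
    vx <- p$speed * cos(th)
    vy <- p$speed * sin(th)
    X[t, ] <- px; Y[t, ] <- py; TH[t, ] <- th; VX[t, ] <- vx; VY[t, ] <- vy
    if (t == Tn) break
    dx <- outer(px, px, "-")   # dx[i, j] = px[i] - px[j]
    dy <- outer(py, py, "-")
    dist <- sqrt(dx * dx + dy * dy)
    diag(dist) <- Inf
    ux <- dx / dist; uy <- dy / dist   # unit vector from j toward i
    des_x <- numeric(n); des_y <- numeric(n)
    # nested Couzin-style shells: repulsion < alignment < attraction
    rep_n <- dist < p$r_rep
    ali_n <- dist < p$r_align
    att_n <- dist >= p$r_align & dist < p$r_att
    for (i in seq_len(n)) {
      if (any(rep_n[i, ])) {       # flee: away from too-close neighbors
        des_x[i] <- sum(ux[i, rep_n[i, ]])
        des_y[i] <- sum(uy[i, rep_n[i, ]])
      } else {
        ax <- ay <- 0
        if (any(ali_n[i, ])) {
          ax <- mean(cos(th[ali_n[i, ]]))
          ay <- mean(sin(th[ali_n[i, ]]))
        }
        tx <- ty <- 0
        if (any(att_n[i, ])) {
          att <- att_n[i, ]
          w <- dist[i, att] / p$r_att   # pull harder on far neighbors
          tx <- -sum(ux[i, att] * w) / sum(att)   # toward neighbors
          ty <- -sum(uy[i, att] * w) / sum(att)
        }
        des_x[i] <- p$w_align * ax + p$w_att * tx
        des_y[i] <- p$w_align * ay + p$w_att * ty
      }
    }
    zero <- des_x == 0 & des_y == 0
    phi <- atan2(des_y, des_x)
    phi[zero] <- th[zero]   # nothing to react to: keep heading
    dtheta <- ((phi - th + pi) %% (2 * pi)) - pi
    th <- th + p$kappa * p$dt * dtheta + stats::rnorm(n, sd = noise_sd)
    px <- px + vx * p$dt
    py <- py + vy * p$dt
  }
  params_out <- c(p, list(model = "school", eta = eta))
  traj <- trajectory(X, Y, TH, VX, VY, L = NA, periodic = FALSE, dt = p$dt,
                     params = params_out, seed = seed)
  if (!is.null(self_check_burn_in) && steps > self_check_burn_in) {
    keep <- (self_check_burn_in + 1L):Tn
    cx <- rowMeans(X[keep, , drop = FALSE])
    cy <- rowMeans(Y[keep, , drop = FALSE])
    spread <- sqrt((X[keep, , drop = FALSE] - cx)^2 +
                   (Y[keep, , drop = FALSE] - cy)^2)
    cohesive <- max(spread) <= 5 * p$r_att
    pol <- mean(polarization(traj)[keep])
    polarized <- pol > 0.8
    traj$params$self_check <- list(cohesive = cohesive, polarized = polarized,
                                   max_spread = max(spread),
                                   mean_polarization = pol)
    if (!cohesive || !polarized) {
      warning(sprintf("schooling self-check failed (cohesive = %s, polarized = %s, mean polarization = %.3f)",
                      cohesive, polarized, pol))
    }
  }
  traj
}

#' Simulate non-interacting groups in one system
#'
#' Each group is an independent [school_simulate()] run with its own derived
#' seed; groups are offset in space so they never overlap, but downstream
#' analyses never use position (or the returned labels) — coordination is
#' measured from velocities alone.
#'
#' @param group_sizes integer vector of group sizes.
#' @param eta angular noise scale shared by the groups.
#' @param steps steps per group.
#' @param seed RNG seed; group `g` uses `seed + g`.
#' @param params optional shared model overrides.
#' @return a [trajectory()] whose `labels` field gives the true group of
#'   each agent.
#' @export
independent_groups <- function(group_sizes, eta = 0.2, steps = 1500,
                               seed = NULL, params = list()) {
  stopifnot(length(group_sizes) >= 1, all(group_sizes >= 2))
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  runs <- lapply(seq_along(group_sizes), function(g) {
    school_simulate(group_sizes[g], eta = eta, params = params, steps = steps,
                    seed = if (is.null(base_seed)) NULL else base_seed + g)
  })
  offset <- 100 * (seq_along(group_sizes) - 1)
  X <- do.call(cbind, lapply(seq_along(runs), function(g) runs[[g]]$x + offset[g]))
  Y <- do.call(cbind, lapply(runs, `[[`, "y"))
  TH <- do.call(cbind, lapply(runs, `[[`, "theta"))
  VX <- do.call(cbind, lapply(runs, `[[`, "vx"))
  VY <- do.call(cbind, lapply(runs, `[[`, "vy"))
  labels <- rep(seq_along(group_sizes), group_sizes)
  trajectory(X, Y, TH, VX, VY, L = NA, periodic = FALSE,
             dt = runs[[1]]$dt,
             params = c(runs[[1]]$params,
                        list(group_sizes = group_sizes)),
             seed = base_seed, labels = labels)
}
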