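#' Vicsek alignment model
#'
#' Self-propelled particles at constant speed `c` in a periodic box of side
#' `L`. At each step every agent adopts the angular average heading of
#' itself and all neighbors within distance `d` (direction of the summed
#' unit heading vectors) plus angular noise drawn uniformly from
#' `[-eta/2, eta/2]`; positions advance by the current velocity
#' (`dt = 1`) and wrap modulo `L`. Low noise yields a globally aligned
#' (ordered) state, high noise a disordered one.
#'
#' @param n number of agents.
#' @param L box side length.
#' @param d interaction radius.
#' @param eta noise amplitude in radians (`0 <= eta <= 2*pi`).
#' @param c constant speed (0.03 by convention).
#' @param steps number of update steps.
#' @param seed RNG seed.
#' @return a [trajectory()] with `steps + 1` recorded states.
#' @export
vicsek_simulate <- function(n, L = 1, d = 0.2, eta = 0.5, c = 0.03,
                            steps = 100, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (eta < 0 || eta > 2 * pi) stop("eta must lie in [0, 2*pi]")
  if (d <= 0 || L <= 0) stop("d and L must be positive")
  if (!is.null(seed)) set.seed(seed)
  Tn <- steps + 1L
  X <- Y <- TH <- VX <- VY <- matrix(0, Tn, n)
  px <- stats::runif(n, 0, L)
  py <- stats::runif(n, 0, L)
  th <- stats::runif(n, -pi, pi)
  for (t in seq_len(Tn)) {
    vx <- c * cos(th)
    vy <- c * sin(th)
    X[t, ] <- px; Y[t, ] <- py; TH[t, ] <- th; VX[t, ] <- vx; VY[t, ] <- vy
    if (t == Tn) break
    # positions advance with the time-t velocity
    px <- (px + vx) %% L
    py <- (py + vy) %% L
    # heading update from time-t neighborhoods (periodic minimum image)
    dx <- abs(outer(px0 <- X[t, ], px0, "-")); dx <- pmin(dx, L - dx)
    dy <- abs(outer(py0 <- Y[t, ], py0, "-")); dy <- pmin(dy, L - dy)
    nbr <- (dx * dx + dy * dy) <= d * d   # includes self (diagonal)
    sx <- nbr %*% cos(th)
    sy <- nbr %*% sin(th)
    th <- atan2(sy, sx)[, 1] + stats::runif(n, -eta / 2, eta / 2)
  }
  trajectory(X, Y, TH, VX, VY, L = L, periodic = TRUE, dt = 1,
             params = list(model = "vicsek", d = d, eta = eta, c = c),
             seed = seed)
}
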