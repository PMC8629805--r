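#' Delta-average-redundancy structure scan
#'
#' Solves the partitioning problem for every component count
#' `m = 1..m_max`, records the best average component redundancy per `m`,
#' and forms the change curve `Delta(m) = rbar(m-1) - rbar(m)` for
#' `m >= 2`. Small changes mean the split separated relatively independent
#' parts of the system; a large jump after a small change means a strongly
#' coordinated component was cut. The first local minimum of the Delta
#' curve is the structure-count heuristic: it marks the largest number of
#' components that can be separated cheaply.
#'
#' The signed `Delta` values are stored, but minima are detected on the
#' magnitude `|Delta(m)|` (the two agree wherever the average redundancy is
#' non-increasing in `m`; with independent groups of unequal sizes the
#' average redundancy can rise slightly while they are being separated). A
#' local minimum at `m` requires `|Delta(m)| < |Delta(m+1)|` and, for
#' `m > 2`, also `|Delta(m)| < |Delta(m-1)|` (the left end of the curve is
#' tested one-sidedly; the right end cannot qualify). Ties within `1e-12`
#' count as equal and are broken toward smaller `m`.
#'
#' @param model a `gaussian_model`.
#' @param m_max largest number of components to scan (`>= 2`).
#' @param restarts random initializations per `m`.
#' @param seed RNG seed.
#' @param solver `"hard"` (default) or `"soft"`.
#' @param ... further arguments to [solve_hard()] or [solve_partition()].
#' @return object of class `delta_curve` with fields `m_values`,
#'   `best_average_redundancy`, `delta` (named by `m`, defined for
#'   `m >= 2`), `local_minima`, `first_local_minimum` (NA when the Delta
#'   sequence is monotone), and the per-`m` hard labels.
#' @export
component_scan <- function(model, m_max = 10, restarts = 100, seed = NULL,
                           solver = c("hard", "soft"), ...) {
  stopifnot(m_max >= 2)
  solver <- match.arg(solver)
  if (!is.null(seed)) set.seed(seed)
  m_values <- seq_len(m_max)
  rbar <- numeric(m_max)
  labels_by_m <- vector("list", m_max)
  for (m in m_values) {
    fit <- if (solver == "hard") {
      solve_hard(model, m = m, restarts = restarts, ...)
    } else {
      solve_partition(model, m = m, restarts = restarts, ...)
    }
    rbar[m] <- fit$average_redundancy
    labels_by_m[[m]] <- fit$hard_labels
  }
  delta <- rbar[m_values[-m_max]] - rbar[-1]
  names(delta) <- m_values[-1]
  delta_curve(m_values, rbar, delta, labels_by_m = labels_by_m)
}

#' Assemble a delta curve from precomputed values
#'
#' @param m_values component counts `1..m_max`.
#' @param best_average_redundancy best average redundancy per `m`.
#' @param delta optional precomputed drops (`m >= 2`); derived otherwise.
#' @param labels_by_m optional per-`m` hard labels.
#' @return a `delta_curve`.
#' @export
delta_curve <- function(m_values, best_average_redundancy, delta = NULL,
                        labels_by_m = NULL) {
  stopifnot(length(m_values) == length(best_average_redundancy))
  if (is.null(delta)) {
    delta <- best_average_redundancy[-length(m_values)] -
      best_average_redundancy[-1]
    names(delta) <- m_values[-1]
  }
  lm_idx <- delta_local_minima(delta)
  structure(
    list(m_values = m_values,
         best_average_redundancy = best_average_redundancy,
         delta = delta, local_minima = lm_idx,
         first_local_minimum = if (length(lm_idx)) lm_idx[1] else NA_integer_,
         labels_by_m = labels_by_m),
    class = "delta_curve"
  )
}

# Local minima of the Delta sequence (names give m). The drop curve is the
# magnitude of the change in average redundancy, so minima are detected on
# |Delta| (identical to the signed curve wherever the average redundancy is
# non-increasing in m). Ties within 1e-12 are equal; the left end is
# one-sided, the right end never qualifies.
delta_local_minima <- function(delta, tol = 1e-12) {
  delta <- abs(delta)
  ms <- as.integer(names(delta))
  k <- length(delta)
  if (k < 2) return(integer(0))
  out <- integer(0)
  for (idx in seq_len(k - 1)) {
    left_ok <- idx == 1 || delta[idx] < delta[idx - 1] - tol
    right_ok <- delta[idx] < delta[idx + 1] - tol
    if (left_ok && right_ok) out <- c(out, ms[idx])
  }
  out
}

#' @export
print.delta_curve <- function(x, ...) {
  cat("Delta-average-redundancy scan over m = 1..",
      max(x$m_values), "\n", sep = "")
  df <- data.frame(m = x$m_values,
                   avg_redundancy = round(x$best_average_redundancy, 6),
                   delta = c(NA, round(x$delta, 6)))
  print(df, row.names = FALSE)
  if (is.na(x$first_local_minimum)) {
    cat("No local minimum in Delta (monotone sequence)\n")
  } else {
    cat("Local minima at m =", paste(x$local_minima, collapse = ", "),
        "| first:", x$first_local_minimum, "\n")
  }
  invisible(x)
}

#' @export
plot.delta_curve <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$m_values, x$best_average_redundancy, type = "b",
                 xlab = "components (m)", ylab = "avg redundancy", ...)
  graphics::plot(as.integer(names(x$delta)), x$delta, type = "b",
                 xlab = "components (m)", ylab = expression(Delta ~ "avg redundancy"))
  if (!is.na(x$first_local_minimum)) {
    graphics::abline(v = x$first_local_minimum, lty = 2)
  }
  invisible(x)
}

#' Serialize a delta curve to JSON
#'
#' @param x a `delta_curve`.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_delta_curve <- function(x, path) {
  stopifnot(inherits(x, "delta_curve"))
  obj <- list(m_values = x$m_values,
              best_average_redundancy = x$best_average_redundancy,
              delta = as.list(x$delta), local_minima = x$local_minima,
              first_local_minimum = x$first_local_minimum,
              labels_by_m = x$labels_by_m)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
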