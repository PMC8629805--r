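#' Solve the soft redundancy-partitioning problem
#'
#' Alternating minimization for the probabilistic assignment of `n` elements
#' to `m` components that maximizes the equally weighted average expected
#' component redundancy at inverse temperature `beta`. Each restart begins
#' from rows drawn from a symmetric Dirichlet (concentration 1) and iterates
#' [iterate_assignment()] until the average redundancy changes by less than
#' `tol` or `max_iter` cycles elapse; the best solution over restarts is
#' returned. Only local optimality is guaranteed, hence the restarts.
#'
#' @param x a `gaussian_model`, or a subset-redundancy function (in which
#'   case `n` must be given).
#' @param m number of components (`m >= 1`; `m > n` is allowed, surplus
#'   components simply end up empty).
#' @param beta inverse temperature; large values (e.g. 200) give effectively
#'   hard assignments.
#' @param restarts number of random initializations.
#' @param max_iter maximum update cycles per restart.
#' @param tol convergence tolerance on the average redundancy.
#' @param estimator `"exact"` (power-set enumeration, `n <= 15`) or `"mc"`.
#' @param K Monte-Carlo sample count for `estimator = "mc"`.
#' @param seed optional RNG seed (integer).
#' @param n number of elements when `x` is a function.
#' @return object of class `partition_result`.
#' @export
solve_partition <- function(x, m, beta = 200, restarts = 10, max_iter = 500,
                            tol = 1e-9, estimator = c("exact", "mc"),
                            K = 1e4, seed = NULL, n = NULL) {
  estimator <- match.arg(estimator)
  if (inherits(x, "gaussian_model")) {
    r_fn <- subset_redundancy_fn(x)
    n <- x$n
  } else if (is.function(x)) {
    if (is.null(n)) stop("'n' is required when 'x' is a function")
    r_fn <- x
  } else stop("'x' must be a gaussian_model or a subset-redundancy function")
  stopifnot(m >= 1, restarts >= 1)
  if (!is.null(seed)) set.seed(seed)
  all_r <- if (estimator == "exact") precompute_subset_redundancy(r_fn, n) else NULL

  best <- NULL
  for (rep in seq_len(restarts)) {
    g <- matrix(stats::rexp(n * m), n, m)
    a <- assignment(g / rowSums(g), beta = beta)
    obj <- average_redundancy(a, r_fn, all_r = all_r)
    trace <- obj
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      a <- iterate_assignment(a, r_fn, estimator = estimator, K = K,
                              all_r = all_r)
      obj_new <- average_redundancy(a, r_fn, all_r = all_r)
      trace <- c(trace, obj_new)
      if (abs(obj_new - obj) < tol) {
        obj <- obj_new
        converged <- TRUE
        break
      }
      obj <- obj_new
    }
    if (!converged) {
      message(sprintf("restart %d: no convergence after %d iterations; keeping last iterate", rep, max_iter))
    }
    if (is.null(best) || obj > best$average_redundancy) {
      comp_r <- vapply(seq_len(m), function(j) {
        if (estimator == "exact") {
          expected_component_redundancy(a, j, r_fn, all_r = all_r)
        } else {
          expected_component_redundancy_mc(a, j, r_fn, K)
        }
      }, numeric(1))
      best <- partition_result(
        assignment = a, component_redundancy = comp_r,
        average_redundancy = mean(comp_r), rate = achieved_rate(a),
        objective_trace = trace,
        hard_labels = max.col(a$p_j_given_i, ties.method = "first"),
        n_restarts_used = restarts, seed = seed,
        method = paste0("soft (", estimator, ")"), m = m, beta = beta,
        converged = converged
      )
    }
  }
  best
}

# Monte-Carlo E[r(A)|j] for systems beyond the exact enumeration cap
expected_component_redundancy_mc <- function(a, j, r_fn, K) {
  p <- a$p_j_given_i[, j]
  draws <- matrix(stats::runif(K * a$n) < rep(p, each = K), nrow = K)
  keys <- apply(draws, 1, function(b) paste(which(b), collapse = ","))
  uk <- unique(keys)
  vals <- vapply(uk, function(key) {
    A <- if (nzchar(key)) as.integer(strsplit(key, ",")[[1]]) else integer(0)
    if (length(A) <= 1) 0 else r_fn(A)
  }, numeric(1))
  mean(vals[match(keys, uk)])
}

#' Solve the hard redundancy-partitioning problem
#'
#' The hard-partition limit of the algorithm: assignments are one-hot and
#' each iteration only considers moving single elements between components.
#' Elements are visited in seeded random order; a move is accepted when it
#' strictly increases the average component redundancy (ties keep the
#' current component, tied gains go to the lowest component index). A
#' restart ends when a full pass makes no move; the best of `restarts`
#' seeded random initializations is returned. Subset redundancy uses the
#' Gaussian bound, evaluated by Cholesky factorization of principal
#' correlation submatrices.
#'
#' @param model a `gaussian_model`.
#' @param m number of components.
#' @param restarts number of random initializations.
#' @param max_passes safety cap on greedy passes per restart.
#' @param seed optional RNG seed.
#' @return object of class `partition_result` (with `hard_labels` set).
#' @export
solve_hard <- function(model, m, restarts = 100, max_passes = 200,
                       seed = NULL) {
  stopifnot(inherits(model, "gaussian_model"), m >= 1, restarts >= 1)
  if (!is.null(seed)) set.seed(seed)
  denom <- model$h + model$k * model$alpha
  res <- hard_partition_cpp(model$P, model$element_map, model$block_logdet,
                            denom, as.integer(m), as.integer(restarts),
                            as.integer(max_passes))
  a <- hard_assignment(res$labels, m = m, beta = Inf)
  partition_result(
    assignment = a, component_redundancy = as.numeric(res$component_redundancy),
    average_redundancy = res$average_redundancy, rate = achieved_rate(a),
    objective_trace = as.numeric(res$objective_trace),
    hard_labels = as.integer(res$labels),
    n_restarts_used = restarts, seed = seed, method = "hard", m = m,
    beta = Inf, converged = res$passes < max_passes
  )
}

partition_result <- function(assignment, component_redundancy,
                             average_redundancy, rate, objective_trace,
                             hard_labels, n_restarts_used, seed, method, m,
                             beta, converged) {
  structure(
    list(assignment = assignment,
         component_redundancy = component_redundancy,
         average_redundancy = average_redundancy, rate = rate,
         objective_trace = objective_trace, hard_labels = hard_labels,
         n_restarts_used = n_restarts_used, seed = seed, method = method,
         m = m, beta = beta, converged = converged),
    class = "partition_result"
  )
}

#' @export
print.partition_result <- function(x, ...) {
  cat("Redundancy partition (", x$method, "): ", x$assignment$n,
      " elements -> ", x$m, " components\n", sep = "")
  cat("  average component redundancy:", format(x$average_redundancy), "\n")
  cat("  achieved rate I(S;S_hat):", format(x$rate), "bits\n")
  cat("  component sizes:",
      paste(tabulate(x$hard_labels, nbins = x$m), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.partition_result <- function(object, ...) {
  cat("Redundancy partition summary\n")
  print(object)
  cat("  per-component expected redundancy:\n")
  print(round(object$component_redundancy, 6))
  cat("  restarts:", object$n_restarts_used,
      "| converged:", object$converged, "\n")
  invisible(object)
}

#' @export
labels.partition_result <- function(object, ...) object$hard_labels

#' Partition a system into maximally coordinated components
#'
#' The package's main fitting function. Accepts raw observations (a numeric
#' matrix or an [observation_matrix()]), rank-Gaussianizes them, estimates
#' the Gaussian redundancy model, and finds the assignment of elements to
#' `m` components that maximizes average expected component redundancy.
#'
#' @param x an [observation_matrix()], numeric matrix (columns grouped via
#'   `element_map`), or a prefitted `gaussian_model`.
#' @param m number of components.
#' @param method `"hard"` (default; greedy hard-partition limit) or
#'   `"soft"` (probabilistic assignments at finite `beta`).
#' @param element_map column grouping when `x` is a bare matrix.
#' @param alpha quantization offset, nats per variate.
#' @param restarts random initializations.
#' @param beta inverse temperature (soft method).
#' @param seed RNG seed.
#' @param ... further arguments to [solve_hard()] or [solve_partition()].
#' @return a `partition_result`, with the fitted `gaussian_model` attached
#'   as attribute `"model"`.
#' @examples
#' set.seed(1)
#' z <- matrix(rnorm(600), 200, 3)
#' x <- cbind(z[, 1], z[, 1] + rnorm(200, sd = 0.1),  # coordinated pair
#'            z[, 2], z[, 3])                          # two loners
#' fit <- redundancy_partition(x, m = 3, restarts = 20, seed = 1)
#' labels(fit)
#' @export
redundancy_partition <- function(x, m, method = c("hard", "soft"),
                                 element_map = NULL,
                                 alpha = bits_to_nats(4), restarts = 100,
                                 beta = 200, seed = NULL, ...) {
  method <- match.arg(method)
  model <- if (inherits(x, "gaussian_model")) {
    x
  } else {
    obs <- if (inherits(x, "observation_matrix")) x
           else observation_matrix(as.matrix(x), element_map = element_map)
    estimate_gaussian_model(rank_gaussianize(obs), alpha = alpha)
  }
  fit <- if (method == "hard") {
    solve_hard(model, m = m, restarts = restarts, seed = seed, ...)
  } else {
    solve_partition(model, m = m, beta = beta, restarts = restarts,
                    seed = seed, ...)
  }
  attr(fit, "model") <- model
  fit
}

#' Serialize a partition result to JSON (and labels to CSV)
#'
#' @param x a `partition_result`.
#' @param path JSON output path.
#' @param labels_csv optional CSV path for the two-column
#'   (element_id, component) hard-label table.
#' @return `path`, invisibly.
#' @export
write_partition <- function(x, path, labels_csv = NULL) {
  stopifnot(inherits(x, "partition_result"))
  obj <- list(
    m = x$m, method = x$method, beta = x$beta,
    p_j_given_i = apply(x$assignment$p_j_given_i, 1, as.numeric,
                        simplify = FALSE),
    component_redundancy = x$component_redundancy,
    average_redundancy = x$average_redundancy, rate_bits = x$rate,
    objective_trace = x$objective_trace, hard_labels = x$hard_labels,
    n_restarts_used = x$n_restarts_used, seed = x$seed,
    converged = x$converged, package_version = as.character(utils::packageVersion("redpart"))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(labels_csv)) {
    utils::write.csv(
      data.frame(element_id = seq_along(x$hard_labels),
                 component = x$hard_labels),
      labels_csv, row.names = FALSE)
  }
  invisible(path)
}
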