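#' Probabilistic assignment of elements to components
#'
#' The state of the partitioning algorithm: a row-stochastic `n x m` matrix
#' `p(j|i)` giving the probability that element `i` belongs to component `j`,
#' an element prior `p(i)` (uniform by default), the implied component
#' marginals `p(j) = sum_i p(j|i) p(i)`, and the inverse temperature `beta`
#' controlling how strongly assignments follow the redundancy gradient.
#'
#' @param p_j_given_i numeric `n x m` matrix; rows must sum to 1.
#' @param p_i element prior, length `n`; defaults to uniform.
#' @param beta nonnegative inverse temperature.
#' @return object of class `assignment`.
#' @export
assignment <- function(p_j_given_i, p_i = NULL, beta = 200) {
  p_j_given_i <- as.matrix(p_j_given_i)
  n <- nrow(p_j_given_i)
  m <- ncol(p_j_given_i)
  if (any(p_j_given_i < -1e-12) || any(p_j_given_i > 1 + 1e-12)) {
    stop("assignment probabilities must lie in [0, 1]")
  }
  p_j_given_i <- pmin(pmax(p_j_given_i, 0), 1)
  rs <- rowSums(p_j_given_i)
  if (any(abs(rs - 1) > 1e-10)) {
    stop("each row of p(j|i) must sum to 1")
  }
  if (is.null(p_i)) p_i <- rep(1 / n, n)
  if (length(p_i) != n || any(p_i < 0) || abs(sum(p_i) - 1) > 1e-10) {
    stop("p_i must be a probability vector of length n")
  }
  if (beta < 0) stop("beta must be nonnegative")
  structure(
    list(p_j_given_i = p_j_given_i, p_i = p_i,
         p_j = as.vector(crossprod(p_j_given_i, p_i)),
         beta = beta, n = n, m = m),
    class = "assignment"
  )
}

#' @export
print.assignment <- function(x, ...) {
  cat("Assignment:", x$n, "elements ->", x$m, "components, beta =", x$beta, "\n")
  invisible(x)
}

#' Hard assignment from a label vector
#'
#' @param labels integer component label per element (1..m).
#' @param m number of components (default `max(labels)`).
#' @param beta inverse temperature to record.
#' @return an [assignment()] with one-hot rows.
#' @export
hard_assignment <- function(labels, m = max(labels), beta = 200) {
  n <- length(labels)
  p <- matrix(0, n, m)
  p[cbind(seq_len(n), labels)] <- 1
  assignment(p, beta = beta)
}

#' Probability of a subset given a component
#'
#' `p(A|j) = prod_{i in A} p(j|i) * prod_{i not in A} (1 - p(j|i))`: the
#' Bernoulli product measure over subsets induced by the assignment column of
#' component `j`. Sums to 1 over the power set.
#'
#' @param a an [assignment()].
#' @param j component index.
#' @param A integer vector of element indices (possibly empty).
#' @return probability in `[0, 1]`.
#' @export
subset_probability <- function(a, j, A) {
  stopifnot(inherits(a, "assignment"))
  p <- a$p_j_given_i[, j]
  inA <- seq_len(a$n) %in% A
  prod(ifelse(inA, p, 1 - p))
}

# 2^n x n inclusion matrix: row (mask+1) gives the 0/1 membership of each of
# n items in subset `mask`.
subset_inclusion_matrix <- function(n) {
  masks <- 0:(2^n - 1)
  sapply(seq_len(n), function(b) bitwAnd(masks %/% 2^(b - 1), 1L))
}

# Bernoulli-product weights over all 2^length(p) subsets given inclusion
# probabilities p (exact at p = 0 or 1).
subset_weights <- function(p, inc = subset_inclusion_matrix(length(p))) {
  w <- rep(1, nrow(inc))
  for (k in seq_along(p)) {
    w <- w * ifelse(inc[, k] == 1, p[k], 1 - p[k])
  }
  w
}

#' Precompute r(A) for every subset of the system
#'
#' Enumerates all `2^n` subsets (capped at `n <= 15`) and evaluates the
#' subset-redundancy function once per subset. The resulting lookup vector is
#' shared by the exact expectation and derivative computations.
#'
#' @param r_fn subset-redundancy function (element-index vector -> value).
#' @param n number of elements.
#' @return numeric vector of length `2^n`, indexed by subset bitmask + 1.
#' @export
precompute_subset_redundancy <- function(r_fn, n) {
  if (n > 15) {
    stop("exact power-set enumeration is capped at n = 15 elements; ",
         "use the Monte-Carlo estimator for larger systems")
  }
  inc <- subset_inclusion_matrix(n)
  vapply(seq_len(nrow(inc)), function(row) {
    A <- which(inc[row, ] == 1)
    if (length(A) <= 1) 0 else r_fn(A)
  }, numeric(1))
}

# resolve (r_fn, all_r) bookkeeping shared by the exact operations
resolve_all_r <- function(a, r_fn, all_r) {
  if (is.null(all_r)) all_r <- precompute_subset_redundancy(r_fn, a$n)
  if (length(all_r) != 2^a$n) stop("all_r has the wrong length")
  all_r
}

#' Expected redundancy of a component
#'
#' `E[r(A)|j] = sum_{A in P(S)} r(A) p(A|j)`, the exact power-set average of
#' subset redundancy under the component's Bernoulli product measure.
#' Exact enumeration is capped at `n <= 15` elements.
#'
#' @param a an [assignment()].
#' @param j component index.
#' @param r_fn subset-redundancy function; must return 0 for the empty set
#'   and singletons.
#' @param all_r optional precomputed [precompute_subset_redundancy()] vector.
#' @return expected redundancy of component `j`.
#' @export
expected_component_redundancy <- function(a, j, r_fn, all_r = NULL) {
  stopifnot(inherits(a, "assignment"))
  all_r <- resolve_all_r(a, r_fn, all_r)
  inc <- subset_inclusion_matrix(a$n)
  w <- subset_weights(a$p_j_given_i[, j], inc)
  sum(all_r * w)
}

#' Average expected redundancy of an assignment
#'
#' `E[r(A)] = (1/m) sum_j E[r(A)|j]`: every component weighted equally,
#' including empty ones.
#'
#' @inheritParams expected_component_redundancy
#' @return scalar average redundancy.
#' @export
average_redundancy <- function(a, r_fn, all_r = NULL) {
  stopifnot(inherits(a, "assignment"))
  all_r <- resolve_all_r(a, r_fn, all_r)
  mean(vapply(seq_len(a$m), function(j) {
    expected_component_redundancy(a, j, r_fn, all_r = all_r)
  }, numeric(1)))
}

#' Exact marginal value of an element to a component
#'
#' `delta_d(i, j) = d(i, j) - d_c(i, j)`, where `d(i, j)` averages `r(A)`
#' over subsets containing `i` (weighted by the inclusion probabilities of
#' the other elements) and `d_c` over subsets excluding `i`, both scaled by
#' `1 / p(i)`. It is the expected gain in component-`j` redundancy from
#' including element `i` versus excluding it, and is proportional to the
#' derivative of `E[r(A)|j]` with respect to `p(j|i)`.
#'
#' @inheritParams expected_component_redundancy
#' @param i element index.
#' @return signed scalar.
#' @export
delta_d_exact <- function(a, i, j, r_fn, all_r = NULL) {
  stopifnot(inherits(a, "assignment"))
  if (a$p_i[i] <= 0) stop("p(i) must be positive")
  all_r <- resolve_all_r(a, r_fn, all_r)
  n <- a$n
  others <- setdiff(seq_len(n), i)
  if (length(others) == 0) return(0)
  inc <- subset_inclusion_matrix(length(others))
  w <- subset_weights(a$p_j_given_i[others, j], inc)
  base_mask <- as.vector(inc %*% 2^(others - 1))
  d_in <- sum(all_r[base_mask + 2^(i - 1) + 1] * w)
  d_out <- sum(all_r[base_mask + 1] * w)
  (d_in - d_out) / a$p_i[i]
}

#' Monte-Carlo estimate of the marginal value of an element
#'
#' Draws `K` subsets of the other elements by independent inclusion with
#' probability `p(j|k)` and averages `r(A union {i}) - r(A)`, scaled by
#' `1/p(i)`. For a hard assignment the sampling distribution is degenerate
#' and the estimate is exact for any `K`.
#'
#' @inheritParams delta_d_exact
#' @param K number of Monte-Carlo samples.
#' @return list with `estimate`, `se` (standard error), and `K`.
#' @export
delta_d_monte_carlo <- function(a, i, j, r_fn, K = 1e4) {
  stopifnot(inherits(a, "assignment"), K >= 1)
  if (a$p_i[i] <= 0) stop("p(i) must be positive")
  n <- a$n
  others <- setdiff(seq_len(n), i)
  p <- a$p_j_given_i[others, j]
  draws <- matrix(stats::runif(K * length(others)) < rep(p, each = K),
                  nrow = K)
  # evaluate r once per distinct sampled subset (exact numeric bitmask keys
  # up to 53 others; string keys beyond)
  keys <- if (length(others) <= 53) {
    as.vector(draws %*% 2^(seq_along(others) - 1))
  } else {
    apply(draws, 1, function(b) paste(which(b), collapse = ","))
  }
  uk <- unique(keys)
  first_row <- match(uk, keys)
  vals_u <- vapply(seq_along(uk), function(u) {
    A <- others[draws[first_row[u], ]]
    (r_fn(sort(c(A, i))) - r_fn(A)) / a$p_i[i]
  }, numeric(1))
  vals <- vals_u[match(keys, uk)]
  est <- mean(vals)
  se <- if (K > 1) stats::sd(vals) / sqrt(K) else 0
  list(estimate = est, se = se, K = K)
}

#' Achieved rate of an assignment
#'
#' The mutual information `I(S; S_hat)` between element identity and
#' component label, in bits: how much of the original element identity the
#' compressed description keeps.
#'
#' @param a an [assignment()].
#' @return nonnegative scalar, bits.
#' @export
achieved_rate <- function(a) {
  stopifnot(inherits(a, "assignment"))
  p <- a$p_j_given_i
  pj <- a$p_j
  terms <- sweep(p, 2, pj, "/")
  contrib <- a$p_i * p * ifelse(p > 0, log2(pmax(terms, .Machine$double.xmin)), 0)
  contrib[p == 0] <- 0
  max(sum(contrib), 0)
}

#' One cycle of the redundancy-partitioning update
#'
#' Applies the alternating-minimization update: recompute `delta_d(i, j)` for
#' all element/component pairs under the current assignment, set
#' `p(j|i) proportional to p(j) exp(beta * delta_d(i, j))` (stabilized by
#' subtracting the row maximum of `beta * delta_d` before exponentiation),
#' then refresh the component marginals `p(j)`. At `beta = 0` the update
#' decouples from the data and every row equals the marginal `p(j)`; as
#' `beta -> infinity` each row approaches a one-hot vector at
#' `argmax_j delta_d(i, j)`.
#'
#' @param a an [assignment()].
#' @param r_fn subset-redundancy function.
#' @param estimator `"exact"` (power-set enumeration) or `"mc"`.
#' @param K Monte-Carlo sample count when `estimator = "mc"`.
#' @param all_r optional precomputed subset-redundancy table.
#' @return updated [assignment()].
#' @export
iterate_assignment <- function(a, r_fn, estimator = c("exact", "mc"),
                               K = 1e4, all_r = NULL) {
  stopifnot(inherits(a, "assignment"))
  estimator <- match.arg(estimator)
  if (estimator == "exact") all_r <- resolve_all_r(a, r_fn, all_r)
  dd <- matrix(0, a$n, a$m)
  for (i in seq_len(a$n)) {
    for (j in seq_len(a$m)) {
      dd[i, j] <- if (estimator == "exact") {
        delta_d_exact(a, i, j, r_fn, all_r = all_r)
      } else {
        delta_d_monte_carlo(a, i, j, r_fn, K = K)$estimate
      }
    }
  }
  z <- a$beta * dd
  z <- z - apply(z, 1, max)
  w <- sweep(exp(z), 2, a$p_j, "*")
  rs <- rowSums(w)
  if (any(!is.finite(rs)) || any(rs <= 0)) {
    stop("overflow or degenerate row in assignment update despite stabilization")
  }
  p_new <- w / rs
  assignment(p_new, p_i = a$p_i, beta = a$beta)
}
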