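# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's internal bitmask/enumeration code paths.

# total correlation in bits by direct -p log p bookkeeping over the flat table
oracle_total_correlation <- function(p) {
  dims <- dim(p)
  n <- length(dims)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  h_joint <- ent(as.vector(p))
  h_marg <- vapply(seq_len(n), function(i) ent(apply(p, i, sum)), numeric(1))
  sum(h_marg) - h_joint
}

# joint table of n identical copies of a variable with marginal probs `probs`
copies_pmf <- function(n, probs) {
  k <- length(probs)
  p <- array(0, dim = rep(k, n))
  idx <- matrix(rep(seq_len(k), each = n), ncol = n, byrow = FALSE)
  for (v in seq_len(k)) p[matrix(rep(v, n), 1)] <- probs[v]
  discrete_pmf(p)
}

# X, Y independent fair coins, Z = XOR(X, Y)
xor_pmf <- function() {
  p <- array(0, dim = c(2, 2, 2))
  for (a in 0:1) for (b in 0:1) p[a + 1, b + 1, bitwXor(a, b) + 1] <- 0.25
  discrete_pmf(p)
}

random_pmf <- function(n, k = 2) {
  p <- array(stats::rexp(k^n), dim = rep(k, n))
  discrete_pmf(p / sum(p))
}

# all subsets of 1..n as a list (expand.grid enumeration, not bitmasks)
all_subsets <- function(n) {
  grid <- do.call(expand.grid, rep(list(c(FALSE, TRUE)), n))
  lapply(seq_len(nrow(grid)), function(r) which(unlist(grid[r, ])))
}

# E[r(A)|j] for an inclusion-probability vector, by direct power-set sum
oracle_expected_redundancy <- function(pvec, r_fn) {
  n <- length(pvec)
  total <- 0
  for (A in all_subsets(n)) {
    w <- prod(pvec[A]) * prod(1 - pvec[setdiff(seq_len(n), A)])
    rA <- if (length(A) <= 1) 0 else r_fn(A)
    total <- total + rA * w
  }
  total
}

# delta_d via central finite differences of the expectation oracle
oracle_delta_d_fd <- function(a, i, j, r_fn, h = 1e-6) {
  pvec <- a$p_j_given_i[, j]
  up <- replace(pvec, i, pvec[i] + h)
  dn <- replace(pvec, i, pvec[i] - h)
  d <- (oracle_expected_redundancy(up, r_fn) -
        oracle_expected_redundancy(dn, r_fn)) / (2 * h)
  d / a$p_i[i]
}

random_soft_assignment <- function(n, m, beta = 200) {
  g <- matrix(stats::rexp(n * m), n, m)
  assignment(g / rowSums(g), beta = beta)
}

# random positive-definite correlation matrix via sample correlations
random_correlation <- function(D, T = 60) {
  stats::cor(matrix(stats::rnorm(T * D), T, D) +
               0.5 * matrix(stats::rnorm(T), T, D))
}

# block-structured correlation: groups of equally correlated scalar elements
block_correlation <- function(sizes, rho = 0.6) {
  D <- sum(sizes)
  P <- diag(D)
  start <- cumsum(c(1, sizes))
  for (g in seq_along(sizes)) {
    idx <- start[g]:(start[g] + sizes[g] - 1)
    P[idx, idx] <- rho
    diag(P)[idx] <- 1
  }
  P
}

# best hard partition by exhaustive enumeration of all label assignments
oracle_best_partition <- function(r_fn, n, m) {
  best <- -Inf
  best_labels <- NULL
  labs <- rep(1L, n)
  repeat {
    groups <- split(seq_len(n), labs)
    obj <- sum(vapply(groups, function(A) {
      if (length(A) <= 1) 0 else r_fn(A)
    }, numeric(1))) / m
    if (obj > best + 1e-15) {
      best <- obj
      best_labels <- labs
    }
    pos <- n
    while (pos >= 1) {
      if (labs[pos] < m) { labs[pos] <- labs[pos] + 1L; break }
      labs[pos] <- 1L
      pos <- pos - 1
    }
    if (pos == 0) break
  }
  list(objective = best, labels = best_labels)
}

# jointly Gaussian sampler from a covariance via its Cholesky factor
rmvn <- function(T, Sigma) {
  L <- chol(Sigma)
  matrix(stats::rnorm(T * ncol(Sigma)), T) %*% L
}
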