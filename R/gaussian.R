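#' Gaussian lower-bound model for system redundancy
#'
#' Estimates everything needed to evaluate the Gaussian lower bound on the
#' relative redundancy of any subset of elements: the system-wide correlation
#' matrix `P_S`, the within-element correlation blocks `P_i`, the marginal
#' differential entropies
#' `h_i = (1/2) log((2*pi*e)^{k_i} det(K_i))` (nats), and a fixed
#' quantization offset `alpha` (nats per variate) that converts differential
#' entropies to approximate discrete entropies and keeps the denominator
#' positive. Cross-system comparisons are only meaningful at a common
#' `alpha`, so it is a required, recorded parameter.
#'
#' The caller is expected to pass rank-Gaussianized observations (see
#' [rank_gaussianize()]); a warning is raised otherwise unless
#' `gaussianized = TRUE` asserts the columns are already marginally Gaussian.
#'
#' @param obs an [observation_matrix()].
#' @param alpha quantization offset in nats per variate; default 4 bits.
#' @param gaussianized set `TRUE` to suppress the rank-transform check.
#' @return object of class `gaussian_model` with fields `P` (D x D
#'   correlation matrix), `element_map`, `block_logdet` (log det `P_i` per
#'   element), `h` (per-element differential entropies, nats), `alpha`,
#'   `k` (variates per element), `n`, `T`.
#' @export
estimate_gaussian_model <- function(obs, alpha = bits_to_nats(4),
                                    gaussianized = FALSE) {
  stopifnot(inherits(obs, "observation_matrix"))
  if (obs$T < 3) stop("need at least T = 3 samples to estimate correlations")
  if (!isTRUE(attr(obs, "rank_gaussianized")) && !gaussianized) {
    warning("observations do not appear to be rank-Gaussianized; ",
            "pass gaussianized = TRUE if the columns are already Gaussian")
  }
  if (obs$T <= obs$D) {
    warning("T <= D: the sample correlation matrix is singular; ",
            "results rely on regularization")
  }
  P <- stats::cor(obs$values)
  P <- regularize_correlation(P)
  k <- vapply(obs$element_map, length, integer(1))
  block_logdet <- vapply(obs$element_map, function(cols) {
    logdet_psd(P[cols, cols, drop = FALSE])
  }, numeric(1))
  h <- 0.5 * (k * log(2 * pi * exp(1)) + block_logdet)
  denom <- sum(h + k * alpha)
  if (denom <= 0) {
    stop("non-positive redundancy denominator; increase alpha (per-variate ",
         "quantization offset, nats)")
  }
  structure(
    list(P = P, element_map = obs$element_map, block_logdet = block_logdet,
         h = h, alpha = alpha, k = k, n = obs$n, T = obs$T),
    class = "gaussian_model"
  )
}

#' @export
print.gaussian_model <- function(x, ...) {
  cat("Gaussian redundancy model:", x$n, "elements,",
      sum(x$k), "variates, alpha =", format(nats_to_bits(x$alpha)),
      "bits/variate\n")
  cat("System redundancy (lower bound):",
      format(gaussian_relative_redundancy(x, seq_len(x$n))), "\n")
  invisible(x)
}

# log det of a symmetric positive (semi)definite matrix via Cholesky,
# with documented shrinkage escalation for numerically singular inputs.
logdet_psd <- function(M) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  eps <- 1e-8
  while (is.null(ch) && eps <= 1e-4) {
    warning(sprintf("singular correlation submatrix: shrinking toward the identity (eps = %g)", eps))
    Mi <- (1 - eps) * M + eps * diag(nrow(M))
    ch <- tryCatch(chol(Mi), error = function(e) NULL)
    eps <- eps * 10
  }
  if (is.null(ch)) stop("correlation submatrix singular even after shrinkage")
  2 * sum(log(diag(ch)))
}

# shrink a full correlation matrix until positive definite
regularize_correlation <- function(P, eps0 = 1e-8, eps_max = 1e-4) {
  P <- (P + t(P)) / 2
  if (!is.null(tryCatch(chol(P), error = function(e) NULL))) return(P)
  eps <- eps0
  while (eps <= eps_max) {
    warning(sprintf("correlation matrix numerically singular: applying shrinkage eps = %g", eps))
    Pi <- (1 - eps) * P + eps * diag(nrow(P))
    if (!is.null(tryCatch(chol(Pi), error = function(e) NULL))) return(Pi)
    eps <- eps * 10
  }
  stop("correlation matrix singular even after shrinkage to eps = 1e-4")
}

#' Construct a Gaussian model directly from a correlation matrix
#'
#' Mainly for tests and synthetic examples where the correlation structure is
#' known exactly rather than estimated from samples.
#'
#' @param P correlation matrix (unit diagonal).
#' @param element_map as in [observation_matrix()]; defaults to scalar
#'   elements.
#' @param alpha quantization offset, nats per variate.
#' @return a `gaussian_model`.
#' @export
gaussian_model_from_correlation <- function(P, element_map = NULL,
                                            alpha = bits_to_nats(4)) {
  P <- as.matrix(P)
  if (any(abs(diag(P) - 1) > 1e-10)) stop("P must have a unit diagonal")
  if (max(abs(P - t(P))) > 1e-10) stop("P must be symmetric")
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("P must be positive semidefinite")
  D <- ncol(P)
  if (is.null(element_map)) element_map <- as.list(seq_len(D))
  element_map <- lapply(element_map, as.integer)
  if (!setequal(unlist(element_map), seq_len(D))) {
    stop("element_map must cover all columns exactly once")
  }
  P <- regularize_correlation(P)
  k <- vapply(element_map, length, integer(1))
  block_logdet <- vapply(element_map, function(cols) {
    logdet_psd(P[cols, cols, drop = FALSE])
  }, numeric(1))
  h <- 0.5 * (k * log(2 * pi * exp(1)) + block_logdet)
  if (sum(h + k * alpha) <= 0) stop("non-positive denominator; increase alpha")
  structure(
    list(P = P, element_map = element_map, block_logdet = block_logdet,
         h = h, alpha = alpha, k = k, n = length(element_map), T = NA_integer_),
    class = "gaussian_model"
  )
}

#' Gaussian total correlation of a subset of elements
#'
#' For a subset `A` of elements, returns
#' `-1/2 [log det(P_A) - sum_{i in A} log det(P_i)]` in nats: the Gaussian
#' mutual information among the elements of `A`, with within-element
#' dependence discounted so that any singleton subset scores exactly zero.
#' With `within_element = TRUE` the within-element block terms are kept
#' (the literal variate-level total correlation `-1/2 log det(P_A)`).
#'
#' @param model a `gaussian_model`.
#' @param subset integer vector of element indices (nonempty).
#' @param within_element count within-element dependence too (default FALSE).
#' @return nonnegative scalar, nats.
#' @export
gaussian_total_correlation <- function(model, subset,
                                       within_element = FALSE) {
  stopifnot(inherits(model, "gaussian_model"))
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) == 0) stop("subset must be nonempty")
  if (any(subset < 1 | subset > model$n)) stop("subset indices out of range")
  cols <- unlist(model$element_map[subset])
  ld <- logdet_psd(model$P[cols, cols, drop = FALSE])
  val <- if (within_element) -0.5 * ld
         else -0.5 * (ld - sum(model$block_logdet[subset]))
  max(val, 0)
}

#' Gaussian lower bound on the relative redundancy of a subset
#'
#' `r(A) >= I_G(A) / sum_{i in A} (h_i + k_i * alpha)`. By definition the
#' redundancy of the empty set and of any singleton is zero.
#'
#' @inheritParams gaussian_total_correlation
#' @return scalar in `[0, 1)`.
#' @export
gaussian_relative_redundancy <- function(model, subset) {
  stopifnot(inherits(model, "gaussian_model"))
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) <= 1) return(0)
  if (any(subset < 1 | subset > model$n)) stop("subset indices out of range")
  denom <- sum(model$h[subset] + model$k[subset] * model$alpha)
  if (denom <= 0) stop("non-positive denominator for subset; increase alpha")
  gaussian_total_correlation(model, subset) / denom
}

#' Subset-redundancy function for a Gaussian model
#'
#' Returns a memoizing function `r(A)` mapping an element-index vector to its
#' Gaussian-bound relative redundancy; the form consumed by the partitioning
#' routines.
#'
#' @param model a `gaussian_model`.
#' @return function of one argument (integer vector of element indices).
#' @export
subset_redundancy_fn <- function(model) {
  cache <- new.env(parent = emptyenv())
  function(subset) {
    subset <- sort(unique(as.integer(subset)))
    if (length(subset) <= 1) return(0)
    key <- paste(subset, collapse = ",")
    val <- cache[[key]]
    if (is.null(val)) {
      val <- gaussian_relative_redundancy(model, subset)
      cache[[key]] <- val
    }
    val
  }
}

#' Serialize / restore a Gaussian model as JSON
#'
#' @param model a `gaussian_model`.
#' @param path JSON file path.
#' @return `write_gaussian_model` returns `path` invisibly;
#'   `read_gaussian_model` returns the model.
#' @export
write_gaussian_model <- function(model, path) {
  stopifnot(inherits(model, "gaussian_model"))
  obj <- list(
    P = as.vector(t(model$P)), D = ncol(model$P),
    element_map = model$element_map, h = model$h, alpha = model$alpha,
    block_logdet = model$block_logdet, n = model$n, T = model$T
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gaussian_model
#' @export
read_gaussian_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  P <- matrix(obj$P, nrow = obj$D, byrow = TRUE)
  em <- obj$element_map
  if (is.matrix(em)) em <- lapply(seq_len(nrow(em)), function(i) em[i, ])
  k <- vapply(em, length, integer(1))
  structure(
    list(P = P, element_map = lapply(em, as.integer),
         block_logdet = obj$block_logdet, h = obj$h, alpha = obj$alpha,
         k = k, n = obj$n, T = obj$T),
    class = "gaussian_model"
  )
}
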