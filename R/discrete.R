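#' Discrete joint probability mass function over system elements
#'
#' Constructs a validated joint PMF for a system of `n` discrete elements,
#' each with a finite alphabet. The joint table is an n-dimensional array
#' whose `i`-th dimension indexes the alphabet of element `i`.
#'
#' @param p numeric array (or vector for `n = 1`) of joint probabilities.
#'   Entries must be nonnegative and sum to 1 within `1e-12`.
#' @return an object of class `discrete_pmf` with fields `p` (the array) and
#'   `alphabet_sizes`.
#' @examples
#' # two independent fair coins
#' pmf <- discrete_pmf(array(0.25, dim = c(2, 2)))
#' total_correlation(pmf)
#' @export
discrete_pmf <- function(p) {
  if (!is.numeric(p)) stop("'p' must be numeric")
  if (is.null(dim(p))) p <- array(p, dim = length(p))
  if (any(!is.finite(p))) stop("probabilities must be finite")
  if (any(p < 0)) stop("probabilities must be nonnegative")
  s <- sum(p)
  if (abs(s - 1) > 1e-12) {
    stop(sprintf("joint probabilities must sum to 1 (got %.15g)", s))
  }
  structure(
    list(p = p, alphabet_sizes = dim(p), n = length(dim(p))),
    class = "discrete_pmf"
  )
}

#' @export
print.discrete_pmf <- function(x, ...) {
  cat("Discrete joint PMF:", x$n, "elements, alphabet sizes",
      paste(x$alphabet_sizes, collapse = " x "), "\n")
  invisible(x)
}

# Shannon entropy in bits of a probability vector (0 log 0 = 0).
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# marginal distribution of element i from the joint array
pmf_marginal <- function(pmf, i) {
  if (pmf$n == 1L) return(as.vector(pmf$p))
  apply(pmf$p, i, sum)
}

#' Total correlation of a discrete system
#'
#' The sum of the marginal entropies minus the joint entropy, in bits: the
#' amount of information made redundant by describing the system jointly
#' rather than element by element. Zero exactly when all elements are
#' independent.
#'
#' @param pmf a [discrete_pmf()].
#' @return nonnegative scalar, bits.
#' @export
total_correlation <- function(pmf) {
  stopifnot(inherits(pmf, "discrete_pmf"))
  h_joint <- shannon_entropy(as.vector(pmf$p))
  h_marg <- vapply(seq_len(pmf$n), function(i) {
    shannon_entropy(pmf_marginal(pmf, i))
  }, numeric(1))
  max(sum(h_marg) - h_joint, 0)
}

#' Relative redundancy of a discrete system
#'
#' Total correlation normalized by the sum of marginal entropies:
#' `r = I / sum_i H(X_i) = 1 - s`, where `s` is the incompressibility (the
#' fraction of the system's information that a joint description cannot
#' remove). `r` lies in `[0, 1 - 1/n]`; it equals `1 - 1/n` for `n`
#' identical copies of any nondegenerate variable and 0 for independent
#' elements.
#'
#' A system whose elements are all constant has `sum H = 0`; its redundancy
#' is defined as zero (with a warning), as such a system is vacuously
#' uncoordinated.
#'
#' @param pmf a [discrete_pmf()].
#' @return list with fields `r` (relative redundancy) and `s = 1 - r`
#'   (incompressibility).
#' @export
relative_redundancy <- function(pmf) {
  stopifnot(inherits(pmf, "discrete_pmf"))
  h_marg <- vapply(seq_len(pmf$n), function(i) {
    shannon_entropy(pmf_marginal(pmf, i))
  }, numeric(1))
  denom <- sum(h_marg)
  if (denom <= 0) {
    warning("all elements are constant (sum of marginal entropies is 0); ",
            "relative redundancy defined as 0")
    return(list(r = 0, s = 1))
  }
  h_joint <- shannon_entropy(as.vector(pmf$p))
  r <- max(1 - h_joint / denom, 0)
  list(r = r, s = 1 - r)
}

#' Convert between bits and nats
#'
#' @param x numeric values.
#' @return converted values.
#' @export
bits_to_nats <- function(x) x * log(2)

#' @rdname bits_to_nats
#' @export
nats_to_bits <- function(x) x / log(2)
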