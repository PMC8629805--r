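test_that("rank-Gaussianization maps ranks to normal quantiles", {
  x <- c(3, 1, 4, 10, 2)
  obs <- observation_matrix(matrix(x, 5, 1))
  g <- rank_gaussianize(obs)
  expect_equal(as.vector(g$values),
               qnorm((rank(x) - 0.5) / 5), tolerance = 1e-12)
  # idempotence up to ties: quantile inputs are returned unchanged
  q <- qnorm((1:9 - 0.5) / 9)
  g2 <- rank_gaussianize(observation_matrix(matrix(q, 9, 1)))
  expect_equal(as.vector(g2$values), q, tolerance = 1e-12)
})

test_that("rank-Gaussianization is invariant to monotone transforms", {
  set.seed(5)
  x <- matrix(rnorm(80), 40, 2)
  g1 <- rank_gaussianize(observation_matrix(x))
  g2 <- rank_gaussianize(observation_matrix(cbind(exp(x[, 1]), x[, 2]^3)))
  expect_equal(g1$values, g2$values, tolerance = 1e-12)
  expect_error(rank_gaussianize(observation_matrix(cbind(x[, 1], 1))),
               "constant column")
})

test_that("estimated marginal entropies match the Gaussian closed forms", {
  set.seed(11)
  obs <- rank_gaussianize(observation_matrix(matrix(rnorm(4000), 1000, 4)))
  model <- estimate_gaussian_model(obs)
  # scalar element, unit variance: h = 0.5 * ln(2*pi*e)
  expect_equal(model$h, rep(0.5 * log(2 * pi * exp(1)), 4), tolerance = 0.02)
  # 2-variate element with near-identity covariance: h ~= ln(2*pi*e)
  obs2 <- rank_gaussianize(observation_matrix(matrix(rnorm(4000), 1000, 4),
                                              element_map_blocks(2, 2)))
  m2 <- estimate_gaussian_model(obs2)
  expect_equal(m2$h, rep(log(2 * pi * exp(1)), 2), tolerance = 0.05)
  expect_error(suppressWarnings(estimate_gaussian_model(
    observation_matrix(matrix(rnorm(4), 2, 2)))), "T = 3")
})

test_that("duplicated columns trigger logged shrinkage, not failure", {
  set.seed(2)
  x <- rnorm(100)
  obs <- observation_matrix(cbind(x, x, rnorm(100)))
  expect_warning(model <- estimate_gaussian_model(rank_gaussianize(obs)),
                 "shrinkage")
  expect_true(all(is.finite(model$h)))
})

test_that("Gaussian total correlation matches the 2x2 closed form", {
  m <- gaussian_model_from_correlation(matrix(c(1, 0.6, 0.6, 1), 2))
  expect_equal(gaussian_total_correlation(m, 1:2), -0.5 * log(1 - 0.36),
               tolerance = 1e-12)
  expect_equal(gaussian_total_correlation(m, 1), 0)
  id <- gaussian_model_from_correlation(diag(4))
  for (A in list(1:2, c(1, 3), 1:4)) {
    expect_equal(gaussian_total_correlation(id, A), 0)
  }
})

test_that("Gaussian redundancy bound matches its assembled closed form", {
  alpha <- bits_to_nats(4)
  m <- gaussian_model_from_correlation(matrix(c(1, 0.6, 0.6, 1), 2),
                                       alpha = alpha)
  num <- -0.5 * log(1 - 0.36)
  den <- 2 * (0.5 * log(2 * pi * exp(1)) + alpha)
  expect_equal(gaussian_relative_redundancy(m, 1:2), num / den,
               tolerance = 1e-12)
  expect_equal(gaussian_relative_redundancy(m, integer(0)), 0)
  expect_equal(gaussian_relative_redundancy(m, 1), 0)
  expect_equal(gaussian_relative_redundancy(
    gaussian_model_from_correlation(diag(3)), 1:3), 0, tolerance = 1e-12)
})

test_that("within-element dependence does not count as coordination", {
  # two 2-variate elements, dependence only inside each element
  P <- diag(4)
  P[1, 2] <- P[2, 1] <- 0.8
  P[3, 4] <- P[4, 3] <- 0.8
  m <- gaussian_model_from_correlation(P, element_map_blocks(2, 2))
  expect_equal(gaussian_total_correlation(m, 1:2), 0, tolerance = 1e-12)
  expect_equal(gaussian_relative_redundancy(m, 1:2), 0, tolerance = 1e-12)
  # the literal variate-level quantity keeps the within-element term
  expect_equal(gaussian_total_correlation(m, 1:2, within_element = TRUE),
               -log(1 - 0.64), tolerance = 1e-12)
})

test_that("redundancy bound is invariant to monotone and scale transforms", {
  set.seed(31)
  x <- rmvn(300, matrix(c(1, 0.5, 0.5, 1), 2))
  r_of <- function(mat) {
    model <- estimate_gaussian_model(rank_gaussianize(observation_matrix(mat)))
    gaussian_relative_redundancy(model, 1:2)
  }
  base <- r_of(x)
  expect_equal(r_of(cbind(exp(x[, 1]), x[, 2])), base, tolerance = 1e-10)
  expect_equal(r_of(1000 * x), base, tolerance = 1e-10)
  expect_gt(base, 0)
})

test_that("Gaussian estimate approaches the closed-form total correlation", {
  rho <- 0.7
  Sigma <- matrix(c(1, rho, rho, 1), 2)
  truth <- -0.5 * log(1 - rho^2)
  set.seed(17)
  est <- replicate(8, {
    model <- estimate_gaussian_model(
      rank_gaussianize(observation_matrix(rmvn(3000, Sigma))))
    gaussian_total_correlation(model, 1:2)
  })
  # converges to the truth from below-or-equal within sampling error
  expect_equal(mean(est), truth, tolerance = 0.03)
  expect_lte(mean(est), truth + 0.02)
})

test_that("model serialization round-trips", {
  set.seed(3)
  obs <- rank_gaussianize(
    observation_matrix(matrix(rnorm(400), 100, 4), element_map_blocks(2, 2)))
  model <- estimate_gaussian_model(obs)
  path <- tempfile(fileext = ".json")
  write_gaussian_model(model, path)
  back <- read_gaussian_model(path)
  expect_equal(back$P, model$P, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$h, model$h, tolerance = 1e-12)
  expect_equal(gaussian_relative_redundancy(back, 1:2),
               gaussian_relative_redundancy(model, 1:2), tolerance = 1e-12)
})
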