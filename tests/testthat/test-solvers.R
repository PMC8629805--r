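test_that("one update cycle has the limiting behaviors of the exponential rule", {
  set.seed(51)
  model <- gaussian_model_from_correlation(block_correlation(c(3, 3), 0.6))
  r_fn <- subset_redundancy_fn(model)

  # beta = 0: every row collapses to the component marginal
  a0 <- random_soft_assignment(6, 2, beta = 0)
  a1 <- iterate_assignment(a0, r_fn)
  for (i in 1:6) {
    expect_equal(a1$p_j_given_i[i, ], a0$p_j, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }

  # large beta: rows concentrate on argmax delta_d
  ab <- assignment(random_soft_assignment(6, 2)$p_j_given_i, beta = 2000)
  dd <- sapply(1:2, function(j) {
    sapply(1:6, function(i) delta_d_exact(ab, i, j, r_fn))
  })
  an <- iterate_assignment(ab, r_fn)
  for (i in 1:6) {
    expect_gt(an$p_j_given_i[i, which.max(dd[i, ])], 0.99)
  }
  expect_equal(rowSums(an$p_j_given_i), rep(1, 6), tolerance = 1e-12)
})

test_that("m = 1 recovers the whole-system redundancy", {
  set.seed(52)
  model <- gaussian_model_from_correlation(random_correlation(5))
  r_fn <- subset_redundancy_fn(model)
  soft <- solve_partition(model, m = 1, restarts = 2, seed = 1)
  hard <- solve_hard(model, m = 1, restarts = 2, seed = 2)
  expect_equal(soft$average_redundancy, r_fn(1:5), tolerance = 1e-9)
  expect_equal(hard$average_redundancy, r_fn(1:5), tolerance = 1e-12)
})

test_that("independent elements yield zero redundancy at m = n", {
  model <- gaussian_model_from_correlation(diag(4))
  fit <- solve_hard(model, m = 4, restarts = 5, seed = 3)
  expect_equal(fit$average_redundancy, 0, tolerance = 1e-12)
})

test_that("near-duplicate pairs are recovered and match exhaustive search", {
  set.seed(53)
  z <- matrix(rnorm(400), 200, 2)
  x <- cbind(z[, 1], z[, 1] + rnorm(200, sd = 0.05),
             z[, 2], z[, 2] + rnorm(200, sd = 0.05))
  model <- estimate_gaussian_model(rank_gaussianize(observation_matrix(x)))
  r_fn <- subset_redundancy_fn(model)
  oracle <- oracle_best_partition(r_fn, 4, 2)

  hard <- solve_hard(model, m = 2, restarts = 20, seed = 4)
  expect_equal(hard$average_redundancy, oracle$objective, tolerance = 1e-10)
  expect_equal(length(unique(hard$hard_labels[1:2])), 1)
  expect_equal(length(unique(hard$hard_labels[3:4])), 1)
  expect_false(hard$hard_labels[1] == hard$hard_labels[3])

  soft <- solve_partition(model, m = 2, beta = 200, restarts = 20, seed = 5)
  expect_equal(soft$average_redundancy, oracle$objective, tolerance = 1e-6)
})

test_that("duplicates share a component when one element is independent", {
  set.seed(54)
  x <- matrix(rnorm(300), 100, 3)
  x[, 2] <- x[, 1] + rnorm(100, sd = 0.05)
  model <- estimate_gaussian_model(rank_gaussianize(observation_matrix(x)))
  r_fn <- subset_redundancy_fn(model)
  fit <- solve_hard(model, m = 2, restarts = 10, seed = 6)
  expect_equal(fit$average_redundancy,
               oracle_best_partition(r_fn, 3, 2)$objective, tolerance = 1e-10)
  expect_equal(fit$hard_labels[1], fit$hard_labels[2])
  expect_false(fit$hard_labels[3] == fit$hard_labels[1])
})

test_that("hard solver matches exhaustive search on random systems", {
  set.seed(55)
  for (n in c(6, 8)) {
    model <- gaussian_model_from_correlation(random_correlation(n))
    r_fn <- subset_redundancy_fn(model)
    for (m in 2:3) {
      fit <- solve_hard(model, m = m, restarts = 40, seed = n * 10 + m)
      oracle <- oracle_best_partition(r_fn, n, m)
      expect_equal(fit$average_redundancy, oracle$objective,
                   tolerance = 1e-10)
    }
  }
})

test_that("hard solver equals the large-beta soft solver on a shared fixture", {
  set.seed(56)
  model <- gaussian_model_from_correlation(block_correlation(c(4, 4), 0.5))
  hard <- solve_hard(model, m = 2, restarts = 20, seed = 7)
  soft <- solve_partition(model, m = 2, beta = 200, restarts = 20, seed = 8)
  expect_equal(soft$average_redundancy, hard$average_redundancy,
               tolerance = 1e-6)
})

test_that("greedy objective trace never decreases", {
  set.seed(57)
  model <- gaussian_model_from_correlation(random_correlation(8))
  fit <- solve_hard(model, m = 3, restarts = 1, seed = 9)
  expect_true(all(diff(fit$objective_trace) >= -1e-12))
})

test_that("average redundancy stabilizes across large beta values", {
  set.seed(58)
  model <- gaussian_model_from_correlation(block_correlation(c(5, 5), 0.9))
  objs <- vapply(c(10, 50, 200, 1000), function(beta) {
    solve_partition(model, m = 2, beta = beta, restarts = 5, max_iter = 200,
                    seed = 60 + beta)$average_redundancy
  }, numeric(1))
  expect_lt((max(objs) - min(objs)) / mean(objs), 0.02)
})

test_that("solutions are equivariant to element relabeling", {
  set.seed(59)
  P <- block_correlation(c(3, 3), 0.6)
  perm <- c(4, 1, 5, 2, 6, 3)
  m1 <- gaussian_model_from_correlation(P)
  m2 <- gaussian_model_from_correlation(P[perm, perm])
  f1 <- solve_hard(m1, m = 2, restarts = 20, seed = 10)
  f2 <- solve_hard(m2, m = 2, restarts = 20, seed = 11)
  expect_equal(f1$average_redundancy, f2$average_redundancy, tolerance = 1e-10)
  # the permuted solution groups exactly the permuted elements
  expect_equal(split(seq_along(perm), f2$hard_labels[order(perm)]),
               split(seq_along(perm), f1$hard_labels), ignore_attr = TRUE)
})

test_that("best average redundancy is non-increasing in m on block fixtures", {
  set.seed(60)
  model <- gaussian_model_from_correlation(block_correlation(c(4, 4), 0.6))
  rbar <- vapply(1:6, function(m) {
    solve_hard(model, m = m, restarts = 20, seed = 100 + m)$average_redundancy
  }, numeric(1))
  expect_true(all(diff(rbar) <= 1e-10))
})

test_that("surplus components are left empty when m exceeds n", {
  model <- gaussian_model_from_correlation(block_correlation(c(2, 2), 0.7))
  fit <- solve_hard(model, m = 6, restarts = 10, seed = 12)
  expect_equal(fit$m, 6)
  expect_true(any(tabulate(fit$hard_labels, 6) == 0))
  expect_true(all(fit$component_redundancy >= 0))
})

test_that("partition results serialize to JSON and CSV", {
  set.seed(61)
  model <- gaussian_model_from_correlation(block_correlation(c(2, 2), 0.7))
  fit <- solve_hard(model, m = 2, restarts = 5, seed = 13)
  jpath <- tempfile(fileext = ".json")
  cpath <- tempfile(fileext = ".csv")
  write_partition(fit, jpath, labels_csv = cpath)
  back <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(back$average_redundancy, fit$average_redundancy,
               tolerance = 1e-12)
  labs <- utils::read.csv(cpath)
  expect_equal(labs$component, fit$hard_labels)
})

test_that("the fitting front-end accepts raw matrices and reports methods", {
  set.seed(62)
  z <- rnorm(150)
  x <- cbind(z, z + rnorm(150, sd = 0.1), rnorm(150))
  fit <- redundancy_partition(x, m = 2, restarts = 10, seed = 14)
  expect_s3_class(fit, "partition_result")
  expect_equal(labels(fit)[1], labels(fit)[2])
  expect_s3_class(attr(fit, "model"), "gaussian_model")
  expect_output(print(fit), "average component redundancy")
  expect_output(summary(fit), "restarts")
})
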