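test_that("identical matrices give zero variance and their common mean", {
  W <- unit_reference()
  d <- estimate_stain_distribution(list(W, W, W, W))
  expect_equal(d$W0, W)
  expect_equal(d$sigma, 0)
  expect_equal(d$n_source, 4L)
})

test_that("two-matrix batch matches a direct hand computation", {
  withr::with_seed(11, {
    W1 <- matrix(runif(6), 3, 2)
    W2 <- matrix(runif(6), 3, 2)
  })
  d <- estimate_stain_distribution(list(W1, W2))
  expect_equal(d$W0, (W1 + W2) / 2)
  # unbiased two-sample variance per entry is (x1 - x2)^2 / 2; the energy
  # identity 6 sigma^2 = sum of per-entry variances follows directly
  expect_equal(6 * d$sigma^2, sum((W1 - W2)^2 / 2), tolerance = 1e-14)
})

test_that("fitted sigma matches the covariance trace exactly", {
  withr::with_seed(5, {
    batch <- replicate(9, matrix(runif(6), 3, 2), simplify = FALSE)
  })
  d <- estimate_stain_distribution(batch)
  M <- vapply(batch, as.vector, numeric(6))
  trace <- sum(diag(stats::cov(t(M))))
  expect_equal(3 * 2 * d$sigma^2, trace, tolerance = 1e-14)
})

test_that("the median mean is robust to a single outlying matrix", {
  W <- unit_reference()
  withr::with_seed(3, {
    batch <- replicate(7, W + matrix(rnorm(6, sd = 0.01), 3, 2),
                       simplify = FALSE)
  })
  base <- estimate_stain_distribution(batch)
  outlier <- W + 5
  with_out <- estimate_stain_distribution(c(batch, list(outlier)))
  expect_lt(max(abs(with_out$W0 - base$W0)), 0.05)   # << outlier displacement 5
  expect_gt(with_out$sigma, base$sigma)
})

test_that("batch-size preconditions are enforced", {
  W <- unit_reference()
  expect_error(estimate_stain_distribution(list(W)), "sigma")
  single <- estimate_stain_distribution(list(W), sigma = 0)
  expect_equal(single$W0, W)
  expect_equal(single$sigma, 0)
  expect_error(estimate_stain_distribution(list()), "non-empty")
  expect_error(estimate_stain_distribution(list(W, matrix(0, 3, 3))), "3 x 2")
})

test_that("sampling is seeded, degenerate at sigma = 0, and clipped at 0", {
  d <- stain_distribution(unit_reference(), sigma = 0.05)
  expect_identical(sample_color_matrix(stain_distribution(d$W0, 0), 99), d$W0)
  s1 <- sample_color_matrix(d, rng_seed = 123)
  s2 <- sample_color_matrix(d, rng_seed = 123)
  expect_identical(s1, s2)
  expect_false(identical(s1, sample_color_matrix(d, rng_seed = 124)))

  near_zero <- stain_distribution(matrix(0.01, 3, 2), sigma = 0.5)
  expect_warning(s <- sample_color_matrix(near_zero, rng_seed = 1), "clipped")
  expect_true(all(s >= 0))
})

test_that("sampled draws reproduce the mean and total energy", {
  d <- stain_distribution(unit_reference(), sigma = 0.05)
  n <- 4000
  draws <- withr::with_seed(77, suppressWarnings({
    vapply(seq_len(n), function(i) as.vector(sample_color_matrix(d)),
           numeric(6))
  }))
  # CLT bound on each entry of the mean
  expect_lt(max(abs(rowMeans(draws) - as.vector(d$W0))),
            4 * d$sigma / sqrt(n))
  trace <- sum(diag(stats::cov(t(draws))))
  expect_equal(trace, 6 * d$sigma^2, tolerance = 0.08)
})

test_that("JSON serialization round trips at full precision", {
  withr::with_seed(21, {
    d <- stain_distribution(matrix(runif(6), 3, 2), sigma = runif(1),
                            n_source = 17L, notes = "fixture")
  })
  path <- withr::local_tempfile(fileext = ".json")
  save_stain_distribution(d, path)
  back <- load_stain_distribution(path)
  expect_identical(back$W0, d$W0)
  expect_identical(back$sigma, d$sigma)
  expect_identical(back$n_source, d$n_source)
})

test_that("malformed distribution files raise format errors", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", p)
  expect_error(load_stain_distribution(p), "malformed")
  jsonlite::write_json(list(m = 2, W0 = diag(3), sigma = 0.1), p,
                       auto_unbox = TRUE)
  expect_error(load_stain_distribution(p), "3 x 2")
  jsonlite::write_json(list(m = 2, W0 = matrix(1, 3, 2)), p, auto_unbox = TRUE)
  expect_error(load_stain_distribution(p), "missing")
})

test_that("the packaged reference distribution carries the published values", {
  d <- cbcs_stain_distribution()
  expect_identical(d$W0, matrix(c(0.544, 0.703, 0.455, 0.141, 0.821, 0.552),
                                nrow = 3))
  expect_identical(d$sigma, 0.053)
  expect_true(all(abs(sqrt(colSums(d$W0^2)) - 1) < 5e-3))
})
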