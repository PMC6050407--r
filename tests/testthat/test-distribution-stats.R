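test_that("ensemble means match closed forms", {
  d <- receptor_distribution(rep(3100, 50), "EC", "VEGFR1")
  ens <- ensemble_concentration(d, seed = 1)
  expect_equal(ens$geometric_mean, 3100)
  expect_equal(ens$arithmetic_mean, 3100)

  d2 <- receptor_distribution(c(100, 10000), "EC", "VEGFR1")
  ens2 <- ensemble_concentration(d2, seed = 1)
  expect_equal(ens2$geometric_mean, 1000)
  expect_equal(ens2$arithmetic_mean, 5050)
})

test_that("ensemble bootstrap is seeded and sane", {
  v <- withr::with_seed(3, 10^rnorm(500, 3.5, 0.3))
  d <- receptor_distribution(v, "EC", "VEGFR1")
  a <- ensemble_concentration(d, seed = 42)
  b <- ensemble_concentration(d, seed = 42)
  expect_identical(a$ci, b$ci)
  expect_lt(a$ci[1], a$geometric_mean)
  expect_gt(a$ci[2], a$geometric_mean)
  # zeros excluded from the geometric mean but tallied
  dz <- receptor_distribution(c(v, 0, 0), "EC", "VEGFR1")
  ez <- ensemble_concentration(dz, seed = 1)
  expect_equal(ez$n_excluded, 2L)
  expect_equal(ez$geometric_mean, a$geometric_mean)
  expect_error(
    ensemble_concentration(receptor_distribution(c(0, 0), "EC", "M")),
    "degenerate")
})

test_that("binning spans log10 range with equal spacing", {
  b <- bin_distribution(c(10, 10^1.7, 999.9999, 1000), bins = 2L)
  expect_equal(b$edges, c(1, 2, 3))
  expect_equal(b$centers, c(1.5, 2.5))
  # the maximum lands in the last bin, counted once
  expect_equal(b$p, c(0.5, 0.5))
  expect_error(bin_distribution(rep(100, 5), bins = 10), "single support")
  expect_error(bin_distribution(c(0, 0), bins = 10), "no positive")
  expect_error(bin_distribution(c(1, 10), bins = 1), ">= 2")
})

test_that("bin masses always sum to one", {
  withr::with_seed(9, {
    for (i in 1:10) {
      v <- 10^rnorm(sample(10:2000, 1), runif(1, 2, 5), runif(1, 0.1, 1))
      b <- bin_distribution(v, bins = sample(2:500, 1))
      expect_lt(abs(sum(b$p) - 1), 1e-12)
      expect_true(all(b$p >= 0))
      expect_true(all(diff(b$edges) > 0))
      expect_equal(diff(range(diff(b$edges))), 0, tolerance = 1e-9)
    }
  })
})

test_that("quadratic entropy matches analytic cases", {
  one <- quadratic_entropy(list(centers = c(1, 2, 3), p = c(0, 1, 0)))
  expect_identical(one$qe, 0)
  expect_equal(one$heterogeneity_class, "low")
  two <- quadratic_entropy(list(centers = c(2, 3), p = c(0.5, 0.5)))
  expect_identical(two$qe, 0.5)
})

test_that("fast quadratic entropy equals the brute-force double sum", {
  withr::with_seed(31, {
    for (i in 1:20) {
      B <- sample(2:500, 1)
      p <- runif(B); p <- p / sum(p)
      centers <- sort(runif(B, 0, 6))
      qe <- quadratic_entropy(list(centers = centers, p = p))$qe
      expect_lt(abs(qe - qe_brute_force(centers, p)), 1e-12)
    }
  })
})

test_that("quadratic entropy is invariant to bin permutation and padding", {
  withr::with_seed(8, {
    p <- runif(10); p <- p / sum(p)
    centers <- runif(10, 0, 4)
    qe0 <- quadratic_entropy(list(centers = centers, p = p))$qe
    perm <- sample.int(10)
    qe_perm <- quadratic_entropy(list(centers = centers[perm], p = p[perm]))$qe
    expect_equal(qe_perm, qe0, tolerance = 1e-12)
    qe_pad <- quadratic_entropy(list(centers = c(centers, 9, 12),
                                     p = c(p, 0, 0)))$qe
    expect_equal(qe_pad, qe0, tolerance = 1e-12)
    # linear scaling of the center grid scales QE linearly
    qe_scaled <- quadratic_entropy(list(centers = 2.5 * centers, p = p))$qe
    expect_equal(qe_scaled, 2.5 * qe0, tolerance = 1e-12)
  })
})

test_that("extreme 0.5/0.5 split maximizes QE on a fixed 3-bin grid", {
  centers <- c(0, 1, 2)
  grid <- seq(0, 1, by = 0.05)
  best <- -Inf; best_p <- NULL
  for (p1 in grid) for (p2 in grid[grid <= 1 - p1 + 1e-12]) {
    p <- c(p1, p2, 1 - p1 - p2)
    qe <- qe_brute_force(centers, p)
    if (qe > best + 1e-12) { best <- qe; best_p <- p }
  }
  expect_equal(best_p, c(0.5, 0, 0.5))
  expect_equal(quadratic_entropy(list(centers = centers, p = best_p))$qe,
               best, tolerance = 1e-12)
})

test_that("QE grows with the log-separation of a two-point mixture", {
  seps <- c(0.2, 0.5, 1, 1.5, 2)
  qes <- vapply(seps, function(s)
    quadratic_entropy(list(centers = c(3, 3 + s), p = c(0.5, 0.5)))$qe,
    numeric(1))
  expect_true(all(diff(qes) > 0))
})

test_that("healthy-like single log-normal samples fall in the low band", {
  withr::with_seed(12, {
    for (s in c(0.2, 0.25, 0.3)) {
      v <- 10^rnorm(5000, 3.7, s)
      qe <- receptor_qe(v, bins = 500)
      expect_gt(qe$qe, 0.15)
      expect_lt(qe$qe, 0.7)
      expect_equal(qe$heterogeneity_class, "low")
    }
  })
  # degenerate support: QE defined as zero
  expect_equal(receptor_qe(rep(2000, 20))$qe, 0)
})
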