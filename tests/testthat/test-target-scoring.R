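# build a score from raw receptor values, fitting k components
score_from_values <- function(values, k = 1, population = "EC",
                              marker = "VEGFR2", reference_gm = NULL,
                              criteria = target_criteria()) {
  d <- receptor_distribution(values, population, marker)
  qe <- receptor_qe(values, bins = 100)
  fit <- fit_k(values, k, seed = 1)
  score_target(d, qe, fit, reference_gm = reference_gm, criteria = criteria)
}

test_that("a high-availability, low-QE, tumor-specific marker is primary", {
  # 73% of cells at ~8,000 receptors/cell, the rest at ~3,000: low entropy,
  # 5-fold over the healthy reference
  v <- withr::with_seed(1, rlnorm10_mix(10000, c(0.73, 0.27),
                                        c(log10(8000), log10(3000)),
                                        c(0.05, 0.05)))
  s <- score_from_values(v, k = 2, reference_gm = 10^mean(log10(v)) / 5)
  expect_gt(s$availability, 0.70)
  expect_lt(s$qe, 0.7)
  expect_equal(s$specificity, "scored")
  expect_equal(s$specificity_fold, 5, tolerance = 1e-6)
  expect_true(s$primary_target)
  expect_false(s$combination_candidate)
})

test_that("zero-receptor cells are never a target", {
  d <- receptor_distribution(rep(0, 100), "GSC", "EGFR")
  qe <- receptor_qe(d$values)
  fit <- qflowkit:::new_mixture_fit(1L, 1, 3, 0.3, 0, 100L, 100L, 0L)
  s <- score_target(d, qe, fit)
  expect_equal(s$availability, 0)
  expect_false(s$primary_target)
  expect_false(s$combination_candidate)
})

test_that("low-concentration markers fail availability regardless of QE", {
  v <- withr::with_seed(2, 10^rnorm(5000, log10(3000), 0.1))
  s <- score_from_values(v, k = 1)
  expect_lt(s$qe, 0.7)
  expect_lt(s$availability, 0.05)
  expect_false(s$primary_target)
})

test_that("missing healthy reference skips specificity rather than failing", {
  v <- withr::with_seed(3, 10^rnorm(5000, log10(10000), 0.15))
  s_noref <- score_from_values(v, k = 1)
  expect_equal(s_noref$specificity, "unscored")
  expect_true(is.na(s_noref$specificity_fold))
  expect_true(s_noref$primary_target)
  # with a reference and insufficient fold, specificity blocks the flag
  s_lowfold <- score_from_values(v, k = 1,
                                 reference_gm = 10^mean(log10(v)))
  expect_false(s_lowfold$primary_target)
})

test_that("minority high-concentration components flag combination therapy", {
  # ~9% of cells carry ~12x the ensemble concentration
  v <- withr::with_seed(4, rlnorm10_mix(10000, c(0.91, 0.09),
                                        c(3.45, 4.65), c(0.2, 0.15)))
  s <- score_from_values(v, k = 2, marker = "VEGFR1")
  expect_true(s$combination_candidate)
  # a majority component at high concentration does not
  v2 <- withr::with_seed(5, rlnorm10_mix(10000, c(0.5, 0.5),
                                         c(3.45, 4.65), c(0.2, 0.15)))
  s2 <- score_from_values(v2, k = 2, marker = "VEGFR1")
  expect_false(s2$combination_candidate)
})

test_that("availability is monotone in receptor counts", {
  withr::with_seed(6, {
    v <- 10^rnorm(2000, 3.7, 0.3)
    s1 <- score_from_values(v)
    s2 <- score_from_values(v * 2)
    expect_gte(s2$availability, s1$availability)
  })
})

test_that("scoring is deterministic", {
  v <- withr::with_seed(7, 10^rnorm(1000, 3.9, 0.2))
  s1 <- score_from_values(v, k = 1)
  s2 <- score_from_values(v, k = 1)
  expect_identical(unclass(s1), unclass(s2))
})

test_that("ranking orders primaries, candidates, rest - stably", {
  mk <- function(pop, avail, primary, combo) {
    structure(list(population = pop, marker = "M", availability = avail,
                   qe = 0.3, k = 1L, specificity_fold = NA_real_,
                   specificity = "unscored", primary_target = primary,
                   combination_candidate = combo, ensemble_gm = 1e4),
              class = "target_score")
  }
  scores <- list(mk("d", 0.2, FALSE, FALSE), mk("a", 0.75, TRUE, FALSE),
                 mk("c", 0.5, FALSE, TRUE), mk("b", 0.9, TRUE, FALSE))
  r <- rank_targets(scores)
  expect_equal(r$population, c("b", "a", "c", "d"))
  expect_equal(r$rank, 1:4)
  # permuted input gives the identical ranking
  r2 <- rank_targets(scores[c(3, 1, 4, 2)])
  expect_equal(r2, r)
  expect_error(rank_targets(list()), "no target scores")
})

test_that("criteria thresholds are validated", {
  expect_error(target_criteria(availability_fraction_min = 0), "positive|0, 1")
  expect_error(target_criteria(minority_weight_max = 1.5), "0, 1")
  expect_error(target_criteria(qe_max = -0.1), "positive")
})
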