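test_that("generation is deterministic in the seed", {
  truth <- two_pop_truth(noise_cv = 0.2)
  a <- generate_cells(truth, 500, seed = 3)
  b <- generate_cells(truth, 500, seed = 3)
  expect_identical(a$events$intensities, b$events$intensities)
  expect_identical(a$labels, b$labels)
  expect_identical(a$receptors, b$receptors)
  c <- generate_cells(truth, 500, seed = 4)
  expect_false(identical(a$events$intensities, c$events$intensities))

  ba <- generate_beads(truth, c(1e3, 1e4), 100, seed = 5)
  bb <- generate_beads(truth, c(1e3, 1e4), 100, seed = 5)
  expect_identical(ba$intensities, bb$intensities)
})

test_that("single-component truth is recovered by sample moments", {
  truth <- one_pop_truth(mu = 3, sigma = 0.2, noise_cv = 0)
  sim <- generate_cells(truth, 10000, seed = 1)
  lg <- log10(sim$receptors[, "VEGFR1"])
  expect_lt(abs(mean(lg) - 3), 0.01)
  expect_lt(abs(sd(lg) - 0.2), 3 * 0.2 / sqrt(2 * 10000))
  # identity calibration, zero noise: intensity equals true receptors
  expect_equal(sim$events$intensities[, "VEGFR1"], sim$receptors[, "VEGFR1"],
               tolerance = 1e-12)
  expect_true(all(sim$receptors > 0))
})

test_that("population fractions follow binomial sampling", {
  truth <- two_pop_truth(frac_b = 0.1)
  sim <- generate_cells(truth, 10000, seed = 7)
  counts <- table(sim$labels)
  expect_lt(abs(counts[["A"]] - 9000), 100)  # +/- 1% of n
  expect_lt(abs(counts[["B"]] - 1000), 100)
})

test_that("bead peaks sit on the truth curve with the stated noise", {
  truth0 <- one_pop_truth(noise_cv = 0, slope = 0.95, intercept = 0.3)
  beads <- generate_beads(truth0, c(1e3, 1e4, 1e5), 50, seed = 1)
  med <- vapply(beads$intensities, median, numeric(1))
  expect_equal(med, 10^(0.3 + 0.95 * log10(c(1e3, 1e4, 1e5))),
               tolerance = 1e-12)

  # identity curve, zero noise: medians equal the peak values exactly
  beads_id <- generate_beads(one_pop_truth(noise_cv = 0),
                             c(1e3, 1e4, 1e5), 50, seed = 1)
  expect_equal(vapply(beads_id$intensities, median, numeric(1)),
               c(1e3, 1e4, 1e5))

  truth1 <- one_pop_truth(noise_cv = 0.1)
  beads1 <- generate_beads(truth1, c(1e3, 1e4, 1e5), 500, seed = 2)
  gcv <- vapply(beads1$intensities, function(v)
    sqrt(exp(sd(log(v))^2) - 1), numeric(1))
  expect_true(all(gcv > 0.08 & gcv < 0.12))

  expect_error(generate_beads(truth1, 1e3, 10, seed = 1), "at least 2")
  expect_error(generate_beads(truth1, c(1e4, 1e3), 10, seed = 1),
               "increasing")
})

test_that("invalid generator inputs are rejected", {
  mm <- list(VEGFR1 = data.frame(weight = 1, mu_log10 = 3, sigma_log10 = 0.2))
  neg <- setNames(rep("negative", length(GATING_CHANNELS)), GATING_CHANNELS)
  expect_error(synthetic_truth(list(
    population_spec("A", 0.5, mm, neg),
    population_spec("B", 0.4, mm, neg))), "sum to 1")
  expect_error(population_spec("A", 1, list(
    VEGFR1 = data.frame(weight = c(0.5, 0.4), mu_log10 = c(3, 4),
                        sigma_log10 = c(0.2, 0.2))), neg), "sum to 1")
  expect_error(generate_cells(two_pop_truth(), 0, seed = 1), "n must be")
})

test_that("the GBM39-like scenario encodes its stated composition", {
  truth <- paperlike_scenario()
  fr <- vapply(truth$populations, function(p) p$fraction, numeric(1))
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  # printed fractions, normalized by their 0.9976 total
  expect_equal(unname(fr["other"]), 0.6246 / 0.9976, tolerance = 1e-12)
  expect_equal(unname(fr["human_EC"]), 0.0520 / 0.9976, tolerance = 1e-12)
  expect_equal(unname(fr["GSC"]), 0.0090 / 0.9976, tolerance = 1e-12)
  # mouse:human EC-like ratio is exactly 6:1
  expect_equal(unname(fr["mouse_EC"] / fr["human_EC"]), 6, tolerance = 1e-12)
})

test_that("the GBM39-like scenario encodes the minority subpopulations", {
  truth <- paperlike_scenario()
  hEC <- truth$populations$human_EC$marker_models

  egfr <- hEC$EGFR
  expect_equal(egfr$weight[2], 0.08)
  gm_log <- sum(egfr$weight * egfr$mu_log10)
  expect_equal(gm_log, log10(21000), tolerance = 1e-5)
  expect_equal(10^egfr$mu_log10[2] / 10^gm_log, 12, tolerance = 1e-3)

  v1 <- hEC$VEGFR1
  expect_equal(v1$weight[2], 0.10)
  expect_equal(10^v1$mu_log10[2], 41000, tolerance = 1e-4)
  expect_equal(10^sum(v1$weight * v1$mu_log10), 3600, tolerance = 1e-4)

  tie2 <- hEC$TIE2
  expect_equal(tie2$weight[2], 0.08)
  expect_equal(10^tie2$mu_log10[2], 65700, tolerance = 1e-4)

  v2 <- hEC$VEGFR2
  expect_equal(v2$weight[2], 0.35)
  expect_equal(10^v2$mu_log10[2], 18500, tolerance = 1e-4)
  expect_equal(10^sum(v2$weight * v2$mu_log10), 5800, tolerance = 1e-4)

  # every population models the full nine-receptor panel
  for (p in truth$populations) {
    expect_setequal(names(p$marker_models), RTK_PANEL)
  }
})

test_that("generated per-component log10 moments match the generator truth", {
  truth <- paperlike_scenario(noise_cv = 0)
  sim <- generate_cells(truth, 10000, seed = 21)
  v1 <- log10(sim$receptors[sim$labels == "mouse_EC", "VEGFR1"])
  expect_lt(abs(mean(v1) - 3.491362), 4 * 0.3 / sqrt(length(v1)))
  expect_lt(abs(sd(v1) - 0.3), 4 * 0.3 / sqrt(2 * length(v1)))
})
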