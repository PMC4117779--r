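test_that("primer efficiency recovers E from dilution-series slopes", {
  d <- 0:-3
  perfect <- primer_efficiency(d, 20 - 3.321928 * d)
  expect_equal(perfect$efficiency, 2, tolerance = 1e-6)
  expect_equal(perfect$r_squared, 1)

  e35 <- primer_efficiency(d, 20 - 3.5 * d)
  expect_equal(e35$efficiency, 10^(1 / 3.5), tolerance = 1e-9)

  expect_error(primer_efficiency(c(0, -1), c(20, 23.3)), "at least 3")
  expect_error(primer_efficiency(d, 20 + 3.3 * d), "slope")
  expect_warning(primer_efficiency(c(0, -0.5, -1), c(20, 21.6, 23.3)), "2 logs")
})

test_that("relative quantity follows efficiency-corrected Cq differences", {
  # identical Cq values in two samples give a quantity ratio of 1
  expect_equal(relative_quantity(25, 20) / relative_quantity(25, 20), 1)
  # one cycle earlier at E = 2 doubles the quantity
  expect_equal(relative_quantity(24, 20) / relative_quantity(25, 20), 2)
  # E = 1.93, delta Cq = -2
  expect_equal(relative_quantity(23, 20, 1.93, 2) /
                 relative_quantity(25, 20, 1.93, 2), 1.93^2)
  expect_error(relative_quantity(25, 20, eff_target = 2.5), "2.2")
})

test_that("spike ratio is the spiked/unspiked quantity ratio minus one", {
  expect_equal(spike_ratio(2, 1), 1)
  expect_equal(spike_ratio(1, 1), 0)
  expect_error(spike_ratio(2, 0), "positive")
  # noiseless titration at multiples k of the endogenous amount gives R = k
  endo <- 1300
  for (k in c(0.25, 0.5, 1, 2, 4)) {
    expect_equal(spike_ratio(endo + k * endo, endo), k)
  }
})

test_that("titration fit inverts the slope to endogenous copies", {
  s <- c(325, 650, 1300, 2600, 5200)
  fit <- fit_titration(s, s / 1300, cells_per_reaction = 1)
  expect_equal(fit$endogenous_per_reaction, 1300, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)

  # duplicated standard amounts act as weighted points: the slope equals the
  # through-origin normal equation sum(S R) / sum(S^2)
  s2 <- c(325, 325, 1300, 2600, 2600)
  r2 <- s2 / 1300 * c(1.1, 0.9, 1, 1.05, 0.95)
  fit2 <- fit_titration(s2, r2, cells_per_reaction = 1)
  expect_equal(fit2$slope_per_molecule, sum(s2 * r2) / sum(s2^2), tolerance = 1e-12)

  expect_error(fit_titration(c(0, 0, 0), c(0, 0, 0), 1), "distinct|zero")
  expect_error(fit_titration(s, -s / 1300, 1), "non-positive")
  expect_warning(fit_titration(s[1:3], s[1:3] / 1e5, 1), "crossing")
})

test_that("estimate is invariant to a common rescaling of relative quantities", {
  rq_u <- c(1.0, 1.1, 0.9, 1.05, 0.95)
  s <- c(400, 800, 1600, 3200, 6400)
  rq_s <- rq_u * (1 + s / 1600)
  base <- fit_titration(s, spike_ratio(rq_s, rq_u), 1)
  scaled <- fit_titration(s, spike_ratio(rq_s * 37.5, rq_u * 37.5), 1)
  expect_equal(scaled$endogenous_per_reaction, base$endogenous_per_reaction)
})

test_that("noiseless simulated titration is recovered exactly, any efficiency", {
  for (eff in c(2, 1.9)) {
    sim <- simulate_qpcr_titration(scenario("hek293t_like"), noise = noiseless(),
                                   seed = 11, efficiency = eff)
    fit <- quantify_spikein(sim$wells, sim$design, target = "hTR",
                            eff_target = eff, eff_reference = eff)
    expect_equal(fit$endogenous_per_cell, 800, tolerance = 1e-6)
  }
})

test_that("replicate Cq summaries flag ranges above half a cycle", {
  wells <- data.frame(sample_id = c("a", "a", "a", "b", "b"),
                      target = "hTR",
                      cq = c(20, 20.1, 20.8, 25, 25.1),
                      replicate = c(1, 2, 3, 1, 2))
  s <- summarize_cq(wells)
  expect_true(s$range_flag[s$sample_id == "a"])
  expect_false(s$range_flag[s$sample_id == "b"])
  expect_error(summarize_cq(transform(wells, cq = cq + 30)), "\\[0, 45\\]")
})

test_that("primer-pair aggregation reports mean and sample SD", {
  agg <- aggregate_primer_pairs(c(650, 790, 830, 1260))
  expect_equal(agg$mean, mean(c(650, 790, 830, 1260)))
  expect_equal(agg$sd, sd(c(650, 790, 830, 1260)))
  expect_equal(aggregate_primer_pairs(c(100, 100, 100))$sd, 0)
  single <- aggregate_primer_pairs(500)
  expect_true(is.na(single$sd) && !single$sd_defined)
})
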