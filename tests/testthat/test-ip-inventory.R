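test_that("mass-balance estimator reproduces the depletion arithmetic", {
  expect_equal(as.numeric(assembled_monomers_per_cell(
    800, depletion_ratios(0.48, 0.84))), 800 * 0.16 / 0.52)
  # limits: no hTR depleted -> 0 assembled; equal ratios -> everything assembled
  expect_equal(as.numeric(assembled_monomers_per_cell(800, 0.5, r_htr = 1)), 0)
  expect_equal(as.numeric(assembled_monomers_per_cell(800, 0.5, r_htr = 0.5)), 800)
  expect_error(assembled_monomers_per_cell(800, 1, r_htr = 0.9), "undefined")
  w <- capture_warnings(
    out <- assembled_monomers_per_cell(800, 0.6, r_htr = 0.4))
  expect_match(w, "fraction > 1")
  expect_true(attr(out, "fraction_gt_1"))
})

test_that("estimator is linear in hTR and monotone in the ratios", {
  base <- as.numeric(assembled_monomers_per_cell(800, 0.48, r_htr = 0.84))
  expect_equal(as.numeric(assembled_monomers_per_cell(1600, 0.48, r_htr = 0.84)),
               2 * base)
  r_htr_grid <- seq(0.5, 0.95, by = 0.05)
  vals <- vapply(r_htr_grid, function(r)
    as.numeric(assembled_monomers_per_cell(800, 0.48, r_htr = r)), numeric(1))
  expect_true(all(diff(vals) < 0))
  r_act_grid <- seq(0.1, 0.7, by = 0.1)
  vals2 <- vapply(r_act_grid, function(r)
    as.numeric(assembled_monomers_per_cell(800, r, r_htr = 0.84)), numeric(1))
  expect_true(all(diff(vals2) > 0))
})

test_that("hTERT per cell follows the elution stoichiometry", {
  expect_rel_equal(tert_per_cell(146, 9.2e6, 15e6), 238, 5e-3)
  expect_rel_equal(tert_per_cell(255, 1.3e6, 3.1e6), 608, 5e-3)
  expect_equal(tert_per_cell(240, 2e6, 2e6), 240)
  expect_error(tert_per_cell(240, 0, 2e6), "positive")
  # joint rescaling of elution concentrations cancels
  expect_equal(tert_per_cell(240, 1.3e6 * 7, 3.1e6 * 7),
               tert_per_cell(240, 1.3e6, 3.1e6))
})

test_that("replicate summaries use the sample SD", {
  s <- replicate_summary(c(146, 245, 332))
  expect_equal(s$mean, 241)
  expect_equal(s$sd, sd(c(146, 245, 332)))
  expect_rel_equal(s$sd, 93, 5e-3)
  single <- replicate_summary(255)
  expect_true(is.na(single$sd) && !single$sd_defined)
  expect_error(replicate_summary(numeric(0)), "empty")
  # two-pass oracle on random sets
  set.seed(7)
  x <- rnorm(25, 100, 20)
  expect_equal(replicate_summary(x)$sd,
               sqrt(sum((x - mean(x))^2) / (length(x) - 1)))
})

test_that("inventories derive free pools with flags, never negative", {
  inv <- build_inventory(1300, 500, 240)
  expect_equal(inv$free_hTR, 1060)
  expect_equal(inv$free_hTERT, 260)
  expect_equal(inv$rnp_dimers_per_cell, 120)
  expect_length(inv$flags, 0)

  inv0 <- build_inventory(1300, 500, 0)
  expect_equal(inv0$free_hTR, 1300)
  expect_equal(inv0$free_hTERT, 500)

  inv_bad <- build_inventory(200, 500, 300)
  expect_true("rnp_exceeds_htr" %in% inv_bad$flags)
  expect_equal(inv_bad$free_hTR, 0)
})

test_that("assembled estimate does not depend on pull-down efficiency", {
  truth <- scenario("hela_like")
  est <- vapply(seq(0.1, 0.9, by = 0.1), function(eps) {
    ip <- simulate_ip(truth, epsilon = eps, noise = noiseless(), seed = 1)
    as.numeric(assembled_monomers_per_cell(truth$n_htr_per_cell, ip$ratios))
  }, numeric(1))
  expect_equal(est, rep(240, length(est)), tolerance = 1e-9)
})

test_that("delta-method SE matches a numeric jackknife of the formula", {
  se <- assembled_monomers_se(800, 0.48, 0.84, se_r_act = 0.02, se_r_htr = 0.01)
  f <- function(ra, rh) 800 * (1 - rh) / (1 - ra)
  h <- 1e-6
  d_ra <- (f(0.48 + h, 0.84) - f(0.48 - h, 0.84)) / (2 * h)
  d_rh <- (f(0.48, 0.84 + h) - f(0.48, 0.84 - h)) / (2 * h)
  expect_equal(se, sqrt((d_ra * 0.02)^2 + (d_rh * 0.01)^2), tolerance = 1e-6)
})

test_that("the benchmark IP table quantifies per replicate and per line", {
  df <- ip_benchmark()
  res <- quantify_ip(df, use_reported_rnp = "reported_rnp_per_cell")
  hek <- res$summary[["HEK293T"]]
  hela <- res$summary[["HeLa"]]
  # per-replicate reproduction from rounded printed ratios: ~6% tolerance
  expect_rel_equal(res$replicates$rnp_per_cell[2], 245, 0.06)
  expect_rel_equal(res$replicates$htert_per_cell[5], 608, 0.06)
  # means reproduce the reported 240 +/- 90 and 500 +/- 110 summaries
  expect_rel_equal(hek$rnp$mean, 240, 0.06)
  expect_rel_equal(hela$htert$mean, 500, 0.02)
})
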