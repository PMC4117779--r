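test_that("equilibrium assembly solves the binding quadratic", {
  # tight-binding limit: everything limited by the scarcer subunit
  expect_equal(equilibrium_assembly(1000, 400, 0), 400)
  expect_equal(equilibrium_assembly(300, 900, 0), 300)
  # A = B = Kd has the closed-form root (3 - sqrt(5))/2 * A
  expect_equal(equilibrium_assembly(1000, 1000, 1000),
               (3 - sqrt(5)) / 2 * 1000, tolerance = 1e-9)
  # agrees with a brute-force numeric root on the quadratic
  a <- 1150; b <- 500; kd <- 1500
  x <- equilibrium_assembly(a, b, kd)
  expect_equal(x^2 - (a + b + kd) * x + a * b, 0, tolerance = 1e-6)
  expect_lte(x, min(a, b))
  expect_error(equilibrium_assembly(-1, 10, 1), "non-negative")
})

test_that("assembly is monotone in either subunit total", {
  grid <- seq(100, 5000, by = 200)
  xa <- vapply(grid, function(a) equilibrium_assembly(a, 500, 1500), numeric(1))
  xb <- vapply(grid, function(b) equilibrium_assembly(1150, b, 1500), numeric(1))
  expect_true(all(diff(xa) > 0))
  expect_true(all(diff(xb) > 0))
})

test_that("IP simulations conserve material exactly before noise", {
  for (eps in c(0.2, 0.5, 0.9)) {
    ip <- simulate_ip(scenario("hek293t_like"), epsilon = eps, seed = 3)
    tr <- ip$fractions
    for (sp in unique(tr$species)) {
      d <- tr[tr$species == sp, ]
      expect_equal(d$true_amount[d$fraction == "input"],
                   d$true_amount[d$fraction == "flow_through"] +
                     d$true_amount[d$fraction == "elution"],
                   tolerance = 1e-9)
    }
  }
})

test_that("fixed seeds reproduce every simulated table exactly", {
  truth <- scenario("hela_like")
  expect_identical(simulate_qpcr_titration(truth, seed = 12),
                   simulate_qpcr_titration(truth, seed = 12))
  expect_identical(simulate_ip(truth, seed = 12), simulate_ip(truth, seed = 12))
  expect_identical(simulate_blot(c(1e6, 2e6), 1.5e6, 1000, seed = 12),
                   simulate_blot(c(1e6, 2e6), 1.5e6, 1000, seed = 12))
  expect_identical(simulate_direct_assay(truth, seed = 12),
                   simulate_direct_assay(truth, seed = 12))
  # and different seeds do not
  expect_false(identical(simulate_ip(truth, seed = 12)$ratios,
                         simulate_ip(truth, seed = 13)$ratios))
})

test_that("noiseless IP with full pull-down gives the closed-form ratios", {
  truth <- scenario("hela_like")
  ip <- simulate_ip(truth, epsilon = 1, noise = noiseless(), seed = 1)
  expect_equal(ip$ratios$r_act, 0)
  expect_equal(ip$ratios$r_htr, 1 - truth$n_rnp_per_cell / truth$n_htr_per_cell,
               tolerance = 1e-12)
  expect_equal(as.numeric(assembled_monomers_per_cell(truth$n_htr_per_cell,
                                                      ip$ratios)),
               truth$n_rnp_per_cell, tolerance = 1e-9)
})

test_that("capturing free hTERT inflates the elution ratio but not the total", {
  truth <- scenario("hela_like")
  plain <- simulate_ip(truth, epsilon = 0.4, noise = noiseless(), seed = 1)
  withf <- simulate_ip(truth, epsilon = 0.4, noise = noiseless(), seed = 1,
                       include_free_tert = TRUE)
  expect_gt(withf$elution$htert_per_ul / withf$elution$htr_per_ul,
            plain$elution$htert_per_ul / plain$elution$htr_per_ul)
  # under the equal-affinity assumption the stoichiometry estimator returns
  # the total hTERT per cell
  est <- tert_per_cell(truth$n_rnp_per_cell,
                       withf$elution$htr_per_ul, withf$elution$htert_per_ul)
  expect_equal(est, truth$n_htert_per_cell, tolerance = 1e-9)
})

test_that("spike-in recovery under Cq noise is unbiased within 5% (median)", {
  est <- vapply(1:200, function(sd) {
    sim <- simulate_qpcr_titration(scenario("hek293t_like"),
                                   noise = noise_model(sigma_cq = 0.15),
                                   seed = sd)
    suppressWarnings(
      quantify_spikein(sim$wells, sim$design, target = "hTR"))$endogenous_per_cell
  }, numeric(1))
  expect_rel_equal(median(est), 800, 0.05)
})

test_that("scenario presets encode the intended inventories", {
  hek <- scenario("hek293t_like")
  expect_equal(hek$n_htr_per_cell, 800)
  expect_equal(hek$n_rnp_per_cell, 240)
  expect_equal(scenario("va13_like")$n_htr_per_cell, 0)
  st <- scenario("super_telomerase")
  expect_gt(st$n_htr_per_cell, 40 * 1150)
  expect_gt(st$n_rnp_per_cell, 240)
  expect_lte(st$n_rnp_per_cell, min(st$n_htr_per_cell, st$n_htert_per_cell))
  expect_error(ground_truth(n_rnp_per_cell = 1000, n_htert_per_cell = 500),
               "exceed")
})
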