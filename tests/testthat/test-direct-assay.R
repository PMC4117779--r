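test_that("dGTP pool composition matches the recipe arithmetic", {
  pool <- dgtp_pool(assay_recipe())
  # cold: 20 ul x 25 uM = 500 pmol; hot: 30 uCi at 3000 Ci/mmol = 10 pmol
  expect_equal(pool$cold_pmol, 500)
  expect_equal(pool$hot_pmol, 10)
  expect_equal(pool$total_conc_um, 10.2)
  expect_rel_equal(pool$sa_dpm_per_pmol, 30 * 2.22e6 / 510, 1e-9)

  # limits: no label -> SA 0 and exactly 10 uM; doubling the reaction volume
  # halves the concentration but leaves the pool amount unchanged
  cold_only <- dgtp_pool(assay_recipe(hot_dgtp_volume_ul = 1e-12,
                                      hot_dgtp_uci_per_ul = 0))
  expect_equal(cold_only$sa_dpm_per_pmol, 0)
  expect_equal(cold_only$total_conc_um, 10)
  bigger <- dgtp_pool(assay_recipe(reaction_volume_ul = 100))
  expect_equal(bigger$total_conc_um, 5.1)
  expect_equal(bigger$cold_pmol + bigger$hot_pmol, 510)
  expect_error(assay_recipe(buffer_volume_ul = 60), "exceed")
})

test_that("loading-control comparison converts gel signal to cpm linearly", {
  expect_equal(product_cpm(1, 1, 1000), 900)
  expect_equal(product_cpm(0, 1, 1000), 0)
  set.seed(3)
  s <- runif(10, 0.1, 5)
  expect_equal(product_cpm(s, 2, 1000), s / 2 * 900)
  expect_error(product_cpm(1, 0, 1000), "positive")
})

test_that("nucleotide totals follow the dG fraction of the repeat", {
  expect_equal(g_fraction("TTAGGG"), 0.5)
  pool <- dgtp_pool(assay_recipe())
  expect_equal(nucleotides_incorporated(pool$sa_dpm_per_pmol, pool), 2)
  # gel exposure scale cancels between products and LC
  cpm_a <- product_cpm(10, 5, 1000)
  cpm_b <- product_cpm(10 * 7, 5 * 7, 1000)
  expect_equal(nucleotides_incorporated(cpm_a, pool),
               nucleotides_incorporated(cpm_b, pool))
  expect_error(nucleotides_incorporated(100, pool, repeat_unit = "TTATTA"), "no G")
})

test_that("enzyme specific activity is a per-enzyme per-minute rate", {
  # 1 pmol of nt over 6.022e11 enzymes in 1 min -> 1 nt/enzyme/min
  expect_equal(enzyme_specific_activity(1, 6.02214076e11, 1), 1)
  expect_equal(enzyme_specific_activity(1, 2 * 6.02214076e11, 1), 0.5)
  expect_equal(enzyme_specific_activity(1, 6.02214076e11, 100), 0.01)
  expect_error(enzyme_specific_activity(1, 0, 100), "positive")
  expect_error(enzyme_specific_activity(1, 1e7, 0), "positive")
})

test_that("simulated assays round-trip to the true specific activity", {
  truth <- ground_truth(km_um = 17, vmax_nt_min = 60)
  gel <- simulate_direct_assay(truth, seed = 21)
  res <- quantify_direct_assay(gel)
  expected_cpm <- gel$true_specific_activity * gel$n_telomerase *
    gel$duration_min / 6.02214076e23 * 1e12 * 0.5 *
    dgtp_pool(assay_recipe())$sa_dpm_per_pmol
  se_rel <- 1 / sqrt(expected_cpm)
  expect_lt(abs(res$specific_activity_nt_min / gel$true_specific_activity - 1),
            4 * se_rel)
  # the specific activity is invariant to the fraction of elution assayed
  gel2 <- gel
  gel2$fraction_assayed <- 0.5
  gel2$n_telomerase <- gel$n_telomerase / 0.5
  res2 <- quantify_direct_assay(gel2)
  expect_equal(res2$specific_activity_nt_min, res$specific_activity_nt_min)
})

test_that("linearity checks pass straight series and flag curvature and outliers", {
  t <- c(30, 60, 90, 120, 150)
  lin <- linearity_check(t, 2 * t)
  expect_true(lin$pass)
  expect_equal(lin$max_rel_deviation, 0)

  # Michaelis-shaped saturation in the abscissa is flagged
  sat <- linearity_check(t, mm_velocity(t, 40, 100))
  expect_false(sat$pass)

  y <- 2 * t; y[3] <- 2 * y[3]
  out <- linearity_check(t, y)
  expect_false(out$pass)
  expect_true(3 %in% out$flagged_points)
  expect_error(linearity_check(t[1:2], y[1:2]), "3 points")
})

test_that("fold changes carry delta-method SDs", {
  expect_equal(fold_change_activity(10, 10)$fold, 1)
  fc <- fold_change_activity(10, 20, 1, 2)
  expect_equal(fc$fold, 2)
  expect_equal(fc$sd, 2 * sqrt(0.01 + 0.01))
  expect_error(fold_change_activity(0, 10), "positive")

  # overexpressing one subunit raises assembled RNP and hence activity
  base <- equilibrium_assembly(1150, 500, 1500)
  over <- equilibrium_assembly(1150 * 60, 500, 1500)
  expect_gt(fold_change_activity(base, over)$fold, 1)
})
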