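# Shared fixtures: noiseless noise model and a quiet wrapper for estimators
# that legitimately warn on degenerate inputs.

noiseless <- function() noise_model(sigma_cq = 0, blot_lognormal_sigma = 0,
                                    poisson_counting = FALSE)

expect_rel_equal <- function(object, expected, rel_tol) {
  expect_lt(abs(object - expected) / abs(expected), rel_tol)
}
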