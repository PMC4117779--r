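#' Ground truth for simulation
#'
#' A complete per-cell state from which every simulated measurement derives:
#' total subunit copies, assembled RNP monomers, enzyme specific activity and
#' dGTP kinetic parameters. Defaults are HeLa-like.
#'
#' @param n_htr_per_cell Total hTR molecules per cell.
#' @param n_htert_per_cell Total hTERT molecules per cell.
#' @param n_rnp_per_cell Assembled telomerase monomers per cell; must not
#'   exceed either subunit total.
#' @param specific_activity_nt_min Nucleotides incorporated per monomer per
#'   minute under the assay's dGTP concentration.
#' @param km_um,vmax_nt_min Michaelis-Menten parameters for dGTP.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(n_htr_per_cell = 1150, n_htert_per_cell = 500,
                         n_rnp_per_cell = 240,
                         specific_activity_nt_min = 20,
                         km_um = 17, vmax_nt_min = 60) {
  if (any(c(n_htr_per_cell, n_htert_per_cell, n_rnp_per_cell) < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (n_rnp_per_cell > min(n_htr_per_cell, n_htert_per_cell))
    stop("assembled RNP cannot exceed either subunit total", call. = FALSE)
  structure(
    list(n_htr_per_cell = n_htr_per_cell,
         n_htert_per_cell = n_htert_per_cell,
         n_rnp_per_cell = n_rnp_per_cell,
         specific_activity_nt_min = specific_activity_nt_min,
         km_um = km_um, vmax_nt_min = vmax_nt_min),
    class = "ground_truth")
}

#' Noise model for simulated measurements
#'
#' Additive Gaussian noise on Cq values, multiplicative lognormal noise on
#' densitometry (matching imaging practice) and Poisson noise on
#' scintillation counts. The default magnitudes are conventional bench
#' values.
#'
#' @param sigma_cq SD of additive Cq noise in cycles.
#' @param blot_lognormal_sigma SD of the log band signal.
#' @param poisson_counting Draw cpm from a Poisson distribution.
#' @param ip_efficiency Pull-down efficiency of the simulated IP in (0, 1].
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(sigma_cq = 0.15, blot_lognormal_sigma = 0.1,
                        poisson_counting = TRUE, ip_efficiency = 0.5) {
  if (sigma_cq < 0 || blot_lognormal_sigma < 0)
    stop("noise SDs must be non-negative", call. = FALSE)
  if (ip_efficiency <= 0 || ip_efficiency > 1)
    stop("`ip_efficiency` must be in (0, 1]", call. = FALSE)
  structure(
    list(sigma_cq = sigma_cq, blot_lognormal_sigma = blot_lognormal_sigma,
         poisson_counting = poisson_counting, ip_efficiency = ip_efficiency),
    class = "noise_model")
}

#' Preset simulation scenarios
#'
#' Ground truths representing the cell types studied: HEK 293T-like and
#' HeLa-like inventories, a telomerase-negative line with zero hTR, and a
#' super-telomerase line with both subunits overexpressed (hTR about
#' 60-fold, hTERT about 10-fold).
#'
#' @param name One of `"hek293t_like"`, `"hela_like"`, `"va13_like"`,
#'   `"super_telomerase"`.
#' @param kd_molecules Dissociation constant (molecules/cell) used to set the
#'   assembled pool of the overexpression scenario via
#'   [equilibrium_assembly()].
#' @return A [ground_truth()].
#' @export
scenario <- function(name = c("hek293t_like", "hela_like", "va13_like",
                              "super_telomerase"),
                     kd_molecules = 1500) {
  name <- match.arg(name)
  switch(name,
    hek293t_like = ground_truth(n_htr_per_cell = 800, n_htert_per_cell = 280,
                                n_rnp_per_cell = 240),
    hela_like = ground_truth(n_htr_per_cell = 1150, n_htert_per_cell = 500,
                             n_rnp_per_cell = 240),
    va13_like = ground_truth(n_htr_per_cell = 0, n_htert_per_cell = 0,
                             n_rnp_per_cell = 0),
    super_telomerase = {
      a <- 1150 * 60; b <- 500 * 10
      x <- equilibrium_assembly(a, b, kd_molecules)
      ground_truth(n_htr_per_cell = a, n_htert_per_cell = b,
                   n_rnp_per_cell = x)
    })
}

#' Equilibrium RNP assembly (tight-binding quadratic)
#'
#' For totals A (hTR) and B (hTERT) binding with dissociation constant Kd
#' (all in molecules per cell, treating the cell as a fixed volume), the
#' assembled amount is the smaller root of `x^2 - (A + B + Kd) x + A B = 0`,
#' which satisfies `0 <= x <= min(A, B)` and increases with either total —
#' raising one subunit alone raises the assembled pool.
#'
#' @param total_htr,total_htert Total subunit copies (>= 0).
#' @param kd_molecules Dissociation constant in molecules/cell (>= 0).
#' @return Assembled RNP count.
#' @examples
#' equilibrium_assembly(1000, 1000, 0)    # min(A, B)
#' equilibrium_assembly(1000, 1000, 1000) # ~382
#' @export
equilibrium_assembly <- function(total_htr, total_htert, kd_molecules) {
  if (any(c(total_htr, total_htert, kd_molecules) < 0))
    stop("inputs must be non-negative", call. = FALSE)
  s <- total_htr + total_htert + kd_molecules
  ## numerically stable smaller root of x^2 - s x + A B = 0
  disc <- sqrt(pmax(s^2 - 4 * total_htr * total_htert, 0))
  x <- 2 * total_htr * total_htert / (s + disc)
  ifelse(total_htr * total_htert == 0, 0, pmin(x, pmin(total_htr, total_htert)))
}

#' Simulate a spike-in qPCR titration
#'
#' Generates the well and design tables of a spike-in titration experiment:
#' each titration point is a matched pair of a spiked and an unspiked sample
#' sharing the same cells and reference-gene level, with
#' `Cq = baseline_cq - log_E(copies) + N(0, sigma_cq)` per well.
#'
#' @param truth A [ground_truth()].
#' @param spike_levels Standard molecules per reaction, relative to the true
#'   endogenous amount (default 0.25x to 4x).
#' @param cells_per_reaction Cell-equivalents of RNA per reaction.
#' @param n_cq_replicates Technical Cq replicates per well.
#' @param noise A [noise_model()].
#' @param seed Integer seed; fixed seeds give identical tables.
#' @param efficiency Amplification efficiency used for both targets.
#' @param baseline_cq Cq of a single template molecule.
#' @param reference_copies Reference-gene copies per reaction (absolute level
#'   is irrelevant to the estimator; only its stability matters).
#' @return List with `wells`, `design` (the CSV schemas that
#'   [quantify_spikein()] reads) and `truth`.
#' @export
simulate_qpcr_titration <- function(truth,
                                    spike_levels = c(0.25, 0.5, 1, 2, 4),
                                    cells_per_reaction = 2000,
                                    n_cq_replicates = 3,
                                    noise = noise_model(),
                                    seed = 1,
                                    efficiency = 2,
                                    baseline_cq = 40,
                                    reference_copies = 1e7) {
  stopifnot(inherits(truth, "ground_truth"), inherits(noise, "noise_model"))
  set.seed(seed)
  endo <- truth$n_htr_per_cell * cells_per_reaction
  if (endo <= 0) stop("titration simulation requires endogenous copies > 0", call. = FALSE)
  std <- spike_levels * endo
  cq_of <- function(copies) baseline_cq - log(copies) / log(efficiency)
  wells <- list(); design <- list()
  for (i in seq_along(std)) {
    sid <- sprintf("spike_%02d", i); uid <- sprintf("unspiked_%02d", i)
    for (id in c(sid, uid)) {
      copies <- endo + if (id == sid) std[i] else 0
      for (tgt in c("hTR", "GAPDH")) {
        mu <- cq_of(if (tgt == "hTR") copies else reference_copies)
        wells[[length(wells) + 1L]] <- data.frame(
          sample_id = id, target = tgt,
          cq = mu + stats::rnorm(n_cq_replicates, 0, noise$sigma_cq),
          replicate = seq_len(n_cq_replicates), stringsAsFactors = FALSE)
      }
    }
    design[[length(design) + 1L]] <- data.frame(
      sample_id = c(sid, uid), std_molecules_added = c(std[i], 0),
      cells_per_reaction = cells_per_reaction, spiked = c(1L, 0L),
      paired_unspiked_id = c(uid, NA), stringsAsFactors = FALSE)
  }
  list(wells = do.call(rbind, wells), design = do.call(rbind, design),
       truth = truth)
}

#' Simulate an hTERT immunoprecipitation experiment
#'
#' Partitions each species between bead-bound and flow-through fractions
#' with exact conservation (input = flow-through + bound before any
#' measurement noise): the pull-down captures a fraction `epsilon` of the
#' assembled RNP (carrying its hTR), free hTR is never captured, and free
#' hTERT is captured only in the `include_free_tert` scenario. Telomerase
#' activity follows the assembled RNP. Measurement noise is lognormal on
#' blot-read quantities and Poisson on activity counts.
#'
#' @param truth A [ground_truth()].
#' @param epsilon Pull-down efficiency in (0, 1].
#' @param noise A [noise_model()]; `noise$blot_lognormal_sigma = 0` and
#'   `poisson_counting = FALSE` give noiseless tables.
#' @param seed Integer seed.
#' @param n_cells Cells in the lysate.
#' @param elution_volume_ul Elution volume.
#' @param include_free_tert Also capture free hTERT with efficiency
#'   `epsilon` (the equal-affinity-for-all-forms assumption).
#' @param activity_counts_scale Expected activity counts per RNP
#'   cell-equivalent, setting the Poisson noise level.
#' @return List with `fractions` (species x fraction amounts), `ratios`
#'   (a [depletion_ratios()]), `elution` (molecules/ul) and `truth`.
#' @export
simulate_ip <- function(truth, epsilon = 0.5, noise = noise_model(),
                        seed = 1, n_cells = 1e6, elution_volume_ul = 100,
                        include_free_tert = FALSE,
                        activity_counts_scale = 1e-2) {
  stopifnot(inherits(truth, "ground_truth"))
  if (epsilon <= 0 || epsilon > 1) stop("`epsilon` must be in (0, 1]", call. = FALSE)
  set.seed(seed)
  rnp <- truth$n_rnp_per_cell * n_cells
  htr_total <- truth$n_htr_per_cell * n_cells
  htert_total <- truth$n_htert_per_cell * n_cells
  free_htert <- htert_total - rnp

  bound_rnp <- epsilon * rnp
  bound_htr <- bound_rnp
  bound_htert <- bound_rnp + if (include_free_tert) epsilon * free_htert else 0
  ## exact conservation pre-noise
  ft_htr <- htr_total - bound_htr
  ft_htert <- htert_total - bound_htert
  ft_act <- rnp - bound_rnp

  lnoise <- function(x) if (noise$blot_lognormal_sigma > 0)
    x * stats::rlnorm(length(x), 0, noise$blot_lognormal_sigma) else x
  count <- function(x) if (noise$poisson_counting)
    stats::rpois(length(x), x * activity_counts_scale) / activity_counts_scale
    else x

  meas_htr <- c(input = lnoise(htr_total), flow_through = lnoise(ft_htr),
                elution = lnoise(bound_htr))
  meas_htert <- c(input = lnoise(htert_total), flow_through = lnoise(ft_htert),
                  elution = lnoise(bound_htert))
  meas_act <- c(input = count(rnp), flow_through = count(ft_act),
                elution = count(bound_rnp))

  fractions <- data.frame(
    species = rep(c("hTR", "hTERT", "activity"), each = 3),
    fraction = rep(c("input", "flow_through", "elution"), times = 3),
    amount = c(meas_htr, meas_htert, meas_act),
    true_amount = c(htr_total, ft_htr, bound_htr,
                    htert_total, ft_htert, bound_htert,
                    rnp, ft_act, bound_rnp),
    stringsAsFactors = FALSE)

  ratios <- depletion_ratios(
    r_act = min(meas_act[["flow_through"]] / meas_act[["input"]], 1),
    r_htr = min(meas_htr[["flow_through"]] / meas_htr[["input"]], 1))
  list(fractions = fractions, ratios = ratios,
       elution = list(htr_per_ul = meas_htr[["elution"]] / elution_volume_ul,
                      htert_per_ul = meas_htert[["elution"]] / elution_volume_ul),
       epsilon = epsilon, n_cells = n_cells, truth = truth)
}

#' Simulate a blot standard titration with sample lanes
#'
#' Band signal is proportional to molecules loaded with per-gel gain `k` and
#' multiplicative lognormal noise; standards and samples share `k` within a
#' gel, so quantification against the gel's own standards is scale-free.
#'
#' @param std_molecules Molecules in the standard lanes.
#' @param sample_molecules True molecules in the sample lanes.
#' @param cells_loaded Cells per sample lane (recycled).
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param gel_gain Signal per molecule for this gel (AU).
#' @return Lane table in the [read_lane_measurements()] schema.
#' @export
simulate_blot <- function(std_molecules, sample_molecules, cells_loaded = NA,
                          noise = noise_model(), seed = 1, gel_gain = 1e-4) {
  set.seed(seed)
  s <- noise$blot_lognormal_sigma
  sig <- function(m) gel_gain * m *
    (if (s > 0) stats::rlnorm(length(m), 0, s) else 1)
  n_std <- length(std_molecules); n_smp <- length(sample_molecules)
  data.frame(
    lane_id = c(sprintf("std_%02d", seq_len(n_std)),
                sprintf("sample_%02d", seq_len(n_smp))),
    target = "hTR",
    role = c(rep("standard", n_std), rep("sample", n_smp)),
    signal = c(sig(std_molecules), sig(sample_molecules)),
    std_molecules = c(std_molecules, rep(NA, n_smp)),
    cells_loaded = c(rep(NA, n_std), rep(cells_loaded, length.out = n_smp)),
    elution_volume_ul = NA,
    stringsAsFactors = FALSE)
}

#' Simulate a direct telomerase extension assay
#'
#' Expected nucleotides incorporated are `v * n_telomerase * duration`, with
#' the velocity either fixed at the truth's specific activity or computed
#' from its Michaelis-Menten parameters at the recipe's dGTP concentration.
#' Product radioactivity follows through the dGTP-pool forward model and is
#' drawn Poisson around its expectation; gel signals are generated so that
#' the loading-control comparison (with 90 percent of LC radioactivity in
#' the band) recovers the product cpm.
#'
#' @param truth A [ground_truth()].
#' @param recipe An [assay_recipe()].
#' @param n_telomerase Telomerase monomers in the assayed aliquot.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param use_mm Compute the velocity from Km/Vmax at the pool concentration
#'   (default) instead of using `truth$specific_activity_nt_min`.
#' @param lc_cpm Loading-control cpm.
#' @param gel_gain Gel signal per cpm (cancels in the analysis).
#' @return One-row gel table in the [read_gel_quantification()] schema, with
#'   attribute `true_specific_activity`.
#' @export
simulate_direct_assay <- function(truth, recipe = assay_recipe(),
                                  n_telomerase = 2.7e7,
                                  noise = noise_model(), seed = 1,
                                  use_mm = TRUE, lc_cpm = 2e5,
                                  gel_gain = 1e-3) {
  stopifnot(inherits(truth, "ground_truth"), inherits(recipe, "assay_recipe"))
  set.seed(seed)
  pool <- dgtp_pool(recipe)
  v <- if (use_mm) mm_velocity(pool$total_conc_um, truth$km_um, truth$vmax_nt_min)
       else truth$specific_activity_nt_min
  nt_molecules <- v * n_telomerase * recipe$duration_min
  nt_pmol <- nt_molecules / AVOGADRO * 1e12
  dgmp_pmol <- nt_pmol * g_fraction(recipe$repeat_unit)
  expected_cpm <- dgmp_pmol * pool$sa_dpm_per_pmol
  cpm <- if (noise$poisson_counting) stats::rpois(1, expected_cpm) else expected_cpm
  data.frame(
    assay_id = "assay_01",
    products_signal = gel_gain * cpm,
    lc_signal = gel_gain * lc_cpm * 0.9,
    lc_cpm = lc_cpm,
    lc_band_fraction = 0.9,
    n_telomerase = n_telomerase,
    fraction_assayed = 1,
    duration_min = recipe$duration_min,
    true_specific_activity = v,
    stringsAsFactors = FALSE)
}

#' Simulate velocity measurements across a dGTP titration
#'
#' Michaelis-Menten velocities at the given concentrations with
#' multiplicative Gaussian noise, the raw material for kinetics parameter
#' recovery. Technical replicates share the truth and differ only in noise.
#'
#' @param km_um,vmax True parameters.
#' @param substrate_um Concentrations of the titration.
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param n_technical Technical replicates per concentration.
#' @param replicate Biological replicate label(s).
#' @param seed Integer seed.
#' @return Data frame `substrate_um, velocity, replicate, technical_rep`.
#' @export
simulate_velocity_points <- function(km_um, vmax,
                                     substrate_um = c(2, 5, 10, 20, 50, 100),
                                     cv = 0.05, n_technical = 2,
                                     replicate = 1, seed = 1) {
  set.seed(seed)
  out <- expand.grid(substrate_um = substrate_um, replicate = replicate,
                     technical_rep = seq_len(n_technical))
  mu <- mm_velocity(out$substrate_um, km_um, vmax)
  out$velocity <- mu * pmax(1 + stats::rnorm(nrow(out), 0, cv), 1e-6)
  out[, c("substrate_um", "velocity", "replicate", "technical_rep")]
}
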