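#' Amplification efficiency from a dilution series
#'
#' Fits Cq against log10(dilution) by ordinary least squares and converts the
#' slope to a per-cycle amplification efficiency `E = 10^(-1/slope)`. A
#' perfect doubling assay gives a slope of -3.3219 cycles per log and E = 2.
#'
#' @param log10_dilution Numeric vector of log10 relative template amounts.
#' @param mean_cq Numeric vector of mean Cq values, same length.
#' @return A list of class `primer_efficiency` with elements `efficiency`,
#'   `slope`, `r_squared` and `n`.
#' @examples
#' primer_efficiency(0:-3, 20 + 3.3219 * (0:3))
#' @export
primer_efficiency <- function(log10_dilution, mean_cq) {
  if (length(log10_dilution) != length(mean_cq))
    stop("inputs must have the same length", call. = FALSE)
  if (length(log10_dilution) < 3L)
    stop("at least 3 dilution points are required", call. = FALSE)
  if (diff(range(log10_dilution)) < 2)
    warning("dilution series spans less than 2 logs; efficiency estimate may be unstable")
  fit <- stats::lm(mean_cq ~ log10_dilution)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("non-negative slope: Cq must decrease with template amount", call. = FALSE)
  structure(
    list(efficiency = 10^(-1 / slope), slope = slope,
         r_squared = .quiet_lm(summary(fit))$r.squared, n = length(mean_cq)),
    class = "primer_efficiency")
}

#' Efficiency-corrected relative quantity
#'
#' Reference-normalized template quantity `E_t^(-Cq_t) / E_r^(-Cq_r)`, defined
#' up to an arbitrary common scale; only ratios between samples sharing the
#' same target and reference are meaningful.
#'
#' @param cq_target,cq_reference Cq values for the target and the internal
#'   reference (e.g. GAPDH) in the same sample.
#' @param eff_target,eff_reference Amplification efficiencies in (1, 2.2].
#' @return Positive relative quantity.
#' @export
relative_quantity <- function(cq_target, cq_reference,
                              eff_target = 2, eff_reference = 2) {
  .check_eff(eff_target); .check_eff(eff_reference)
  eff_target^(-cq_target) / eff_reference^(-cq_reference)
}

.check_eff <- function(e) {
  if (any(e <= 1 | e > 2.2))
    stop("amplification efficiency must be in (1, 2.2]", call. = FALSE)
  invisible(e)
}

#' Standard-to-endogenous ratio for one spike-in titration point
#'
#' A spiked sample contains endogenous plus standard molecules; its matched
#' unspiked sample contains the endogenous molecules only. Their quantity
#' ratio minus one is the molar ratio of standard to endogenous RNA. Under
#' measurement noise the ratio can come out non-positive for small spikes;
#' such points are retained (dropping them would bias the fit upward) and the
#' caller may flag them.
#'
#' @param relative_quantity_spiked,relative_quantity_unspiked Reference-
#'   normalized quantities from [relative_quantity()] for a matched pair.
#' @return The calculated ratio (standard : endogenous); can be <= 0 under noise.
#' @export
spike_ratio <- function(relative_quantity_spiked, relative_quantity_unspiked) {
  if (any(relative_quantity_unspiked <= 0))
    stop("unspiked relative quantity must be positive", call. = FALSE)
  relative_quantity_spiked / relative_quantity_unspiked - 1
}

#' Fit a spike-in titration and estimate endogenous copies
#'
#' The calculated ratio R is modeled as proportional to the number of
#' standard molecules added, `R = m * S`. The standard equals the endogenous
#' amount where R = 1, so the endogenous copies per reaction are `1/m`. A
#' line through the origin is the default because R = 0 at S = 0 by
#' construction; an unconstrained line is available for diagnostics.
#'
#' @param std_molecules_added Standard molecules added per reaction (S).
#' @param ratio Calculated standard:endogenous ratios (R), from [spike_ratio()].
#' @param cells_per_reaction Number of cell-equivalents of RNA per reaction.
#' @param weighting `"none"` (default) or `"inv_std"` for 1/S weights, which
#'   emphasize the low-spike points nearest the R = 1 crossing.
#' @param through_origin Fit `R ~ 0 + S` (default) or `R ~ S`.
#' @return A list of class `titration_fit` with `slope_per_molecule`,
#'   `intercept`, `r_squared`, `endogenous_per_reaction`,
#'   `endogenous_per_cell`, `n_points` and `n_nonpositive_ratio`.
#' @examples
#' s <- c(325, 650, 1300, 2600, 5200)
#' fit_titration(s, s / 1300, cells_per_reaction = 1)
#' @export
fit_titration <- function(std_molecules_added, ratio, cells_per_reaction,
                          weighting = c("none", "inv_std"),
                          through_origin = TRUE) {
  weighting <- match.arg(weighting)
  s <- std_molecules_added
  if (length(s) != length(ratio)) stop("inputs must have the same length", call. = FALSE)
  if (length(unique(s)) < 3L)
    stop("at least 3 distinct standard amounts are required", call. = FALSE)
  if (all(s == 0)) stop("all standard amounts are zero", call. = FALSE)
  if (any(cells_per_reaction <= 0))
    stop("`cells_per_reaction` must be positive", call. = FALSE)
  w <- if (weighting == "inv_std") ifelse(s > 0, 1 / s, 0) else rep(1, length(s))
  fit <- if (through_origin) stats::lm(ratio ~ 0 + s, weights = w)
         else stats::lm(ratio ~ s, weights = w)
  cf <- stats::coef(fit)
  m <- unname(cf[["s"]])
  if (!is.finite(m) || m <= 0)
    stop("non-positive titration slope: endogenous amount not identifiable", call. = FALSE)
  if (all(ratio < 1) || all(ratio > 1))
    warning("no titration point brackets the ratio = 1 crossing; estimate is an extrapolation")
  per_reaction <- 1 / m
  structure(
    list(slope_per_molecule = m,
         intercept = if (through_origin) 0 else unname(cf[[1]]),
         r_squared = .quiet_lm(summary(fit))$r.squared,
         endogenous_per_reaction = per_reaction,
         endogenous_per_cell = per_reaction / cells_per_reaction,
         n_points = length(s),
         n_nonpositive_ratio = sum(ratio <= 0),
         weighting = weighting, through_origin = through_origin),
    class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat("Spike-in titration fit (", x$n_points, " points, ",
      if (x$through_origin) "through origin" else "free intercept", ")\n", sep = "")
  cat(sprintf("  slope: %.4g per molecule, R^2 = %.4f\n", x$slope_per_molecule, x$r_squared))
  cat(sprintf("  endogenous: %.4g per reaction, %.4g per cell\n",
              x$endogenous_per_reaction, x$endogenous_per_cell))
  if (x$n_nonpositive_ratio > 0)
    cat("  note:", x$n_nonpositive_ratio, "point(s) with ratio <= 0 retained in fit\n")
  invisible(x)
}

#' Summarize replicate Cq values per sample and target
#'
#' Averages technical Cq replicates and flags any sample/target combination
#' whose replicate range exceeds a QC threshold (default 0.5 cycles).
#'
#' @param wells Data frame with columns `sample_id`, `target`, `cq` and
#'   optionally `replicate`.
#' @param max_range Replicate-range QC threshold in cycles.
#' @return Data frame with `sample_id`, `target`, `cq` (mean), `n`,
#'   `cq_range`, `range_flag`.
#' @export
summarize_cq <- function(wells, max_range = 0.5) {
  stopifnot(all(c("sample_id", "target", "cq") %in% names(wells)))
  if (any(wells$cq < 0 | wells$cq > 45))
    stop("Cq values must lie in [0, 45]", call. = FALSE)
  agg <- stats::aggregate(cq ~ sample_id + target, data = wells,
                          FUN = function(x) c(mean = mean(x), n = length(x),
                                              rng = diff(range(x))))
  out <- data.frame(sample_id = agg$sample_id, target = agg$target,
                    cq = agg$cq[, "mean"], n = as.integer(agg$cq[, "n"]),
                    cq_range = agg$cq[, "rng"], stringsAsFactors = FALSE)
  out$range_flag <- out$cq_range > max_range
  out
}

#' Absolute copies per cell from a spike-in qPCR experiment
#'
#' Full workflow for one primer pair: average Cq replicates, compute
#' reference-normalized quantities, form spiked/unspiked ratios from the
#' titration design, and fit the titration line.
#'
#' @param wells Well table: `sample_id`, `target`, `cq`, `replicate`.
#' @param design Titration design: `sample_id`, `std_molecules_added`,
#'   `cells_per_reaction`, `spiked` (0/1), `paired_unspiked_id`.
#' @param target Target (primer pair) label present in `wells`.
#' @param reference Reference target label (internal control).
#' @param eff_target,eff_reference Amplification efficiencies.
#' @param ... Passed to [fit_titration()].
#' @return A `titration_fit` with an additional `points` data frame attached.
#' @export
quantify_spikein <- function(wells, design, target, reference = "GAPDH",
                             eff_target = 2, eff_reference = 2, ...) {
  cq <- summarize_cq(wells)
  getcq <- function(id, tgt) {
    v <- cq$cq[cq$sample_id == id & cq$target == tgt]
    if (length(v) != 1L)
      stop("missing or duplicated Cq for sample '", id, "', target '", tgt, "'",
           call. = FALSE)
    v
  }
  spiked <- design[design$spiked == 1, , drop = FALSE]
  if (nrow(spiked) < 3L) stop("need at least 3 spiked samples", call. = FALSE)
  rq <- function(id) relative_quantity(getcq(id, target), getcq(id, reference),
                                       eff_target, eff_reference)
  pts <- data.frame(
    sample_id = spiked$sample_id,
    std_molecules_added = spiked$std_molecules_added,
    cells_per_reaction = spiked$cells_per_reaction,
    stringsAsFactors = FALSE)
  pts$ratio <- mapply(function(id, uid) spike_ratio(rq(id), rq(uid)),
                      spiked$sample_id, spiked$paired_unspiked_id)
  cells <- unique(pts$cells_per_reaction)
  if (length(cells) != 1L)
    stop("all titration reactions must use the same number of cells", call. = FALSE)
  fit <- fit_titration(pts$std_molecules_added, pts$ratio, cells, ...)
  fit$points <- pts
  fit$target <- target
  fit
}

#' Combine copies-per-cell estimates from several primer pairs
#'
#' @param estimates Numeric vector of copies-per-cell estimates.
#' @return List with `mean`, `sd` (NA with a flag when n < 2) and `n`.
#' @export
aggregate_primer_pairs <- function(estimates) {
  if (length(estimates) < 1L) stop("no estimates supplied", call. = FALSE)
  list(mean = mean(estimates),
       sd = if (length(estimates) >= 2L) stats::sd(estimates) else NA_real_,
       n = length(estimates),
       sd_defined = length(estimates) >= 2L)
}

#' Read qPCR well and titration design tables
#'
#' @param path CSV file path. Wells: `sample_id,target,cq,replicate`.
#'   Design: `sample_id,std_molecules_added,cells_per_reaction,spiked,
#'   paired_unspiked_id`.
#' @return Data frame.
#' @export
read_qpcr_wells <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "target", "cq")
  if (!all(need %in% names(df)))
    stop("well table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  df
}

#' @rdname read_qpcr_wells
#' @export
read_titration_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "std_molecules_added", "cells_per_reaction", "spiked",
            "paired_unspiked_id")
  if (!all(need %in% names(df)))
    stop("design table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  df
}
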