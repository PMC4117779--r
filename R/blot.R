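#' Fit a densitometry standard curve
#'
#' Least-squares line of background-subtracted band signal on the number of
#' standard molecules loaded. The origin-forced fit is the default since zero
#' molecules should give zero net signal; the linear range is recorded as the
#' span of the standard signals so that sample bands outside it can be
#' flagged as extrapolated.
#'
#' @param std_molecules Molecules loaded in each standard lane.
#' @param signal Net densitometry signal of each standard lane (AU).
#' @param force_origin Force the line through the origin (default TRUE).
#' @return Object of class `standard_curve`: `slope_signal_per_molecule`,
#'   `intercept`, `r_squared`, `linear_range`, `n`.
#' @examples
#' fit_standard_curve(c(1e6, 2e6), c(100, 200))
#' @export
fit_standard_curve <- function(std_molecules, signal, force_origin = TRUE) {
  if (length(std_molecules) != length(signal))
    stop("inputs must have the same length", call. = FALSE)
  if (length(unique(std_molecules)) < 2L)
    stop("at least 2 standard lanes with distinct amounts are required", call. = FALSE)
  if (any(std_molecules <= 0)) stop("standard amounts must be positive", call. = FALSE)
  fit <- if (force_origin) stats::lm(signal ~ 0 + std_molecules)
         else stats::lm(signal ~ std_molecules)
  cf <- stats::coef(fit)
  slope <- unname(cf[["std_molecules"]])
  if (!is.finite(slope) || slope <= 0)
    stop("non-positive calibration slope", call. = FALSE)
  structure(
    list(slope_signal_per_molecule = slope,
         intercept = if (force_origin) 0 else unname(cf[[1]]),
         r_squared = .quiet_lm(summary(fit))$r.squared,
         linear_range = range(signal),
         n = length(signal)),
    class = "standard_curve")
}

#' Convert band signals to molecules via a standard curve
#'
#' @param signal Net band signal(s) in the same AU as the standards.
#' @param curve A [fit_standard_curve()] object.
#' @return Data frame with `molecules` (clamped at 0 with a warning if the
#'   inverse prediction is negative) and `extrapolated` (TRUE when the signal
#'   falls outside the standards' linear range).
#' @export
quantify_band <- function(signal, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  mol <- (signal - curve$intercept) / curve$slope_signal_per_molecule
  if (any(mol < 0)) {
    warning("negative inverse prediction clamped to 0 molecules")
    mol <- pmax(mol, 0)
  }
  data.frame(
    molecules = mol,
    extrapolated = signal < curve$linear_range[1] | signal > curve$linear_range[2])
}

#' Molecules per cell from a quantified band
#'
#' @param molecules Molecules in the lane.
#' @param cells_loaded Number of cell-equivalents loaded in the lane.
#' @return Molecules per cell.
#' @export
copies_per_cell <- function(molecules, cells_loaded) {
  if (any(cells_loaded <= 0)) stop("`cells_loaded` must be positive", call. = FALSE)
  if (any(molecules < 0)) stop("`molecules` must be non-negative", call. = FALSE)
  molecules / cells_loaded
}

#' Upper bound on copies per cell from a blot detection limit
#'
#' When a target is undetectable, the assay detection limit divided by the
#' number of cells loaded bounds the possible copies per cell from above.
#'
#' @param limit_molecules Detection limit in molecules (e.g. from
#'   [rna_mass_to_molecules()] applied to the limiting mass).
#' @param cells_loaded Cells loaded in the blank lane.
#' @return List of class `detection_bound`: `bound_per_cell`, inputs.
#' @examples
#' detection_limit_bound(8.3e6, 1e6) # < 8.3 copies/cell
#' @export
detection_limit_bound <- function(limit_molecules, cells_loaded) {
  if (any(limit_molecules < 0)) stop("`limit_molecules` must be non-negative", call. = FALSE)
  if (any(cells_loaded <= 0)) stop("`cells_loaded` must be positive", call. = FALSE)
  structure(
    list(bound_per_cell = limit_molecules / cells_loaded,
         limit_molecules = limit_molecules, cells_loaded = cells_loaded),
    class = "detection_bound")
}

#' @export
print.detection_bound <- function(x, ...) {
  cat(sprintf("< %.3g molecules per cell (detection limit %.3g molecules over %.3g cells)\n",
              x$bound_per_cell, x$limit_molecules, x$cells_loaded))
  invisible(x)
}

#' Normalize a sample signal to an internal control
#'
#' Rescales a lane's signal by the ratio of a reference control signal to the
#' lane's own control signal, correcting for loading differences. With equal
#' controls this is the identity.
#'
#' @param sample_signal Net target signal in the lane.
#' @param control_signal Internal-control signal in the same lane (> 0).
#' @param reference_control_signal Control signal in the reference lane (> 0).
#' @return Normalized signal.
#' @export
control_normalize <- function(sample_signal, control_signal,
                              reference_control_signal) {
  if (any(control_signal <= 0) || any(reference_control_signal <= 0))
    stop("control signals must be positive", call. = FALSE)
  sample_signal * reference_control_signal / control_signal
}

#' Read a blot lane table
#'
#' @param path CSV with columns `lane_id,target,role,signal,std_molecules,
#'   cells_loaded,elution_volume_ul` (roles: standard, sample,
#'   internal_control; irrelevant fields may be empty/NA).
#' @return Data frame.
#' @export
read_lane_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lane_id", "target", "role", "signal")
  if (!all(need %in% names(df)))
    stop("lane table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  df
}

#' Quantify a blot from a lane table
#'
#' Fits the standard curve from `role == "standard"` lanes and quantifies the
#' `role == "sample"` lanes, reporting molecules, molecules per cell (when
#' `cells_loaded` is given) and molecules per microliter (when
#' `elution_volume_ul` is given).
#'
#' @param lanes Data frame as from [read_lane_measurements()].
#' @param force_origin Passed to [fit_standard_curve()].
#' @return List with `curve` and a `samples` data frame.
#' @export
quantify_blot <- function(lanes, force_origin = TRUE) {
  std <- lanes[lanes$role == "standard", , drop = FALSE]
  smp <- lanes[lanes$role == "sample", , drop = FALSE]
  curve <- fit_standard_curve(std$std_molecules, std$signal,
                              force_origin = force_origin)
  q <- quantify_band(smp$signal, curve)
  out <- data.frame(lane_id = smp$lane_id, target = smp$target,
                    molecules = q$molecules, extrapolated = q$extrapolated,
                    stringsAsFactors = FALSE)
  out$molecules_per_cell <- if ("cells_loaded" %in% names(smp))
    ifelse(!is.na(smp$cells_loaded) & smp$cells_loaded > 0,
           q$molecules / smp$cells_loaded, NA_real_) else NA_real_
  out$molecules_per_ul <- if ("elution_volume_ul" %in% names(smp))
    ifelse(!is.na(smp$elution_volume_ul) & smp$elution_volume_ul > 0,
           q$molecules / smp$elution_volume_ul, NA_real_) else NA_real_
  list(curve = curve, samples = out)
}
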