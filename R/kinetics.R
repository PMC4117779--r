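#' Michaelis-Menten velocity
#'
#' @param s Substrate concentration (uM).
#' @param km Michaelis constant (uM).
#' @param vmax Maximal velocity (nt per enzyme per minute).
#' @return Velocity `vmax * s / (km + s)`.
#' @export
mm_velocity <- function(s, km, vmax) {
  if (any(s < 0) || any(km <= 0) || any(vmax <= 0))
    stop("`s` must be non-negative and `km`, `vmax` positive", call. = FALSE)
  vmax * s / (km + s)
}

#' Lineweaver-Burk estimate of Km and Vmax
#'
#' Ordinary least squares of 1/v on 1/S. The intercept is 1/Vmax and the
#' slope is Km/Vmax; their standard deviations follow from the coefficient
#' covariance by the delta method. Because the double-reciprocal transform
#' distorts the error structure, an optional `w ~ v^4` weighting is provided,
#' which restores approximately constant variance when the raw velocities
#' have constant variance.
#'
#' @param substrate_um Substrate concentrations (uM), at least 3 distinct.
#' @param velocity Velocities (nt per enzyme per minute), positive.
#' @param weighted Use `v^4` weights (default FALSE, the classical plot).
#' @return Object of class `mm_fit` with `km_um`, `vmax`, `km_sd`, `vmax_sd`,
#'   `method`, `r_squared`.
#' @export
lineweaver_burk_fit <- function(substrate_um, velocity, weighted = FALSE) {
  .check_mm_points(substrate_um, velocity)
  x <- 1 / substrate_um
  y <- 1 / velocity
  w <- if (weighted) velocity^4 else rep(1, length(velocity))
  fit <- stats::lm(y ~ x, weights = w)
  b <- stats::coef(fit)
  b0 <- unname(b[1]); b1 <- unname(b[2])
  if (b0 <= 0)
    stop("non-positive intercept: data do not approach saturation", call. = FALSE)
  if (b1 <= 0)
    stop("non-positive slope: velocities do not decrease with 1/S", call. = FALSE)
  V <- .quiet_lm(stats::vcov(fit))
  ## delta method: Vmax = 1/b0, Km = b1/b0
  g_vmax <- c(-1 / b0^2, 0)
  g_km <- c(-b1 / b0^2, 1 / b0)
  structure(
    list(km_um = b1 / b0, vmax = 1 / b0,
         km_sd = sqrt(drop(t(g_km) %*% V %*% g_km)),
         vmax_sd = sqrt(drop(t(g_vmax) %*% V %*% g_vmax)),
         method = "lineweaver_burk",
         r_squared = .quiet_lm(summary(fit))$r.squared,
         n = length(velocity)),
    class = "mm_fit")
}

#' Nonlinear least-squares Michaelis-Menten fit
#'
#' Levenberg-Marquardt least squares on the untransformed rate law
#' `v = Vmax S / (Km + S)`, initialized from the Lineweaver-Burk estimates
#' unless starting values are supplied. Unlike the double-reciprocal fit it
#' does not overweight the low-substrate points.
#'
#' @param substrate_um,velocity As in [lineweaver_burk_fit()].
#' @param init Optional list with `km` and `vmax` starting values.
#' @return Object of class `mm_fit` (with `r_squared = NA`).
#' @export
nonlinear_mm_fit <- function(substrate_um, velocity, init = NULL) {
  .check_mm_points(substrate_um, velocity)
  if (is.null(init)) {
    lb <- lineweaver_burk_fit(substrate_um, velocity)
    init <- list(km = lb$km_um, vmax = lb$vmax)
  }
  df <- data.frame(s = substrate_um, v = velocity)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ vmax * s / (km + s), data = df,
                      start = list(km = init$km, vmax = init$vmax),
                      lower = c(km = 1e-12, vmax = 1e-12),
                      control = minpack.lm::nls.lm.control(ftol = 1e-12,
                                                           ptol = 1e-12,
                                                           maxiter = 200)),
    error = function(e)
      stop("nonlinear fit failed to converge: ", conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(km = NA_real_, vmax = NA_real_))
  structure(
    list(km_um = unname(cf["km"]), vmax = unname(cf["vmax"]),
         km_sd = unname(se["km"]), vmax_sd = unname(se["vmax"]),
         method = "nonlinear", r_squared = NA_real_,
         n = length(velocity)),
    class = "mm_fit")
}

.check_mm_points <- function(s, v) {
  if (length(s) != length(v)) stop("inputs must have the same length", call. = FALSE)
  if (any(s <= 0) || any(v <= 0))
    stop("substrate concentrations and velocities must be positive", call. = FALSE)
  if (length(unique(s)) < 3L)
    stop("at least 3 distinct substrate concentrations are required", call. = FALSE)
  invisible(NULL)
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit (%s, n = %d)\n", x$method, x$n))
  cat(sprintf("  Km   = %.3g +/- %.2g uM\n", x$km_um, x$km_sd))
  cat(sprintf("  Vmax = %.3g +/- %.2g nt/enzyme/min\n", x$vmax, x$vmax_sd))
  invisible(x)
}

#' Average technical replicates of velocity measurements
#'
#' @param df Data frame with columns `substrate_um`, `velocity`, `replicate`
#'   (biological) and optionally `technical_rep`.
#' @return Data frame with one row per substrate concentration and
#'   biological replicate, velocities averaged over technical replicates.
#' @export
average_technical_reps <- function(df) {
  stopifnot(all(c("substrate_um", "velocity", "replicate") %in% names(df)))
  stats::aggregate(velocity ~ substrate_um + replicate, data = df, FUN = mean)
}

#' Per-replicate kinetics fits with a pooled summary
#'
#' Averages technical replicates, fits each biological replicate separately
#' with the requested method, and reports the across-replicate mean and
#' sample SD of Km and Vmax.
#'
#' @param df As in [average_technical_reps()].
#' @param method `"lineweaver_burk"` or `"nonlinear"`.
#' @return List with `fits` (one `mm_fit` per replicate) and `pooled`
#'   (mean/sd of km and vmax across replicates).
#' @export
fit_mm_replicates <- function(df, method = c("lineweaver_burk", "nonlinear")) {
  method <- match.arg(method)
  avg <- average_technical_reps(df)
  fits <- lapply(split(avg, avg$replicate), function(d) {
    if (method == "lineweaver_burk") lineweaver_burk_fit(d$substrate_um, d$velocity)
    else nonlinear_mm_fit(d$substrate_um, d$velocity)
  })
  km <- vapply(fits, `[[`, numeric(1), "km_um")
  vmax <- vapply(fits, `[[`, numeric(1), "vmax")
  list(fits = fits,
       pooled = list(km = replicate_summary(km), vmax = replicate_summary(vmax)))
}
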