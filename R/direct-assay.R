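#' Direct telomerase extension assay recipe
#'
#' The defaults describe a 50 ul reaction: 30 ul enzyme sample plus 20 ul
#' assay buffer containing 25 uM cold dGTP and 3 ul of alpha-32P-dGTP at
#' 10 uCi/ul and 3000 Ci/mmol, run for 2 h at 37 C on a telomeric-repeat
#' primer.
#'
#' @param reaction_volume_ul Total reaction volume.
#' @param buffer_volume_ul Assay buffer volume contributing the cold dGTP.
#' @param buffer_cold_dgtp_um Cold dGTP concentration in the buffer (uM).
#' @param hot_dgtp_volume_ul Volume of labeled dGTP added (ul).
#' @param hot_dgtp_uci_per_ul Activity concentration of the labeled stock.
#' @param hot_dgtp_ci_per_mmol Specific radioactivity of the labeled stock.
#' @param duration_min Assay duration in minutes.
#' @param temperature_c Assay temperature (recorded, not used numerically).
#' @param repeat_unit Telomeric repeat synthesized (used for the dG fraction).
#' @return Object of class `assay_recipe`.
#' @export
assay_recipe <- function(reaction_volume_ul = 50, buffer_volume_ul = 20,
                         buffer_cold_dgtp_um = 25, hot_dgtp_volume_ul = 3,
                         hot_dgtp_uci_per_ul = 10, hot_dgtp_ci_per_mmol = 3000,
                         duration_min = 120, temperature_c = 37,
                         repeat_unit = "TTAGGG") {
  if (buffer_volume_ul + hot_dgtp_volume_ul > reaction_volume_ul)
    stop("component volumes exceed the reaction volume", call. = FALSE)
  if (duration_min <= 0) stop("`duration_min` must be positive", call. = FALSE)
  structure(
    list(reaction_volume_ul = reaction_volume_ul,
         buffer_volume_ul = buffer_volume_ul,
         buffer_cold_dgtp_um = buffer_cold_dgtp_um,
         hot_dgtp_volume_ul = hot_dgtp_volume_ul,
         hot_dgtp_uci_per_ul = hot_dgtp_uci_per_ul,
         hot_dgtp_ci_per_mmol = hot_dgtp_ci_per_mmol,
         duration_min = duration_min, temperature_c = temperature_c,
         repeat_unit = repeat_unit),
    class = "assay_recipe")
}

#' dGTP pool composition and specific radioactivity
#'
#' Combines the cold dGTP from the assay buffer with the labeled dGTP to give
#' the total dGTP concentration in the reaction and the specific
#' radioactivity of the pool (dpm per pmol of dGTP), which converts product
#' radioactivity into moles of dGMP incorporated.
#'
#' @param recipe An [assay_recipe()].
#' @return List of class `dgtp_pool`: `cold_pmol`, `hot_pmol`,
#'   `total_conc_um`, `hot_fraction`, `sa_dpm_per_pmol`, `total_dpm`.
#' @examples
#' dgtp_pool(assay_recipe()) # ~10.2 uM, ~1.31e5 dpm/pmol
#' @export
dgtp_pool <- function(recipe) {
  stopifnot(inherits(recipe, "assay_recipe"))
  cold_pmol <- recipe$buffer_volume_ul * recipe$buffer_cold_dgtp_um
  hot_uci <- recipe$hot_dgtp_volume_ul * recipe$hot_dgtp_uci_per_ul
  hot_pmol <- if (hot_uci > 0)
    activity_to_pmol(hot_uci, recipe$hot_dgtp_ci_per_mmol) else 0
  total_pmol <- cold_pmol + hot_pmol
  if (total_pmol <= 0) stop("reaction contains no dGTP", call. = FALSE)
  total_dpm <- uci_to_dpm(hot_uci)
  structure(
    list(cold_pmol = cold_pmol, hot_pmol = hot_pmol,
         total_conc_um = total_pmol / recipe$reaction_volume_ul,
         hot_fraction = hot_pmol / total_pmol,
         total_dpm = total_dpm,
         sa_dpm_per_pmol = total_dpm / total_pmol),
    class = "dgtp_pool")
}

#' Absolute product radioactivity from gel signals
#'
#' The extension-product ladder signal is converted to cpm by comparison with
#' the co-precipitated loading control (LC) oligonucleotide, whose absolute
#' cpm were measured by scintillation counting. Only `lc_band_fraction` of
#' the LC sample's radioactivity runs at the LC band position, so the LC band
#' signal corresponds to `lc_cpm * lc_band_fraction` counts.
#'
#' @param products_signal Summed densitometry signal of extension products (AU).
#' @param lc_signal Densitometry signal of the LC band (AU, > 0).
#' @param lc_cpm Scintillation-measured cpm of the LC sample.
#' @param lc_band_fraction Fraction of LC radioactivity in the LC band.
#' @return Product radioactivity in cpm.
#' @examples
#' product_cpm(1, 1, 1000) # 900 with the default 0.9 band fraction
#' @export
product_cpm <- function(products_signal, lc_signal, lc_cpm,
                        lc_band_fraction = 0.9) {
  if (any(lc_signal <= 0)) stop("`lc_signal` must be positive", call. = FALSE)
  if (any(products_signal < 0)) stop("`products_signal` must be non-negative", call. = FALSE)
  if (any(lc_cpm <= 0)) stop("`lc_cpm` must be positive", call. = FALSE)
  if (any(lc_band_fraction <= 0 | lc_band_fraction > 1))
    stop("`lc_band_fraction` must be in (0, 1]", call. = FALSE)
  products_signal / lc_signal * (lc_cpm * lc_band_fraction)
}

#' Fraction of dG in a repeat unit
#'
#' @param repeat_unit DNA repeat sequence, e.g. `"TTAGGG"`.
#' @return Fraction of G residues (0.5 for the telomeric repeat).
#' @export
g_fraction <- function(repeat_unit) {
  chars <- strsplit(toupper(repeat_unit), "")[[1]]
  if (length(chars) == 0L) stop("empty repeat unit", call. = FALSE)
  sum(chars == "G") / length(chars)
}

#' Total nucleotides incorporated from product radioactivity
#'
#' Product cpm are converted to dpm, divided by the dGTP pool specific
#' radioactivity to give pmol of dGMP incorporated, and scaled by the inverse
#' dG fraction of the repeat to give total nucleotides. The asymptotic repeat
#' composition is used (products of two or more repeats make the error from
#' the permuted first repeat negligible).
#'
#' @param cpm Product radioactivity in cpm, from [product_cpm()].
#' @param pool A [dgtp_pool()] object.
#' @param repeat_unit Repeat sequence for the dG fraction.
#' @param counting_efficiency Scintillation counting efficiency in (0, 1].
#' @param elapsed_days,half_life_days Optional 32P decay correction back to
#'   the labeling reference date; disabled at `elapsed_days = 0`.
#' @return Total nucleotides incorporated, in pmol of nucleotide.
#' @export
nucleotides_incorporated <- function(cpm, pool, repeat_unit = "TTAGGG",
                                     counting_efficiency = 1,
                                     elapsed_days = 0, half_life_days = 14.26) {
  stopifnot(inherits(pool, "dgtp_pool"))
  if (pool$sa_dpm_per_pmol <= 0)
    stop("pool has zero specific radioactivity; products cannot be quantified",
         call. = FALSE)
  fg <- g_fraction(repeat_unit)
  if (fg == 0) stop("repeat unit contains no G: no label is incorporated", call. = FALSE)
  dpm <- cpm_to_dpm(cpm, counting_efficiency) *
    decay_factor(elapsed_days, half_life_days)
  dgmp_pmol <- dpm / pool$sa_dpm_per_pmol
  dgmp_pmol / fg
}

#' Enzyme specific activity from total nucleotides incorporated
#'
#' @param total_nt_pmol Total nucleotides incorporated (pmol), from
#'   [nucleotides_incorporated()].
#' @param n_telomerase Number of telomerase monomers in the reaction (the
#'   number of eluted hTR molecules assayed serves as the proxy).
#' @param duration_min Reaction time in minutes.
#' @return Nucleotides incorporated per telomerase monomer per minute.
#' @export
enzyme_specific_activity <- function(total_nt_pmol, n_telomerase, duration_min) {
  if (any(n_telomerase <= 0)) stop("`n_telomerase` must be positive", call. = FALSE)
  if (any(duration_min <= 0)) stop("`duration_min` must be positive", call. = FALSE)
  if (any(total_nt_pmol < 0)) stop("`total_nt_pmol` must be non-negative", call. = FALSE)
  total_nt_pmol * 1e-12 * AVOGADRO / n_telomerase / duration_min
}

#' Quantify a direct assay from a gel table
#'
#' End-to-end per-assay quantification: product cpm via the loading control,
#' nucleotides incorporated via the dGTP pool, and specific activity per
#' telomerase monomer. The fraction of the elution assayed cancels between
#' products and enzyme count when `n_telomerase` refers to the assayed
#' aliquot; when it refers to the whole elution, supply `fraction_assayed`.
#'
#' @param gel Data frame with columns `assay_id,products_signal,lc_signal,
#'   lc_cpm,lc_band_fraction,n_telomerase,fraction_assayed,duration_min`.
#' @param recipe An [assay_recipe()] shared by all assays.
#' @return Data frame with `product_cpm`, `nt_pmol` and
#'   `specific_activity_nt_min` per assay, plus a `summary` attribute with
#'   the across-assay mean and SD of the specific activity.
#' @export
quantify_direct_assay <- function(gel, recipe = assay_recipe()) {
  pool <- dgtp_pool(recipe)
  lbf <- if ("lc_band_fraction" %in% names(gel)) gel$lc_band_fraction else 0.9
  fa <- if ("fraction_assayed" %in% names(gel)) gel$fraction_assayed else 1
  cpm <- product_cpm(gel$products_signal, gel$lc_signal, gel$lc_cpm, lbf)
  nt <- nucleotides_incorporated(cpm, pool, recipe$repeat_unit)
  sa <- enzyme_specific_activity(nt, gel$n_telomerase * fa, gel$duration_min)
  out <- data.frame(assay_id = gel$assay_id, product_cpm = cpm, nt_pmol = nt,
                    specific_activity_nt_min = sa, stringsAsFactors = FALSE)
  attr(out, "summary") <- replicate_summary(sa)
  out
}

#' Origin-forced linearity check for validation series
#'
#' Fits `y = b x` through the origin and reports the maximum relative
#' residual. Time courses and enzyme titrations should be linear; saturation
#' or outliers show up as points whose deviation from the fitted line exceeds
#' the threshold.
#'
#' @param x Abscissa (time in minutes, or enzyme amount).
#' @param y Total nucleotides incorporated (or any linear response).
#' @param threshold Maximum tolerated relative deviation (default 0.15).
#' @return List with `slope`, `max_rel_deviation`, `pass`, and the indices of
#'   `flagged_points`.
#' @export
linearity_check <- function(x, y, threshold = 0.15) {
  if (length(x) != length(y)) stop("inputs must have the same length", call. = FALSE)
  if (length(x) < 3L) stop("at least 3 points are required", call. = FALSE)
  fit <- stats::lm(y ~ 0 + x)
  pred <- stats::fitted(fit)
  rel <- ifelse(pred != 0, abs(y - pred) / abs(pred), abs(y))
  list(slope = unname(stats::coef(fit)[1]),
       max_rel_deviation = max(rel),
       pass = max(rel) <= threshold,
       flagged_points = which(rel > threshold))
}

#' Fold change in activity between two conditions
#'
#' @param a,b Mean activities (per cell-equivalent) of the reference and the
#'   comparison condition; `a` must be positive.
#' @param sd_a,sd_b Replicate SDs, for first-order (delta-method) propagation.
#' @return List with `fold` (= b/a) and `sd`.
#' @examples
#' fold_change_activity(10, 20, 1, 2) # 2.0 +/- 0.28
#' @export
fold_change_activity <- function(a, b, sd_a = 0, sd_b = 0) {
  if (any(a <= 0)) stop("reference activity must be positive", call. = FALSE)
  fold <- b / a
  list(fold = fold, sd = abs(fold) * sqrt((sd_a / a)^2 + (sd_b / b)^2))
}

#' Read a direct-assay gel quantification table
#'
#' @param path CSV with columns `assay_id,products_signal,lc_signal,lc_cpm,
#'   lc_band_fraction,n_telomerase,fraction_assayed,duration_min`.
#' @return Data frame.
#' @export
read_gel_quantification <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("assay_id", "products_signal", "lc_signal", "lc_cpm",
            "n_telomerase", "duration_min")
  if (!all(need %in% names(df)))
    stop("gel table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  df
}
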