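#' Depletion ratios from an hTERT immunoprecipitation
#'
#' Flow-through/input ratios for telomerase activity and for hTR. The
#' activity ratio must be strictly below 1 for the mass-balance estimator to
#' be defined. Ratios may be given directly or computed with
#' [ratio_from_measurements()].
#'
#' @param r_act Telomerase activity flow-through/input ratio in \[0, 1).
#' @param r_htr hTR flow-through/input ratio in \[0, 1\].
#' @return Object of class `depletion_ratios`.
#' @export
depletion_ratios <- function(r_act, r_htr) {
  if (any(r_act < 0 | r_act > 1) || any(r_htr < 0 | r_htr > 1))
    stop("depletion ratios must lie in [0, 1]", call. = FALSE)
  structure(list(r_act = r_act, r_htr = r_htr), class = "depletion_ratios")
}

#' @rdname depletion_ratios
#' @param input,flow_through Paired measurements of the same species in the
#'   same units and normalization (e.g. activity per cell-equivalent).
#' @export
ratio_from_measurements <- function(input, flow_through) {
  if (any(input <= 0)) stop("input measurements must be positive", call. = FALSE)
  if (any(flow_through < 0)) stop("flow-through measurements must be non-negative", call. = FALSE)
  flow_through / input
}

#' Assembled telomerase monomers per cell from IP depletion
#'
#' The central mass-balance estimator: the fraction of hTR depleted from the
#' lysate by an hTERT pull-down, relative to the fraction of telomerase
#' activity depleted, is the fraction of hTR assembled into active RNP.
#' Multiplied by the total hTR copies per cell it gives assembled monomers
#' per cell:
#'
#' `N_RNP = n_htr * (1 - r_htr) / (1 - r_act)`
#'
#' Because both ratios are measured on the same pull-down, the absolute IP
#' efficiency cancels. When `r_htr < r_act` the implied assembled fraction
#' exceeds 1 (possible under measurement noise); the value is returned with
#' an attribute flag rather than an error.
#'
#' @param n_htr Total hTR molecules per cell.
#' @param ratios A [depletion_ratios()] object, or `r_act` directly.
#' @param r_htr hTR ratio when `ratios` is given as a number.
#' @return Assembled telomerase monomers per cell, with attribute
#'   `fraction_gt_1` flagging estimates whose assembled fraction exceeds 1.
#' @examples
#' assembled_monomers_per_cell(800, depletion_ratios(0.48, 0.84)) # ~246
#' @export
assembled_monomers_per_cell <- function(n_htr, ratios, r_htr = NULL) {
  if (inherits(ratios, "depletion_ratios")) {
    r_act <- ratios$r_act; r_htr <- ratios$r_htr
  } else {
    r_act <- ratios
    if (is.null(r_htr)) stop("supply `r_htr` when `ratios` is numeric", call. = FALSE)
  }
  if (any(n_htr <= 0)) stop("`n_htr` must be positive", call. = FALSE)
  if (any(r_act >= 1))
    stop("activity ratio of 1 means no activity was depleted; estimator undefined",
         call. = FALSE)
  out <- n_htr * (1 - r_htr) / (1 - r_act)
  flag <- r_htr < r_act
  if (any(flag))
    warning("hTR depleted more than activity: implied assembled fraction > 1")
  attr(out, "fraction_gt_1") <- flag
  out
}

#' Total hTERT per cell from elution stoichiometry
#'
#' In the IP elution every hTR molecule marks one telomerase monomer, while
#' the eluted hTERT includes every form the antibody captured. Assuming equal
#' capture of all hTERT forms, the elution hTERT:hTR molar ratio equals the
#' cellular total-hTERT:RNP ratio, so
#'
#' `N_hTERT = n_rnp * htert_per_ul / htr_per_ul`
#'
#' Any common rescaling of the two elution concentrations cancels.
#'
#' @param n_rnp Assembled telomerase monomers per cell.
#' @param htr_per_ul,htert_per_ul Elution concentrations (molecules/ul).
#' @return hTERT molecules per cell.
#' @examples
#' tert_per_cell(146, 9.2e6, 15e6) # ~238
#' @export
tert_per_cell <- function(n_rnp, htr_per_ul, htert_per_ul) {
  if (any(htr_per_ul <= 0)) stop("`htr_per_ul` must be positive", call. = FALSE)
  if (any(htert_per_ul < 0)) stop("`htert_per_ul` must be non-negative", call. = FALSE)
  if (any(n_rnp < 0)) stop("`n_rnp` must be non-negative", call. = FALSE)
  n_rnp * htert_per_ul / htr_per_ul
}

#' Mean and sample SD across biological replicates
#'
#' @param values Numeric vector of per-replicate estimates.
#' @return List with `mean`, `sd` (sample SD, n-1; NA and flagged for a
#'   singleton) and `n`.
#' @examples
#' replicate_summary(c(146, 245, 332)) # ~241 +/- 93
#' @export
replicate_summary <- function(values) {
  if (length(values) == 0L) stop("empty replicate list", call. = FALSE)
  list(mean = mean(values),
       sd = if (length(values) >= 2L) stats::sd(values) else NA_real_,
       n = length(values),
       sd_defined = length(values) >= 2L)
}

#' Delta-method standard error for the assembled-monomer estimator
#'
#' First-order propagation of per-ratio standard errors through
#' `N = n_htr (1 - r_htr)/(1 - r_act)`, for single-replicate datasets where a
#' replicate SD is unavailable.
#'
#' @param n_htr,r_act,r_htr Point estimates.
#' @param se_n_htr,se_r_act,se_r_htr Standard errors (0 if omitted).
#' @return Standard error of the assembled-monomer estimate.
#' @export
assembled_monomers_se <- function(n_htr, r_act, r_htr,
                                  se_n_htr = 0, se_r_act = 0, se_r_htr = 0) {
  n <- assembled_monomers_per_cell(n_htr, r_act, r_htr = r_htr)
  d_n <- (1 - r_htr) / (1 - r_act)
  d_rhtr <- -n_htr / (1 - r_act)
  d_ract <- n_htr * (1 - r_htr) / (1 - r_act)^2
  sqrt((d_n * se_n_htr)^2 + (d_rhtr * se_r_htr)^2 + (d_ract * se_r_act)^2)
}

#' Assemble a per-cell inventory of telomerase components
#'
#' Derives the free (non-RNP) pools from the totals and the assembled count.
#' Free pools are floored at zero (with a flag) when the assembled estimate
#' exceeds a total, which can happen under measurement noise. The dimer count
#' is simply half the monomer count, for the scenario in which the active
#' enzyme is a dimer.
#'
#' @param n_htr,n_htert,n_rnp Per-cell totals of hTR and hTERT, and assembled
#'   RNP monomers. All non-negative.
#' @return Object of class `cell_inventory`.
#' @examples
#' build_inventory(1300, 500, 240)
#' @export
build_inventory <- function(n_htr, n_htert, n_rnp) {
  if (any(c(n_htr, n_htert, n_rnp) < 0))
    stop("inventory counts must be non-negative", call. = FALSE)
  flags <- character(0)
  if (n_rnp > n_htr) flags <- c(flags, "rnp_exceeds_htr")
  if (n_rnp > n_htert) flags <- c(flags, "rnp_exceeds_htert")
  structure(
    list(hTR_per_cell = n_htr, hTERT_per_cell = n_htert,
         rnp_monomers_per_cell = n_rnp,
         rnp_dimers_per_cell = n_rnp / 2,
         free_hTR = max(n_htr - n_rnp, 0),
         free_hTERT = max(n_htert - n_rnp, 0),
         flags = flags),
    class = "cell_inventory")
}

#' @export
print.cell_inventory <- function(x, ...) {
  cat("Per-cell telomerase inventory\n")
  cat(sprintf("  hTR total:        %8.0f\n", x$hTR_per_cell))
  cat(sprintf("  hTERT total:      %8.0f\n", x$hTERT_per_cell))
  cat(sprintf("  RNP monomers:     %8.0f  (dimers: %.0f)\n",
              x$rnp_monomers_per_cell, x$rnp_dimers_per_cell))
  cat(sprintf("  free hTR:         %8.0f\n", x$free_hTR))
  cat(sprintf("  free hTERT:       %8.0f\n", x$free_hTERT))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Read an IP inventory table
#'
#' @param path CSV with columns `experiment_id,cell_line,replicate,
#'   n_htr_per_cell,r_act,r_htr,htr_per_ul_elution,htert_per_ul_elution`
#'   (elution columns optional / may be NA).
#' @return Data frame.
#' @export
read_ip_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_line", "replicate", "n_htr_per_cell", "r_act", "r_htr")
  if (!all(need %in% names(df)))
    stop("IP table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  df
}

#' Per-cell-line inventory estimates from an IP table
#'
#' Applies [assembled_monomers_per_cell()] per replicate, then
#' [tert_per_cell()] where elution concentrations are available, and
#' summarizes each cell line with mean and sample SD.
#'
#' @param df Data frame as from [read_ip_table()].
#' @param use_reported_rnp Optional column name holding externally determined
#'   assembled-monomer counts to use as the input to [tert_per_cell()]
#'   instead of the counts computed from the ratios (e.g. when the table's
#'   assembled counts were derived from unrounded ratios).
#' @return List with a per-replicate data frame `replicates` and a per-line
#'   list `summary` of `rnp` and `htert` mean/sd.
#' @export
quantify_ip <- function(df, use_reported_rnp = NULL) {
  rnp <- suppressWarnings(
    assembled_monomers_per_cell(df$n_htr_per_cell,
                                df$r_act, r_htr = df$r_htr))
  rnp_for_tert <- if (!is.null(use_reported_rnp)) df[[use_reported_rnp]] else rnp
  has_elu <- all(c("htr_per_ul_elution", "htert_per_ul_elution") %in% names(df))
  htert <- if (has_elu) {
    ok <- !is.na(df$htr_per_ul_elution) & !is.na(df$htert_per_ul_elution)
    out <- rep(NA_real_, nrow(df))
    out[ok] <- tert_per_cell(rnp_for_tert[ok], df$htr_per_ul_elution[ok],
                             df$htert_per_ul_elution[ok])
    out
  } else rep(NA_real_, nrow(df))
  reps <- data.frame(cell_line = df$cell_line, replicate = df$replicate,
                     rnp_per_cell = as.numeric(rnp), htert_per_cell = htert,
                     fraction_gt_1 = attr(rnp, "fraction_gt_1"),
                     stringsAsFactors = FALSE)
  summ <- lapply(split(reps, reps$cell_line), function(d)
    list(rnp = replicate_summary(d$rnp_per_cell),
         htert = if (any(!is.na(d$htert_per_cell)))
           replicate_summary(d$htert_per_cell[!is.na(d$htert_per_cell)]) else NULL))
  list(replicates = reps, summary = summ)
}

#' Benchmark IP depletion dataset
#'
#' Published benchmark measurements of hTERT immunoprecipitation depletion in
#' HEK 293T and HeLa cells (three biological replicates per line): activity
#' and hTR flow-through/input ratios, the hTR copies per cell used for the
#' mass balance (800 and 1300 respectively), and elution concentrations of
#' hTR and hTERT. The `reported_*` columns carry the originally reported
#' per-replicate estimates, which derive from unrounded ratios and therefore
#' differ by a few percent from what the rounded ratios reproduce.
#'
#' @return Data frame in the [read_ip_table()] schema.
#' @export
ip_benchmark <- function() {
  read_ip_table(system.file("extdata", "ip_depletion_benchmark.csv",
                            package = "rnpinventory", mustWork = TRUE))
}
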