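#' Describe an in vitro translation reaction for 35S labeling
#'
#' Captures the methionine bookkeeping of a coupled transcription/translation
#' reaction supplemented with both cold methionine and 35S-methionine. The
#' defaults correspond to a 500 ul reaction supplemented with 10 ul of 1.0 mM
#' cold Met and 10 ul of a 35S-Met stock of 1 mCi in 98 ul at 1175 Ci/mmol.
#'
#' @param hot_met_volume_ul Volume of the hot Met stock added (ul).
#' @param hot_met_stock_activity_mci Total activity of the hot stock (mCi).
#' @param hot_met_stock_volume_ul Volume of the hot stock (ul).
#' @param hot_met_specific_activity_ci_per_mmol Stock specific activity.
#' @param cold_met_volume_ul Volume of the cold Met solution added (ul).
#' @param cold_met_conc_mm Concentration of the cold Met solution (mM).
#' @param total_volume_ul Total reaction volume (ul).
#' @return Object of class `translation_reaction`.
#' @export
translation_reaction <- function(hot_met_volume_ul = 10,
                                 hot_met_stock_activity_mci = 1,
                                 hot_met_stock_volume_ul = 98,
                                 hot_met_specific_activity_ci_per_mmol = 1175,
                                 cold_met_volume_ul = 10,
                                 cold_met_conc_mm = 1.0,
                                 total_volume_ul = 500) {
  vals <- c(hot_met_volume_ul, hot_met_stock_activity_mci,
            hot_met_stock_volume_ul, hot_met_specific_activity_ci_per_mmol,
            total_volume_ul)
  if (any(vals <= 0)) stop("reaction volumes and activities must be positive", call. = FALSE)
  if (cold_met_volume_ul < 0 || cold_met_conc_mm < 0)
    stop("cold methionine amounts must be non-negative", call. = FALSE)
  structure(
    list(hot_met_volume_ul = hot_met_volume_ul,
         hot_met_stock_activity_mci = hot_met_stock_activity_mci,
         hot_met_stock_volume_ul = hot_met_stock_volume_ul,
         hot_met_specific_activity_ci_per_mmol = hot_met_specific_activity_ci_per_mmol,
         cold_met_volume_ul = cold_met_volume_ul,
         cold_met_conc_mm = cold_met_conc_mm,
         total_volume_ul = total_volume_ul),
    class = "translation_reaction")
}

#' Specific radioactivity of the methionine pool
#'
#' The hot Met aliquot contributes `activity / specific activity` moles and
#' all of the activity; the cold Met solution contributes `volume x
#' concentration` moles. Endogenous lysate methionine is ignored by default
#' (it is negligible next to the supplemented pool) but can be supplied as an
#' additive cold term to probe that assumption.
#'
#' @param rxn A [translation_reaction()].
#' @param endogenous_met_pmol Additional unlabeled Met in the reaction (pmol).
#' @return List of class `met_pool`: `hot_pmol`, `cold_pmol`, `total_dpm`,
#'   `sa_dpm_per_pmol`.
#' @examples
#' met_pool_specific_activity(translation_reaction()) # ~2.25e4 dpm/pmol
#' @export
met_pool_specific_activity <- function(rxn, endogenous_met_pmol = 0) {
  stopifnot(inherits(rxn, "translation_reaction"))
  hot_uci <- rxn$hot_met_stock_activity_mci * 1000 /
    rxn$hot_met_stock_volume_ul * rxn$hot_met_volume_ul
  hot_pmol <- activity_to_pmol(hot_uci, rxn$hot_met_specific_activity_ci_per_mmol)
  cold_pmol <- rxn$cold_met_volume_ul * rxn$cold_met_conc_mm * 1000 +
    endogenous_met_pmol
  total_pmol <- hot_pmol + cold_pmol
  if (total_pmol <= 0) stop("total methionine in the reaction is zero", call. = FALSE)
  total_dpm <- uci_to_dpm(hot_uci)
  structure(
    list(hot_pmol = hot_pmol, cold_pmol = cold_pmol,
         hot_activity_uci = hot_uci, total_dpm = total_dpm,
         sa_dpm_per_pmol = total_dpm / total_pmol),
    class = "met_pool")
}

#' Protein molecules from a scintillation measurement
#'
#' Converts the 35S counts of an immunoprecipitated protein sample into a
#' number of protein molecules: counts are corrected for counting efficiency
#' and for the fraction of total lane radioactivity actually in the protein
#' band, divided by the Met-pool specific radioactivity to give pmol of
#' methionine, divided by the methionines per protein, scaled up from the
#' measured aliquot to the whole preparation, and converted to molecules.
#'
#' @param cpm Measured counts per minute.
#' @param sa_met_dpm_per_pmol Specific radioactivity of the Met pool
#'   (dpm/pmol), from [met_pool_specific_activity()].
#' @param met_per_protein Number of methionine residues per protein molecule
#'   (>= 1); see [count_methionines()].
#' @param band_purity Fraction of lane radioactivity in the protein band.
#' @param fraction_of_reaction Fraction of the preparation counted.
#' @param counting_efficiency Scintillation counting efficiency in (0, 1].
#' @param elapsed_days,half_life_days Optional decay correction back to the
#'   labeling date (35S half-life 87.4 d); disabled at `elapsed_days = 0`.
#' @return Number of protein molecules in the whole preparation.
#' @export
molecules_from_cpm <- function(cpm, sa_met_dpm_per_pmol, met_per_protein,
                               band_purity = 0.9, fraction_of_reaction = 1,
                               counting_efficiency = 1,
                               elapsed_days = 0, half_life_days = 87.4) {
  if (any(sa_met_dpm_per_pmol <= 0)) stop("`sa_met_dpm_per_pmol` must be positive", call. = FALSE)
  if (any(met_per_protein < 1)) stop("`met_per_protein` must be >= 1", call. = FALSE)
  if (any(band_purity <= 0 | band_purity > 1)) stop("`band_purity` must be in (0, 1]", call. = FALSE)
  if (any(fraction_of_reaction <= 0 | fraction_of_reaction > 1))
    stop("`fraction_of_reaction` must be in (0, 1]", call. = FALSE)
  dpm <- cpm_to_dpm(cpm, counting_efficiency) *
    decay_factor(elapsed_days, half_life_days)
  met_pmol <- dpm * band_purity / sa_met_dpm_per_pmol
  protein_pmol <- met_pmol / met_per_protein / fraction_of_reaction
  protein_pmol * 1e-12 * AVOGADRO
}

#' Count methionine residues in a protein sequence
#'
#' @param fasta Path to a protein FASTA file, or a character vector of amino
#'   acid sequences.
#' @return Named integer vector of Met counts per sequence.
#' @export
count_methionines <- function(fasta) {
  seqs <- if (length(fasta) == 1L && file.exists(fasta)) {
    vapply(seqinr::read.fasta(fasta, seqtype = "AA", as.string = TRUE),
           function(s) toupper(as.character(s)[1]), character(1))
  } else {
    stats::setNames(toupper(fasta),
                    names(fasta) %||% paste0("seq", seq_along(fasta)))
  }
  vapply(seqs, function(s)
    sum(strsplit(s, "")[[1]] == "M"), integer(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibrate a western blot against a counted protein standard
#'
#' Fits a standard curve from lanes loaded with known numbers of standard
#' protein molecules (from [molecules_from_cpm()]) and converts sample-lane
#' signals to molecules per microliter of elution.
#'
#' @param std_molecules Molecules loaded in each standard lane.
#' @param std_signal Net western signal of each standard lane.
#' @param sample_signal Net signals of the elution sample lanes.
#' @param elution_volume_ul Elution volume represented by each sample lane.
#' @param force_origin Passed to [fit_standard_curve()].
#' @return List with the `curve` and a data frame `samples` with `molecules`,
#'   `molecules_per_ul` and `extrapolated`.
#' @export
western_calibration <- function(std_molecules, std_signal, sample_signal,
                                elution_volume_ul, force_origin = TRUE) {
  if (any(elution_volume_ul <= 0))
    stop("`elution_volume_ul` must be positive", call. = FALSE)
  curve <- fit_standard_curve(std_molecules, std_signal, force_origin = force_origin)
  q <- quantify_band(sample_signal, curve)
  if (any(q$molecules == 0)) warning("zero-signal sample lane quantified as 0 molecules")
  list(curve = curve,
       samples = data.frame(molecules = q$molecules,
                            molecules_per_ul = q$molecules / elution_volume_ul,
                            extrapolated = q$extrapolated))
}

#' Read a scintillation measurement table
#'
#' @param path CSV with columns `sample_id,cpm,fraction_of_reaction,
#'   counting_efficiency`.
#' @return Data frame.
#' @export
read_scintillation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "cpm", "fraction_of_reaction")
  if (!all(need %in% names(df)))
    stop("scintillation table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"counting_efficiency" %in% names(df)) df$counting_efficiency <- 1
  df
}
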