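---
title: "Methods: absolute quantification of telomerase components and activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: absolute quantification of telomerase components and activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnpinventory)
```

This vignette explains the models behind each estimator, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical and design choices made where more than
one reasonable option existed.

## The measurement problem

Telomerase is a very low-abundance ribonucleoprotein: a few hundred
assembled enzymes per immortalized human cell, against thousands of copies
of its RNA subunit (hTR) and hundreds of its protein subunit (hTERT).
Absolute counts at this scale cannot come from a single assay. The package
chains five measurement models, each anchored to a physical standard:

1. a spike-in titration for absolute RNA copies per cell,
2. blot densitometry against standard-molecule titrations,
3. radiolabel bookkeeping for a counted protein standard,
4. an IP mass balance for assembled RNP and total hTERT,
5. a radiolabeled primer-extension assay for catalytic activity.

## Spike-in titration RT-qPCR

Quantifying an RNA against an external standard curve run in separate
reactions is vulnerable to matrix effects: primers can anneal
non-specifically to other cDNAs, changing their effective efficiency
between a pure standard and a cellular sample. Titrating the standard
*into* the cellular RNA before reverse transcription removes this class of
artifact, because standard and endogenous molecules then experience
identical chemistry.

For titration point $i$ with $S_i$ standard molecules added, the
reference-normalized quantity of the target in the spiked sample is
proportional to $N + S_i$ and in the matched unspiked sample to $N$, where
$N$ is the endogenous amount per reaction. The calculated ratio

$$R_i = \frac{Q_{\text{spiked},i}}{Q_{\text{unspiked},i}} - 1$$

is therefore $S_i / N$ in expectation, and the through-origin least-squares
line $R = mS$ gives $\hat N = 1/m$. This construction makes the graphical
rule — the standard amount at which $R = 1$ equals the endogenous amount —
exact. An unconstrained intercept is available for diagnostics
(`through_origin = FALSE`), but the origin constraint is the default since
$R = 0$ at $S = 0$ holds by construction.

Choices worth knowing about:

* **Negative ratios are kept.** Under Cq noise, small spikes can yield
  $R_i \le 0$. Truncating them would bias $\hat N$ upward, so they are
  retained and counted in `n_nonpositive_ratio`.
* **Weighting.** Default unweighted; `weighting = "inv_std"` applies $1/S$
  weights, emphasizing the points nearest the $R = 1$ crossing.
* **Replicate QC.** Technical Cq replicates are averaged per sample;
  sample/target combinations whose replicate range exceeds 0.5 cycles are
  flagged (a common qPCR QC convention).
* **Efficiencies.** Per-primer efficiency from its own dilution series
  (`primer_efficiency`, $E = 10^{-1/\text{slope}}$) when available,
  otherwise $E = 2$. The estimator is invariant to the reference gene's
  absolute level; only its stability across the titration matters, and the
  simulator enforces that matched pairs share the same reference level.

## Blot quantification

Standard lanes with known molecule counts define a signal-per-molecule
calibration. The fit is origin-forced by default — zero molecules should
give zero *net* (background-subtracted) signal — with an unconstrained
option. Background subtraction is assumed done upstream in the imaging
software; inputs are net signals. Samples whose signals fall outside the
span of the standard signals are reported with an `extrapolated` flag
rather than suppressed. Where a band runs as a doublet, the two band
signals should be summed per lane before input.

The detection-limit bound converts an assay's limiting mass into an upper
bound on copies per cell: 2 pg of a 451-nt RNA is
`rna_mass_to_molecules(2, rna_species("hTR", 451))` ≈ 8.3 × 10⁶ molecules
(molar mass modeled as $451 \times 320.5 + 159$ Da; the residue mass and
end correction are exposed as parameters), so a blank lane loaded with 10⁶
cells bounds the target below ~8 copies per cell. The transcript length
used for that conversion is the canonical hTR length; it is a parameter,
not a measured quantity.

Internal-control normalization (`control_normalize`) is provided but not
applied by default; the control lane is treated as QC unless the user opts
in.

## The ³⁵S protein standard

The number of protein molecules in a labeled translation is counted
through methionine bookkeeping. The Met pool combines the hot aliquot
(moles = activity / specific activity; with the default recipe,
10 µl of a 1 mCi/98 µl stock at 1175 Ci/mmol is 102.04 µCi ≈ 86.8 pmol)
with the cold supplement (10 µl × 1.0 mM = 10 000 pmol), giving a pool
specific radioactivity of ≈ 2.25 × 10⁴ dpm/pmol. Endogenous lysate
methionine is ignored by default — it is negligible against the
supplemented pool — but an additive term (`endogenous_met_pmol`) lets the
user probe that assumption; at 1% of the supplement it shifts estimates by
less than 1%.

Protein molecules then follow from measured cpm: correct for counting
efficiency (default 1.0, configurable per instrument), multiply by the
fraction of lane radioactivity actually in the protein band (default 0.9),
divide by the pool SA to get pmol of Met, divide by the Met residues per
protein, and scale from the counted aliquot to the whole preparation.
`met_per_protein` has **no default**: it depends on the exact construct,
and `count_methionines()` computes it from a protein FASTA. ³⁵S decay
correction is off by default (87.4-day half-life makes same-week
corrections 1–3%) and available via `elapsed_days`.

## The IP mass balance

The central estimators rest on one idea: ratios measured on the same
pull-down cancel the pull-down efficiency.

If an anti-hTERT IP captures a fraction $\varepsilon$ of assembled RNP,
the activity flow-through/input ratio is $r_{\text{act}} = 1 -
\varepsilon$ and the hTR ratio is $r_{\text{hTR}} = 1 - \varepsilon
N_{\text{RNP}} / N_{\text{hTR}}$, so

$$N_{\text{RNP}} = N_{\text{hTR}}\,
\frac{1 - r_{\text{hTR}}}{1 - r_{\text{act}}}$$

with $\varepsilon$ cancelling exactly. The property-based tests verify
this invariance over $\varepsilon \in \{0.1, \dots, 0.9\}$ on noiseless
simulations. $r_{\text{act}} = 1$ (no activity depleted) leaves the
estimator undefined and is an error; $r_{\text{hTR}} < r_{\text{act}}$
implies an assembled fraction above 1, which noise can produce, and is
reported with a warning flag rather than rejected — the cap at 1 is
applied only in the derived free-pool fields of `build_inventory()`.

For total hTERT, every eluted hTR marks one RNP monomer while eluted
hTERT includes all antibody-captured forms. Under the equal-affinity
assumption,

$$N_{\text{hTERT}} = N_{\text{RNP}}\,
\frac{[\text{hTERT}]_{\text{elution}}}{[\text{hTR}]_{\text{elution}}},$$

invariant to any common rescaling of the elution concentrations. The
simulator's `include_free_tert` switch exposes the assumption: with it
off, only assembled hTERT elutes and the estimator returns
$N_{\text{RNP}}$; with it on (the scenario the estimator assumes), the
estimator returns total hTERT exactly on noiseless data.

Uncertainty is reported as the across-replicate mean ± sample SD, matching
how such experiments are summarized; a first-order delta-method SE
(`assembled_monomers_se`) covers single-replicate datasets.

The packaged benchmark table (`ip_benchmark()`) carries published
depletion ratios and elution concentrations for HEK 293T and HeLa cells at
two-decimal precision. That rounding propagates to about ±6% on
per-replicate reproductions of the originally reported counts (worst case:
800 × 0.06/0.35 = 137 vs a reported 146); the reported means are defined
over the reported per-replicate counts, which reproduce to within 2%.

## Direct-assay activity

The dGTP pool of the default recipe contains 20 µl × 25 µM = 500 pmol cold
plus 30 µCi / 3000 Ci·mmol⁻¹ = 10 pmol labeled dGTP in 50 µl: 10.2 µM
total (conventionally quoted as 10 µM) at a specific radioactivity of
30 × 2.22 × 10⁶ / 510 ≈ 1.31 × 10⁵ dpm/pmol.

Product quantification is scale-free in gel exposure: the products-to-LC
signal ratio times the LC's scintillation-measured cpm (times the 0.9
fraction of LC radioactivity actually in the band) gives product cpm; the
pool SA converts cpm to pmol of dGMP; dividing by the repeat's dG fraction
(0.5 for TTAGGG) gives total nucleotides. The asymptotic repeat
composition is used without correcting for the permuted first repeat on
the primer — for products of two or more repeats the error is under 5%.
³²P decay correction (14.26-day half-life) is off by default and available
via `elapsed_days`.

Specific activity divides total nucleotides by the number of telomerase
monomers in the reaction — for which the number of eluted hTR molecules is
the proxy — and by the duration. It is invariant to the fraction of the
elution assayed, since products and enzymes scale together.
`linearity_check()` validates the regime: time courses and enzyme
titrations should be linear through the origin, with points deviating more
than 15% (configurable) flagged.

## Kinetics

Both a Lineweaver–Burk fit (OLS of $1/v$ on $1/S$; $V_{max} =
1/\text{intercept}$, $K_m = \text{slope}/\text{intercept}$; SDs by the
delta method from the coefficient covariance) and nonlinear least squares
on the untransformed hyperbola (Levenberg–Marquardt, initialized from the
LB estimates, parameter tolerance 10⁻⁸) are provided. They agree exactly
on noiseless data; under heteroscedastic noise the double-reciprocal
transform overweights low-substrate points, which is why the NLS route and
an optional $v^4$ weighting of the LB fit exist. Technical replicates are
averaged before fitting; biological replicates are fitted separately and
pooled as mean ± SD. Data with a non-positive $1/v$ intercept carry no
saturation information and raise an estimation error.

## The synthetic-data generator

Every raw measurement type the pipeline consumes can be generated from a
`ground_truth()`: qPCR well tables ($Cq = \text{baseline} - \log_E
(\text{copies}) + \mathcal N(0, \sigma_{Cq})$, matched pairs sharing cells
and reference level), IP fraction tables (exact conservation, input =
flow-through + bound, before any measurement noise), blot lane tables
(signal $\propto$ molecules with per-gel gain and lognormal noise), direct
assay gels (expected nucleotides through the Michaelis–Menten rate at the
pool concentration, Poisson-distributed counts through the dGTP forward
model), and velocity titrations.

Noise structure: additive Gaussian on Cq (default σ = 0.15 cycles),
multiplicative lognormal on densitometry (default σ = 0.1), Poisson on
scintillation counts. These magnitudes are conventional bench values, all
configurable through `noise_model()`. The equilibrium-assembly model
treats per-cell counts as concentrations in an implicit fixed volume, so
$K_d$ is expressed in molecules per cell; the assembled amount is the
smaller root of $x^2 - (A + B + K_d)x + AB = 0$, computed in the
numerically stable form $2AB / (s + \sqrt{s^2 - 4AB})$.

Scenario presets encode the study conditions: `hek293t_like` (800 hTR,
280 hTERT, 240 RNP per cell), `hela_like` (1150/500/240), `va13_like`
(zero hTR) and `super_telomerase` (hTR ×60, hTERT ×10, assembled pool from
the equilibrium model).

What the simulations do **not** emulate: RNA-extraction losses (which bias
real copy numbers downward), chemiluminescence nonlinearity in westerns,
cross-reacting antibody bands, cell-to-cell heterogeneity, and cell-cycle
variation in expression. Passing recovery tests therefore demonstrate that
the *estimators* are correct under the stated noise structure, not that a
particular wet-lab result is free of systematic error.

## Problem sizes and determinism

Recovery tests use 50–300 simulated experiments per property (200 seeds
for the spike-in and kinetics medians, 300 for interval-coverage checks,
which need a larger Monte Carlo sample because coverage is a tail
statistic), enough that the Monte Carlo error is small relative to each
tolerance. All simulators take an explicit integer seed, and identical
seeds reproduce tables byte for byte; `run_inventory()` reports are
likewise reproducible byte for byte for a fixed config.

## Known limitations

* The estimators assume the depletion ratios come from the *same*
  pull-down; combining ratios across experiments reintroduces the IP
  efficiency.
* Western chemiluminescence is less precise than the radioisotopic
  measurements; hTERT counts inherit that imprecision.
* The alternative reading of the elution stoichiometry — a cross-reacting
  protein inflating apparent lysate hTERT — is handled only through the
  `include_free_tert` simulation switch, not modeled mechanistically.
* The Michaelis–Menten module covers single-substrate (dGTP) kinetics;
  multi-substrate and processivity-resolved kinetics are out of scope.
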