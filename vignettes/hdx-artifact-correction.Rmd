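---
title: "Modeling and correcting exchange artifacts in HDX-MS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and correcting exchange artifacts in HDX-MS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxamend)
library(dplyr)
```

## The problem

Hydrogen–deuterium exchange mass spectrometry (HDX-MS) reports, for each
proteolytic peptide of a protein, the relative fractional uptake (RFU) of
deuterium across a series of isotope exposure times.  The isotope levels
recorded at the detector are not the levels attained in solution: during
quench, digestion and chromatography, peptides lose deuterium back to the
protiated solvent (*back exchange*) and unlabeled amides pick up deuterium
from residual D~2~O in quench buffers (*forward exchange*).  Differential
workflows largely cancel these artifacts, but any *absolute* use of the
data — protection-factor optimization, structure-based simulation, decoy
ranking — requires correction.

With per-peptide controls — `RFU_back`, the measured uptake of a fully
deuterated sample run through the full fluidics path, and `RFU_fwd`, the
uptake of an unlabeled sample quenched into D~2~O-containing buffer — the
two artifacts act as an affine map on each peptide's RFU:

$$\mathrm{RFU_{err}} = \mathrm{RFU} \cdot (\mathrm{RFU_{back}} -
\mathrm{RFU_{fwd}}) + \mathrm{RFU_{fwd}},
\qquad
\mathrm{RFU} = \frac{\mathrm{RFU_{err}} - \mathrm{RFU_{fwd}}}
{\mathrm{RFU_{back}} - \mathrm{RFU_{fwd}}}.$$

`corrupt_rfu()` and `correct_rfu()` implement the pair; they are exact
inverses, and corruption compresses the dynamic range by the factor
`back − fwd`.  The forward direction is how the package *generates*
realistically corrupted synthetic data; the backward direction is the
correction every downstream consumer applies.  Correction output is not
clipped to [0,1] by default, because out-of-range values are a useful
diagnostic of bad controls; the CLI `correct` subcommand clips by default.

## The forward model

Uptake is simulated from per-residue natural-log protection factors
$\ln P_j$ and intrinsic (random-coil) rates $k_{\mathrm{int},j}$ under the
EX2-regime polyexponential model,

$$\mathrm{RFU}(t) = \frac{1}{N}\sum_{j=1}^{N}
\left[1 - \exp\!\left(-\frac{k_{\mathrm{int},j}\,t}{P_j}\right)\right],$$

with the sum running over a peptide's *reporting* residues: prolines carry
no exchangeable amide NH, and the peptide's first residue loses its amide
information on digestion.  Two conventions in this model were genuinely
open and are fixed as follows:

* **Denominator `N`** counts reporting residues only, not the full peptide
  length.  Normalizing by the full length would rescale every RFU by a
  peptide-specific constant; the reporting-residue convention keeps
  `RFU → 1` as `t → ∞`, which is what the two-point control algebra
  assumes.  This choice affects the absolute RFU scale and is therefore
  stated prominently on `peptide_rfu()`.
* **N-terminal exclusion** is "residue 1 always; residue 2 optionally"
  (`exclude_residue2`, default off).  The coil-theory module instead uses a
  spontaneous-loss rule for positions 1–2 of back-exchange predictions,
  where rapid D-to-H conversion of the first two positions is the standard
  assumption.
* The labeling-buffer deuterium fraction defaults to 1.0 and is
  configurable (`d_fraction`).

## Intrinsic rates

`intrinsic_rates()` evaluates sequence-specific random-coil rates in the
poly-DL-alanine reference framework of Bai and co-workers: per-catalysis
reference rates (acid, base, water) plus additive log~10~ side-chain
correction factors for a residue and its preceding neighbor, Arrhenius
scaling of each catalytic term (activation energies 14, 17 and 19
kcal/mol), and a temperature-dependent solvent ion product.  The tables are
vendored as CSV under `inst/extdata/` and can be overridden.  Direction
matters: H-to-D (labeling) and D-to-H (back exchange) use separate
reference constants and solvent ionization scales.  Asp, Glu, His and the
C-terminal carboxyl blend protonated/deprotonated factor variants at the
working pH, so the same machinery serves both pH ~7 labeling and pH 2.5
quench conditions.  A pD glass-electrode offset (+0.4 by default,
configurable) is applied only in the H-to-D direction; whether such a
correction is appropriate for a given instrument workflow is a lab-level
decision, which is why it is exposed rather than hard-coded.

Rates are minimized near pH 2.5–3 — the reason quench works — and the
package tests assert this V-shape, the Arrhenius identity and the locality
of neighbor effects.

## Protection-factor optimization

`optimize_lnp()` inverts peptide-level uptake to per-residue $\ln P$ by
bounded multi-start L-BFGS-B on

$$\sum_{\mathrm{cells}} \left[\mathrm{RFU}_{\mathrm{obs}} -
\mathrm{RFU}_{\mathrm{model}}(\ln P)\right]^2 +
\lambda \sum_i (\ln P_i - \ln P_{i+1})^2,$$

with analytic gradients.  The residue-level problem is under-determined
(more residues than informative constraints), which the first-difference
smoothness prior handles; no residue grouping is used.  The default
$\lambda = 10^{-4}$ was chosen by an L-curve sweep on synthetic fixtures
(recovery R² against the generating profile peaks there across profile
seeds, and the fit is insensitive to measurement noise at that weight).
Because the prior biases the solution wherever the data are strong, the
optimizer *anneals*: the multi-start search runs at full $\lambda$, then the
best solution is polished at $\lambda/10$.  Bounds default to
$\ln P \in [0, 20]$; time points are weighted uniformly (no per-peptide
error model, since none is available at this level).  Fits are
deterministic given `seed`, and peptide row order is irrelevant.

What a fit can and cannot recover: with seven exposure times from 15 s to
8 h and typical pH-7 rates, protections roughly in $\ln P \in [2, 13]$
produce kinetics inside the observable window; residues outside it (fully
exchanged at the first time point, or inert at the last) are constrained
only by the smoothness prior.  Zero-coverage residues are masked with a
warning rather than extrapolated.

## The synthetic error study

`build_error_study()` reproduces, at desk scale, the design used to ask
*how much control error downstream optimization tolerates*:

1. per protein, a smooth random $\ln P$ profile (stationary AR(1) mapped
   into [0, 14], lag-1 autocorrelation 0.9) over a random sequence with
   average globular composition, and an overlapping ~50-peptide map
   (a guaranteed tiling pass plus random peptides);
2. true uptake simulated at 7 times from 15 s to 8 h;
3. per-peptide controls drawn independently from [0,1]-truncated normal
   libraries of 10 000 values — back 0.70 ± 0.08, forward 0.05 ± 0.02 —
   and independence justified by the observed lack of correlation between
   the two control types in experimental pools;
4. corruption to `RFU_err`, then, for every error threshold (2, 5, 10,
   20 percentage points of RFU) and target (back only, forward only, both),
   random-sign absolute offsets injected into the controls and the data
   reconstituted with the modified controls.

"x% RFU" is implemented as an absolute offset of x/100 RFU units (RFU is
already a fraction), with fair-coin signs so the injected error has no net
drift.  At the defaults this yields 3 × (3·4 + 1) = 39 reconstituted
datasets.  `evaluate_study()` fits every dataset and reports
$\Delta R^2 = R^2_{\mathrm{error\,free}} - R^2_{\mathrm{erroneous}}$
against the true profile, as mean ± SD over proteins;
`autoplot()` renders the familiar grouped-bar summary.  The library means
and SDs are package defaults calibrated to the qualitative description of
heavily corrupted data, not fitted to any published histogram.

The generator emulates the *structure* of real experiments (overlapping
digests, realistic control magnitudes, a kinetically observable protection
range) but not several features of real data: no mass-spectral noise model,
no EX1/bimodal exchange, no correlated control errors within a run, and no
peptide-length dependence of back exchange.  Passing the study therefore
demonstrates the machinery's sensitivity to control errors under clean
conditions; it does not certify performance on any particular instrument's
data.

## The MLP corrector

`train_mlp()` learns a map from uncorrected uptake to the two control
targets.  Each peptide is collapsed to a single feature, the population
variance of its RFU time course (`rfu_variance()`), which makes the model
applicable irrespective of the number or spacing of time points.  The
network is a from-scratch feedforward MLP: nine hidden ReLU layers by
default (widths 64-64-48-48-32-32-16-16-8 — the layer count is the
documented default, the widths are a package choice since only "different
unit numbers" is specified), a linear two-unit output (RFU_back, RFU_fwd),
MSE loss, full-batch gradient descent with backpropagated analytic
gradients, 1000 epochs by default.  The variance feature is z-scored with
training-set statistics stored in the model.  Training and validation sets
must not share a protein, so the validation trace measures generalization
to unseen proteins.  Backprop correctness is tested against central finite
differences (≤ 10⁻⁵ relative error), and the whole train/predict/correct
path is bit-reproducible given a seed.

Predictions are clamped to [0,1]; pairs predicted with `back ≤ fwd` are
nudged apart by a minimal gap and counted.  `correct_with_model()` composes
prediction with the two-point correction.  Population (not sample) variance
is used for the feature — the convention chosen where the normalization was
ambiguous — and the variance is the *only* input feature.

## Coil-theory controls

As a physics-based baseline, `predict_back_exchange()` and
`predict_forward_exchange()` integrate each reporting amide's two-state
kinetics along the post-quench timeline: transit through the pepsin column
at ambient temperature, then trapping (180 s default) plus per-peptide
chromatographic retention at 4 °C, all at pH 2.5.  Back exchange decays a
fully deuterated peptide with D-to-H rates, with spontaneous loss at
peptide positions 1–2; forward exchange grows toward the small residual
trap deuterium fraction (0.12% by default) with H-to-D rates.  The
spontaneous-loss rule is applied to back-exchange predictions only: applied
to forward exchange it would break the equilibrium limit
`RFU_fwd → f_D` that the two-state model requires.  Piecewise-exponential
evaluation over the temperature segments is exact for piecewise-constant
rates and is verified against fine-step numerical integration.  Acetonitrile
effects on rates are ignored, retention times are inputs rather than
predictions, and column interactions are out of scope — the known reasons
such calculations underestimate real back exchange.

## Structure-based ranking

`protection_from_structure()` uses the phenomenological two-descriptor
model $\ln P_i = \beta_c N_c(i) + \beta_h N_h(i)$ with heavy-atom contacts
within 6.5 Å of the amide nitrogen (sequence neighbors excluded) and a
geometric N···O hydrogen-bond criterion (2.4 Å) that needs no hydrogens;
$\beta_c = 0.35$, $\beta_h = 2.0$ are the standard parameters of this model
family, all configurable.  `perturb_decoys()` generates toy decoy
ensembles by smooth residue-correlated displacement fields of graded
magnitude (a stand-in for fragment-assembly decoy generators, labeled
synthetic throughout); `backbone_rmsd()` is a direct Kabsch
superposition cross-checked against bio3d; `label_decoys()` applies the
strict 2.5 Å native threshold; and `rank_decoys()` scores each decoy by the
RMSE between its simulated uptake and a reference dataset, summarizing
native/non-native separability by midrank ROC/AUC (cross-checked against
pROC).

## Problem sizes and numerical choices

The test suite and acceptance script run entirely on synthetic data at
these sizes, chosen to exercise the full pipeline in seconds to minutes on
one CPU: error study 3 proteins × 100 residues × 50 peptides × 7 times;
recovery fixtures 80–100 residues; end-to-end benchmark 3 seeds × 200
decoys on a 60-residue helical hairpin with a 30-peptide map; MLP runs of
300–1000 epochs.  Degenerate inputs are handled explicitly: peptides with
no reporting residues raise typed errors; degenerate control pairs
(`back ≤ fwd`) are rejected on input, redrawn during sampling, and
pushed apart with a count when produced by error injection or model
prediction; reference profiles with zero variance make R² an error rather
than a number.

## Known limitations

* The intrinsic-rate correction factors are transcribed from the standard
  literature tables; the package's results are self-consistent, but users
  needing certified absolute rates should supply their own table via the
  `factor_table`/`reference_table` overrides.
* The optimizer is a functional stand-in for dedicated HDX optimization
  servers: trends and orderings are faithful, exact per-dataset ΔR² values
  are algorithm-specific.
* The MLP learns whatever relationship the training controls carry; on the
  synthetic study, where controls are assigned independently of the
  kinetics, it converges to the conditional mean of the control libraries,
  which is exactly what correction then uses.  Richer experimental
  training data would let the same architecture learn peptide-specific
  corrections.
* Decoys are coordinate perturbations, not physically plausible misfolds;
  AUC values on them calibrate the machinery, not the method's real-world
  discrimination power.
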