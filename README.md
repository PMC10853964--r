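# hdxamend

Correction and simulation of back- and forward-exchange artifacts in
hydrogen–deuterium exchange mass spectrometry (HDX-MS) data.

## What problem this solves

HDX-MS measures, per proteolytic peptide, the relative fractional uptake
(RFU) of deuterium across isotope exposure times.  The recorded isotope
levels deviate from the in-solution values: deuterium is lost during quench,
digestion and chromatography (**back exchange**) and gained from residual
D₂O in quench buffers (**forward exchange**).  Differential workflows
tolerate this; absolute downstream processing — residue-level
protection-factor optimization, HDX-guided structure ranking — does not.
With per-peptide controls (RFU_back from a fully deuterated sample,
RFU_fwd from an unlabeled sample quenched in D₂O-containing buffer) the
artifacts form an affine map,

    RFU_err = RFU · (RFU_back − RFU_fwd) + RFU_fwd
    RFU     = (RFU_err − RFU_fwd) / (RFU_back − RFU_fwd)

and the package provides everything around this algebra for people who
develop or evaluate correction strategies:

* a forward simulator of peptide uptake from per-residue protection factors
  under the EX2 polyexponential model
  `RFU(t) = (1/N) Σ_j [1 − exp(−k_int,j · t / P_j)]`;
* sequence- and condition-specific intrinsic amide exchange rates `k_int`
  (poly-DL-alanine reference framework, direction-specific, Arrhenius
  temperature scaling);
* a bounded, smoothness-regularized, multi-start protection-factor
  optimizer with analytic gradients;
* a synthetic error-impact study quantifying how control errors corrupt
  optimization (ΔR² per error threshold and target);
* a from-scratch multilayer perceptron that predicts per-peptide controls
  from the variance of uncorrected uptake (9 hidden ReLU layers, linear
  output, MSE loss, backpropagation);
* random-coil-theory control prediction along the quench/chromatography
  timeline;
* decoy ranking by agreement of structure-derived simulated uptake with a
  reference dataset, with ROC/AUC native-fold classification.

Everything is tibble-in/tibble-out and pipes with dplyr; fitted objects
support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Simulate a 100-residue protein with a 50-peptide map, corrupt it with
sampled controls, correct it back, and recover protection factors:

```r
library(hdxamend)

profile  <- generate_protection_profile(100, seed = 42)
sequence <- paste(profile$aa, collapse = "")
map      <- generate_peptide_map(sequence, 50, seed = 43)
rates    <- intrinsic_rates(sequence)   # pH 7, 20 °C, H -> D
uptake   <- simulate_uptake(map, profile, rates, default_times())

ctl <- assign_controls(map,
                       sample_control_library(10000, "back", seed = 44),
                       sample_control_library(10000, "fwd",  seed = 45),
                       seed = 46)
observed <- apply_controls(uptake, ctl, mode = "corrupt")
uptake_rmse(observed, uptake)
#> [1] 0.2297  # corruption moves the data by ~0.23 RMSE (RFU)

restored <- apply_controls(observed, ctl, mode = "correct")
uptake_rmse(restored, uptake)
#> [1] 5.6e-17  # exact controls invert the corruption to machine precision

fit <- optimize_lnp(restored, rates, reference = profile, seed = 1)
glance(fit)
#> # A tibble: 1 × 5
#>      loss converged r2_vs_reference n_fitted n_residues
#>     <dbl> <lgl>               <dbl>    <int>      <int>
#> 1 0.00269 TRUE                0.908       92        100
```

The fitted profile matches the generating one at R² = 0.91 over the 92
residues that carry an observable amide and peptide coverage
(`autoplot(fit, reference_profile = profile)` overlays the two).

How much do *errors in the controls* cost?  The error study corrupts and
reconstitutes synthetic datasets with mis-measured controls and reports the
drop in optimization accuracy:

```r
study <- build_error_study(seed = 1)      # 3 proteins, 39 datasets
ev <- evaluate_study(study, thresholds = 20, targets = "both", seed = 2)
ev
#> # A tibble: 1 × 5
#>   threshold target mean_dr2 sd_dr2 n_proteins
#>       <dbl> <chr>     <dbl>  <dbl>      <int>
#> 1        20 both      0.820  0.197          3
```

A ±0.20 RFU error in both controls destroys most of the recoverable
residue-level information (mean ΔR² ≈ 0.8); `autoplot(ev)` draws the
threshold-by-target bar summary.

A thin CLI covering simulate / corrupt / correct / controls-coil /
optimize / error-study ships in `inst/cli/hdxamend`.

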