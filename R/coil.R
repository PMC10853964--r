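#' Quench-to-detection timeline for coil-theory control prediction
#'
#' Describes the post-quench history a peptide experiences: transit through
#' the pepsin column at ambient temperature, then trapping and
#' chromatographic separation at the cold temperature, all at quench pH.
#' Back exchange (D to H) proceeds along this whole timeline; forward
#' exchange (H to D) proceeds toward the small residual deuterium fraction
#' left after dilution of the D2O-containing quench buffer.
#'
#' @param trap_time Peptide trapping time in seconds (default 180).
#' @param pepsin_transit Transit time through the pepsin column at ambient
#'   temperature, seconds (scenario values 0, 30, 180; default 0).
#' @param cold_temperature Kelvin (default 277.15, i.e. 4 C).
#' @param ambient_temperature Kelvin (default 295.15).
#' @param ph_quench Quench pH (default 2.5).
#' @param d2o_fraction_trap Average residual D2O fraction during trapping
#'   (default 0.0012, i.e. 0.12%).
#' @param spontaneous_loss Assume instantaneous D-to-H conversion of the
#'   first and second peptide positions in back-exchange predictions
#'   (default `TRUE`).
#' @return A list of class `"quench_timeline"`.
#' @export
quench_timeline <- function(trap_time = 180, pepsin_transit = 0,
                            cold_temperature = 277.15,
                            ambient_temperature = 295.15,
                            ph_quench = 2.5, d2o_fraction_trap = 0.0012,
                            spontaneous_loss = TRUE) {
  stopifnot(trap_time >= 0, pepsin_transit >= 0, cold_temperature > 0,
            ambient_temperature > 0, d2o_fraction_trap >= 0,
            d2o_fraction_trap <= 1)
  structure(list(trap_time = trap_time, pepsin_transit = pepsin_transit,
                 cold_temperature = cold_temperature,
                 ambient_temperature = ambient_temperature,
                 ph_quench = ph_quench,
                 d2o_fraction_trap = d2o_fraction_trap,
                 spontaneous_loss = spontaneous_loss),
            class = "quench_timeline")
}

# Per-residue quench-condition rates (s^-1) for a peptide at one temperature.
# pd correction is off: the quench solvent is essentially protiated.
quench_rates <- function(peptide, direction, temperature, ph) {
  cond <- exchange_conditions(ph_read = ph, temperature = temperature,
                              d2o_fraction = 0, direction = direction,
                              pd_correction = 0)
  suppressWarnings(intrinsic_rates(peptide, cond))$k_int
}

coil_reporters <- function(peptide) {
  aa <- split_sequence(peptide)
  if (length(aa) < 3) {
    abort("peptide shorter than 3 residues has no usable reporters",
          class = "hdx_no_reporter_error")
  }
  which(seq_along(aa) > 1 & aa != "P")
}

#' Predict a peptide's back-exchange control from coil theory
#'
#' Starts from a fully deuterated peptide and decays each reporting amide's
#' deuterium fraction as `exp(-k_DH * t)` piecewise over the timeline
#' segments -- pepsin transit at ambient temperature first, then trapping
#' plus retention at the cold temperature -- with D-to-H intrinsic rates
#' computed at each segment's temperature and the quench pH.  With
#' `spontaneous_loss`, peptide positions 1-2 are set to zero deuterium
#' instantly.  The predicted control is the mean deuterium fraction over
#' reporting residues.
#'
#' @param peptide One-letter peptide sequence (>= 3 residues).
#' @param retention_time Chromatographic retention time in seconds.
#' @param timeline A [quench_timeline()].
#' @return Predicted RFU_back in \[0,1\].
#' @export
predict_back_exchange <- function(peptide, retention_time,
                                  timeline = quench_timeline()) {
  stopifnot(retention_time >= 0)
  rep_idx <- coil_reporters(peptide)
  k_amb <- quench_rates(peptide, "D_to_H", timeline$ambient_temperature,
                        timeline$ph_quench)[rep_idx]
  k_cold <- quench_rates(peptide, "D_to_H", timeline$cold_temperature,
                         timeline$ph_quench)[rep_idx]
  d <- exp(-(k_amb * timeline$pepsin_transit +
               k_cold * (timeline$trap_time + retention_time)))
  if (timeline$spontaneous_loss) d[rep_idx <= 2] <- 0
  mean(d)
}

#' Predict a peptide's forward-exchange control from coil theory
#'
#' Starts protonated; each reporting amide approaches the residual trap
#' deuterium fraction as `f_D * (1 - exp(-k_HD * t))`, evaluated piecewise
#' with the temperature switch between the ambient pepsin transit and the
#' cold trap/retention segments.
#'
#' @inheritParams predict_back_exchange
#' @return Predicted RFU_fwd in \[0, `d2o_fraction_trap`\].
#' @export
predict_forward_exchange <- function(peptide, retention_time,
                                     timeline = quench_timeline()) {
  stopifnot(retention_time >= 0)
  rep_idx <- coil_reporters(peptide)
  f <- timeline$d2o_fraction_trap
  k_amb <- quench_rates(peptide, "H_to_D", timeline$ambient_temperature,
                        timeline$ph_quench)[rep_idx]
  k_cold <- quench_rates(peptide, "H_to_D", timeline$cold_temperature,
                         timeline$ph_quench)[rep_idx]
  d <- f * (1 - exp(-k_amb * timeline$pepsin_transit))
  d <- f + (d - f) * exp(-k_cold * (timeline$trap_time + retention_time))
  mean(d)
}

#' Correct an uptake table with coil-theory controls
#'
#' Predicts both controls for every peptide from its retention time and the
#' quench timeline, then applies the two-point correction.  Peptides whose
#' predicted controls are degenerate (`back <= fwd`) are flagged and left
#' uncorrected with a warning.
#'
#' @param uptake Long uptake tibble.
#' @param retention Tibble with peptide key columns plus `retention_s`.
#' @param timeline A [quench_timeline()].
#' @param clip Clamp corrected RFU to \[0,1\].
#' @return A list with `controls` (provenance `"predicted_coil"`) and
#'   `corrected` (uptake tibble).
#' @export
coil_correct <- function(uptake, retention, timeline = quench_timeline(),
                         clip = FALSE) {
  key <- c("protein", "peptide", "start", "end")
  require_columns(retention, c(key, "retention_s"), "retention table")
  map <- peptide_map(uptake) %>% left_join(retention, by = key)
  if (anyNA(map$retention_s)) {
    abort("retention times missing for some peptides",
          class = "hdx_alignment_error")
  }
  ctl <- map %>%
    mutate(rfu_back = purrr::map2_dbl(.data$peptide, .data$retention_s,
                                      predict_back_exchange,
                                      timeline = timeline),
           rfu_fwd = purrr::map2_dbl(.data$peptide, .data$retention_s,
                                     predict_forward_exchange,
                                     timeline = timeline),
           provenance = "predicted_coil") %>%
    select(all_of(c(key, "rfu_back", "rfu_fwd", "provenance")))
  ok <- ctl$rfu_back > ctl$rfu_fwd
  if (any(!ok)) {
    warn(paste0(sum(!ok), " peptide(s) had degenerate predicted controls ",
                "and were left uncorrected"))
  }
  corrected <- uptake
  if (any(ok)) {
    fixed <- apply_controls(
      dplyr::semi_join(uptake, ctl[ok, key], by = key),
      ctl[ok, ], mode = "correct", clip = clip)
    corrected <- bind_rows(fixed,
                           dplyr::anti_join(uptake, ctl[ok, key], by = key)) %>%
      arrange(.data$protein, .data$start, .data$end, .data$peptide,
              .data$exposure_s)
  }
  list(controls = ctl, corrected = corrected)
}
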