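#' The back/forward-exchange corruption and correction algebra
#'
#' Observed HDX-MS uptake deviates from the in-solution value through back
#' exchange (deuterium lost during quench, digestion and chromatography) and
#' forward exchange (deuterium gained from residual D2O in quench solutions).
#' With per-peptide controls -- `back`, the RFU of a fully deuterated sample
#' run through the full fluidics path, and `fwd`, the RFU of an unlabeled
#' sample quenched in D2O-containing buffer -- the two processes act as an
#' affine map:
#'
#' * corruption: `rfu_err = rfu_true * (back - fwd) + fwd`
#' * correction: `rfu_true = (rfu_err - fwd) / (back - fwd)`
#'
#' The two are exact inverses when no clipping is applied.  Corruption
#' compresses the dynamic range by the factor `back - fwd` and always lands in
#' `[fwd, back]`.
#'
#' @param rfu_true,rfu_err RFU values (vectorized).
#' @param back,fwd Control RFU values with `back > fwd`, both in \[0,1\]
#'   (recycled against the RFU vector).
#' @param clip For `correct_rfu()`: clamp the result to \[0,1\].  Out-of-range
#'   corrected values are diagnostic of bad controls, so the default is
#'   `FALSE`; when clipping, the number of clipped cells is reported in
#'   attribute `"n_clipped"`.
#' @return A numeric vector of RFU values.
#' @examples
#' corrupt_rfu(0.5, back = 0.8, fwd = 0.1)        # 0.45
#' correct_rfu(0.45, back = 0.8, fwd = 0.1)       # 0.5
#' @export
corrupt_rfu <- function(rfu_true, back, fwd) {
  check_controls_scalar(back, fwd)
  rfu_true * (back - fwd) + fwd
}

#' @rdname corrupt_rfu
#' @export
correct_rfu <- function(rfu_err, back, fwd, clip = FALSE) {
  check_controls_scalar(back, fwd)
  out <- (rfu_err - fwd) / (back - fwd)
  if (clip) {
    n_clipped <- sum(out < 0 | out > 1)
    out <- clamp(out)
    attr(out, "n_clipped") <- n_clipped
  }
  out
}

check_controls_scalar <- function(back, fwd) {
  if (any(back <= fwd)) {
    abort("degenerate controls: rfu_back must exceed rfu_fwd",
          class = "hdx_degenerate_controls_error")
  }
  if (any(back < 0 | back > 1 | fwd < 0 | fwd > 1)) {
    abort("controls must lie in [0, 1]", class = "hdx_value_error")
  }
  invisible(NULL)
}

#' Apply per-peptide controls to a whole uptake table
#'
#' Element-wise [corrupt_rfu()] or [correct_rfu()] over every
#' (peptide, time) cell, matching controls to peptides by
#' (`protein`, `peptide`, `start`, `end`).
#'
#' @param uptake A long uptake tibble.
#' @param controls A control tibble covering every peptide of `uptake`.
#' @param mode `"correct"` (default) or `"corrupt"`.
#' @param clip Clamp corrected values to \[0,1\] (ignored for `"corrupt"`).
#' @return An uptake tibble of the same shape; the applied mode and control
#'   provenance are recorded in attributes `"correction"` and `"provenance"`,
#'   and the clipped-cell count in `"n_clipped"` when clipping.
#' @export
apply_controls <- function(uptake, controls, mode = c("correct", "corrupt"),
                           clip = FALSE) {
  mode <- match.arg(mode)
  validate_controls(controls)
  key <- c("protein", "peptide", "start", "end")
  joined <- left_join(uptake, controls[c(key, "rfu_back", "rfu_fwd")], by = key)
  missing <- joined %>% filter(is.na(.data$rfu_back)) %>% distinct(.data$peptide)
  if (nrow(missing) > 0) {
    abort(paste0("no control pair for peptide(s): ",
                 paste(head(missing$peptide, 5), collapse = ", ")),
          class = "hdx_alignment_error")
  }
  n_clipped <- 0L
  out <- joined %>%
    mutate(rfu = if (mode == "corrupt") {
      corrupt_rfu(.data$rfu, .data$rfu_back, .data$rfu_fwd)
    } else {
      (.data$rfu - .data$rfu_fwd) / (.data$rfu_back - .data$rfu_fwd)
    })
  check_controls_scalar(joined$rfu_back, joined$rfu_fwd)
  if (mode == "correct" && clip) {
    n_clipped <- sum(out$rfu < 0 | out$rfu > 1)
    out$rfu <- clamp(out$rfu)
  }
  out <- out %>% select(all_of(uptake_cols))
  attr(out, "correction") <- mode
  attr(out, "provenance") <- if ("provenance" %in% names(controls)) {
    unique(controls$provenance)
  }
  attr(out, "n_clipped") <- n_clipped
  out
}
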