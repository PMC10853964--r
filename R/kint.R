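#' Exchange conditions for intrinsic-rate calculation
#'
#' Bundles the solution conditions under which sequence-specific intrinsic
#' amide exchange rates are evaluated.
#'
#' `ph_read` is the uncorrected glass-electrode reading.  For the H-to-D
#' direction (exchange into D2O) a pD correction offset (`pd_correction`,
#' default +0.4) is added to the reading; for D-to-H (back exchange into
#' protiated solvent) the reading is used as is.
#'
#' @param ph_read pH meter reading.
#' @param temperature Kelvin; readings outside 270--320 K trigger an
#'   extrapolation warning when rates are computed.
#' @param d2o_fraction Deuterium fraction of the solvent, in \[0,1\].
#' @param direction `"H_to_D"` (labeling) or `"D_to_H"` (back exchange).
#' @param pd_correction Offset added to `ph_read` in the H-to-D direction.
#' @return A list of class `"exchange_conditions"`.
#' @export
exchange_conditions <- function(ph_read = 7, temperature = 293.15,
                                d2o_fraction = 1, direction = c("H_to_D", "D_to_H"),
                                pd_correction = 0.4) {
  direction <- match.arg(direction)
  stopifnot(temperature > 0, d2o_fraction >= 0, d2o_fraction <= 1)
  structure(list(ph_read = ph_read, temperature = temperature,
                 d2o_fraction = d2o_fraction, direction = direction,
                 pd_correction = pd_correction),
            class = "exchange_conditions")
}

# Load the vendored factor/reference tables, allowing user overrides.
load_factor_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "exchange_sidechain_factors.csv",
                                package = "hdxamend")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

load_reference_rates <- function(path = NULL) {
  path <- path %||% system.file("extdata", "exchange_reference_rates.csv",
                                package = "hdxamend")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Side-chain pKa values used to blend protonation-state variants
# (solvent-specific: glass-electrode-corrected scale for D2O).
SIDECHAIN_PKA <- list(
  H2O = c(D = 3.87, E = 4.33, H = 7.00, CT = 3.55),
  D2O = c(D = 4.48, E = 4.93, H = 7.42, CT = 4.00)
)

GAS_CONSTANT_KCAL <- 1.987e-3  # kcal / mol / K
T_REF <- 293

# Factor lookup for one residue key: named vector c(acid_left, acid_right,
# base_left, base_right), zeros where the table has no entry.
factor_row <- function(tab, key, direction) {
  sel <- tab[tab$residue == key &
               (tab$direction == "both" | tab$direction == direction), ]
  out <- c(acid_left = 0, acid_right = 0, base_left = 0, base_right = 0)
  if (nrow(sel) > 0) {
    nm <- paste(sel$term, sel$side, sep = "_")
    out[nm] <- sel$value
  }
  out
}

# Blend protonated/deprotonated factor variants on the linear (10^F) scale at
# the working pL.  `base` is the one-letter code; returns a factor vector.
blended_factors <- function(tab, aa, pl, pka_set, direction) {
  if (aa %in% c("D", "E", "H")) {
    f_prot <- 1 / (1 + 10^(pl - pka_set[[aa]]))
    fp <- factor_row(tab, paste0(aa, "_prot"), direction)
    fd <- factor_row(tab, paste0(aa, "_deprot"), direction)
    log10(f_prot * 10^fp + (1 - f_prot) * 10^fd)
  } else {
    factor_row(tab, aa, direction)
  }
}

#' Intrinsic amide exchange rates for a sequence
#'
#' Computes per-residue intrinsic (random-coil) amide exchange rate constants
#' `k_int` in s^-1 from the poly-DL-alanine reference framework: a reference
#' rate for acid-, base- and water-catalyzed exchange plus additive log10
#' side-chain correction factors for the residue itself ("left") and its
#' preceding neighbor ("right"), direction-specific reference constants, and
#' Arrhenius scaling of each catalytic term to the requested temperature.
#' Asp, Glu, His (and the C-terminal carboxyl) blend their protonated and
#' deprotonated factor variants at the working pH.
#'
#' Residue 1 carries no reporting backbone amide and is always masked
#' (`k_int = NA`), as are prolines, which have no exchangeable NH.
#'
#' @param sequence One-letter amino-acid string.
#' @param conditions An [exchange_conditions()] object.
#' @param mask_residue2 Also mask the second residue (used by coil-theory
#'   consumers); default `FALSE`.
#' @param peptide_termini Apply free N-terminal amine and C-terminal carboxyl
#'   neighbor factors (default `TRUE`).
#' @param factor_table,reference_table Optional overrides for the vendored
#'   CSV tables (paths or pre-read data frames).
#' @return A tibble with columns `residue`, `aa`, `k_int` (s^-1; `NA` at
#'   masked positions), carrying the conditions in attribute `"conditions"`.
#' @examples
#' rates <- intrinsic_rates("AKLVP", exchange_conditions(ph_read = 7))
#' rates$k_int[5]  # NA: proline
#' @export
intrinsic_rates <- function(sequence, conditions = exchange_conditions(),
                            mask_residue2 = FALSE, peptide_termini = TRUE,
                            factor_table = NULL, reference_table = NULL) {
  stopifnot(inherits(conditions, "exchange_conditions"))
  aa <- split_sequence(sequence)
  n <- length(aa)
  if (conditions$temperature < 270 || conditions$temperature > 320) {
    warn("temperature outside 270-320 K: extrapolating beyond the calibrated range")
  }
  tab <- if (is.data.frame(factor_table)) factor_table else load_factor_table(factor_table)
  refs <- if (is.data.frame(reference_table)) reference_table else load_reference_rates(reference_table)
  refs <- refs[refs$direction == conditions$direction, ]
  ref <- setNames(refs$log10_k, refs$term)
  ea <- setNames(refs$ea_kcal, refs$term)

  solvent <- if (conditions$direction == "H_to_D") "D2O" else "H2O"
  pka_set <- SIDECHAIN_PKA[[solvent]]
  pl <- conditions$ph_read +
    if (conditions$direction == "H_to_D") conditions$pd_correction else 0
  temp <- conditions$temperature
  arr <- function(term) exp(-ea[[term]] / GAS_CONSTANT_KCAL * (1 / temp - 1 / T_REF))
  pkw <- ref[["pkw"]] + ea[["pkw"]] / (log(10) * GAS_CONSTANT_KCAL) *
    (1 / temp - 1 / T_REF)

  k <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i == 1 || aa[i] == "P") next
    if (i == 2 && mask_residue2) next
    own <- blended_factors(tab, aa[i], pl, pka_set, conditions$direction)
    prev <- blended_factors(tab, aa[i - 1], pl, pka_set, conditions$direction)
    fa <- own[["acid_left"]] + prev[["acid_right"]]
    fb <- own[["base_left"]] + prev[["base_right"]]
    if (peptide_termini) {
      if (i == 2) {
        nt <- factor_row(tab, "NT", conditions$direction)
        fa <- fa + nt[["acid_right"]]
        fb <- fb + nt[["base_right"]]
      }
      if (i == n) {
        f_prot <- 1 / (1 + 10^(pl - pka_set[["CT"]]))
        ctp <- factor_row(tab, "CT_prot", conditions$direction)
        ctd <- factor_row(tab, "CT_deprot", conditions$direction)
        fa <- fa + log10(f_prot * 10^ctp[["acid_left"]] +
                           (1 - f_prot) * 10^ctd[["acid_left"]])
        fb <- fb + log10(f_prot * 10^ctp[["base_left"]] +
                           (1 - f_prot) * 10^ctd[["base_left"]])
      }
    }
    k_acid <- 10^(ref[["acid"]] + fa - pl) * arr("acid")
    k_base <- 10^(ref[["base"]] + fb + pl - pkw) * arr("base")
    k_water <- 10^(ref[["water"]] + fb) * arr("water")
    k[i] <- (k_acid + k_base + k_water) / 60  # tables are per minute
  }
  out <- tibble(residue = seq_len(n), aa = aa, k_int = k)
  attr(out, "conditions") <- conditions
  attr(out, "mask_residue2") <- mask_residue2
  attr(out, "peptide_termini") <- peptide_termini
  attr(out, "sequence") <- paste(aa, collapse = "")
  out
}

#' Recompute a rate set in the opposite exchange direction
#'
#' Swaps the direction of the conditions attached to a rate tibble and
#' recomputes every residue's rate with the other direction's reference
#' constants and solvent ionization.  Because the acid/base catalytic balance
#' differs residue by residue, the result is not a scalar multiple of the
#' input; applying the flip twice restores the original rates.
#'
#' @param rates A tibble produced by [intrinsic_rates()].
#' @return A rate tibble for the opposite direction.
#' @export
flip_direction <- function(rates) {
  cond <- attr(rates, "conditions")
  if (is.null(cond)) abort("rates carry no conditions attribute",
                           class = "hdx_structural_error")
  cond$direction <- if (cond$direction == "H_to_D") "D_to_H" else "H_to_D"
  intrinsic_rates(attr(rates, "sequence"), cond,
                  mask_residue2 = attr(rates, "mask_residue2"),
                  peptide_termini = attr(rates, "peptide_termini"))
}
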