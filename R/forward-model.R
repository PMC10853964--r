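#' Reporting residues of a peptide
#'
#' A peptide position reports exchange when it carries an observable backbone
#' amide: the peptide's first residue never reports (its amide is lost on
#' digestion), prolines never report, residues masked in the supplied profile
#' or rate set do not report, and the second residue can optionally be
#' excluded (the convention used by the coil-theory module).
#'
#' @param start,end 1-based inclusive residue span in the protein.
#' @param masked Logical vector over the whole protein, `TRUE` where a residue
#'   carries no value (e.g. `is.na(profile$lnp)`).
#' @param exclude_residue2 Also drop the peptide's second position.
#' @return Integer vector of protein residue indices that report.
#' @export
reporting_residues <- function(start, end, masked, exclude_residue2 = FALSE) {
  idx <- seq.int(start, end)
  drop_local <- if (exclude_residue2) 1:2 else 1
  idx <- idx[-drop_local]
  idx[!masked[idx]]
}

#' Simulate peptide RFU from protection factors
#'
#' Projects peptide-level relative fractional uptake from per-residue
#' natural-log protection factors and intrinsic rates under the EX2-style
#' polyexponential model: each reporting residue j exchanges with observed
#' rate `k_int[j] / exp(lnp[j])`, and the peptide RFU at exposure time t is
#' the mean deuterium fraction
#' `RFU = (1/N) * sum_j (1 - exp(-k_int[j] * t / P_j))`
#' over its N reporting residues.  Prolines and the peptide's first residue
#' (optionally also the second) are discounted from both the sum and the
#' denominator.
#'
#' @param start,end Peptide span (1-based, inclusive).
#' @param profile Protection-profile tibble (`lnp` with `NA` masks).
#' @param rates Rate tibble from [intrinsic_rates()] aligned to the protein.
#' @param t Exposure time(s) in seconds (vectorized).
#' @param exclude_residue2 Drop the peptide's second position as well.
#' @param d_fraction Deuterium fraction of the labeling buffer (default 1).
#' @return Numeric vector of RFU values, one per element of `t`, each in
#'   \[0, `d_fraction`\].
#' @examples
#' prof <- tibble::tibble(protein = "p", residue = 1:3,
#'                        aa = c("A", "K", "L"), lnp = c(NA, 0, 0))
#' rt <- intrinsic_rates("AKL")
#' peptide_rfu(1, 3, prof, rt, t = 60)
#' @export
peptide_rfu <- function(start, end, profile, rates, t,
                        exclude_residue2 = FALSE, d_fraction = 1) {
  stopifnot(all(t > 0))
  masked <- is.na(profile$lnp) | is.na(rates$k_int)
  idx <- reporting_residues(start, end, masked, exclude_residue2)
  if (length(idx) == 0) {
    abort(paste0("peptide [", start, ", ", end, "] has no reporting residues"),
          class = "hdx_no_reporter_error")
  }
  kobs <- rates$k_int[idx] * exp(-profile$lnp[idx])
  d_fraction * colMeans(1 - exp(-outer(kobs, t)))
}

#' Simulate a full uptake table
#'
#' Applies [peptide_rfu()] to every peptide of a map across an exposure-time
#' grid, producing a long uptake tibble.
#'
#' @param map Peptide-map tibble (`protein`, `peptide`, `start`, `end`).
#' @param profile Protection-profile tibble for the protein.
#' @param rates Rate tibble aligned to the protein.
#' @param times Strictly increasing exposure times in seconds.
#' @param exclude_residue2,d_fraction Passed on to [peptide_rfu()].
#' @return A validated long uptake tibble.
#' @export
simulate_uptake <- function(map, profile, rates, times,
                            exclude_residue2 = FALSE, d_fraction = 1) {
  validate_peptide_map(map)
  stopifnot(length(times) >= 1, all(diff(times) > 0), all(times > 0))
  rows <- purrr::pmap(map[c("protein", "peptide", "start", "end")],
                      function(protein, peptide, start, end) {
    rfu <- tryCatch(
      peptide_rfu(start, end, profile, rates, times,
                  exclude_residue2 = exclude_residue2,
                  d_fraction = d_fraction),
      error = function(e) {
        abort(paste0("peptide ", peptide, " [", start, ", ", end, "]: ",
                     conditionMessage(e)),
              class = "hdx_no_reporter_error")
      })
    tibble(protein = protein, peptide = peptide, start = start, end = end,
           exposure_s = times, rfu = rfu)
  })
  out <- bind_rows(rows) %>%
    arrange(.data$protein, .data$start, .data$end, .data$peptide,
            .data$exposure_s)
  validate_uptake(out)
  out
}
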