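#' Per-peptide and overall RMSE between two uptake tables
#'
#' Measures the root-mean-square difference in RFU between two uptake tables
#' over a shared peptide map and exposure-time grid, the standard way of
#' summarising how far, e.g., corrected data sit from uncorrected data.
#'
#' @param a,b Uptake tibbles with identical peptide maps and time grids.
#' @return `compare_uptake()` returns a tibble with one row per peptide
#'   (`protein`, `peptide`, `start`, `end`, `rmse`) and the overall RMSE over
#'   all (peptide, time) cells in attribute `"overall_rmse"`.
#'   `uptake_rmse()` returns the overall RMSE as a bare number.
#' @examples
#' u <- tibble::tibble(protein = "p", peptide = "AKL", start = 1L, end = 3L,
#'                     exposure_s = c(15, 60), rfu = c(0.2, 0.5))
#' v <- dplyr::mutate(u, rfu = rfu + 0.1)
#' uptake_rmse(u, v)  # 0.1
#' @export
compare_uptake <- function(a, b) {
  if (!same_map(a, b)) {
    abort("uptake tables have different peptide maps",
          class = "hdx_structural_error")
  }
  key <- c("protein", "peptide", "start", "end", "exposure_s")
  joined <- dplyr::inner_join(a, b, by = key, suffix = c("_a", "_b"))
  if (nrow(joined) != nrow(a) || nrow(joined) != nrow(b)) {
    abort("uptake tables have different exposure-time grids",
          class = "hdx_structural_error")
  }
  per <- joined %>%
    group_by(.data$protein, .data$peptide, .data$start, .data$end) %>%
    summarise(rmse = sqrt(mean((.data$rfu_a - .data$rfu_b)^2)),
              .groups = "drop")
  attr(per, "overall_rmse") <- sqrt(mean((joined$rfu_a - joined$rfu_b)^2))
  per
}

#' @rdname compare_uptake
#' @export
uptake_rmse <- function(a, b) {
  attr(compare_uptake(a, b), "overall_rmse")
}

#' Coefficient of determination between two per-residue value sets
#'
#' Standard R-squared of `est` against the reference `ref`,
#' `1 - SS_res / SS_tot`, computed over positions where both vectors are
#' non-missing.  Values can be negative (a fit worse than the reference mean);
#' nothing is clipped.
#'
#' @param est,ref Numeric vectors of equal length (e.g. two lnP profiles);
#'   pairs with an `NA` on either side are dropped.
#' @return A single number.
#' @export
r_squared <- function(est, ref) {
  if (length(est) != length(ref)) {
    abort("est and ref must have equal length", class = "hdx_structural_error")
  }
  keep <- !is.na(est) & !is.na(ref)
  est <- est[keep]
  ref <- ref[keep]
  if (length(ref) < 3) {
    abort("need at least 3 commonly unmasked values",
          class = "hdx_structural_error")
  }
  ss_tot <- sum((ref - mean(ref))^2)
  if (ss_tot == 0) {
    abort("reference has zero variance; R-squared is undefined",
          class = "hdx_undefined_r2_error")
  }
  1 - sum((est - ref)^2) / ss_tot
}
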