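#' Tabular data contracts
#'
#' hdxamend works on plain tibbles with fixed column contracts so that every
#' result pipes into dplyr/tidyr directly.  Residue coordinates are 1-based and
#' inclusive throughout, the HDX-MS community convention.
#'
#' * **peptide map**: one row per proteolytic peptide with columns `protein`,
#'   `peptide` (one-letter sequence), `start`, `end`.
#' * **uptake table** (long): peptide-map columns plus `exposure_s` (seconds)
#'   and `rfu` (relative fractional uptake in \[0,1\]; values outside the unit
#'   interval are tolerated only on tables flagged as uncorrected).
#' * **control table**: peptide-map columns plus `rfu_back`, `rfu_fwd` and a
#'   `provenance` column (one of `experimental`, `sampled`, `predicted_coil`,
#'   `predicted_ai`); every peptide must satisfy `rfu_back > rfu_fwd`.
#' * **protection profile**: `protein`, `residue`, `aa`, `lnp` with `lnp = NA`
#'   at masked positions (prolines and excluded N-terminal residues).
#'
#' `validate_*()` functions check the contract and return their input
#' invisibly, so they drop into a pipe as assertions.
#'
#' @param map,uptake,controls,profile A data frame to validate.
#' @param protein_sequence Optional named character vector of full protein
#'   sequences (names are protein ids).  When supplied, every peptide substring
#'   is checked against its protein.
#' @param allow_out_of_range For uptake tables: permit RFU outside \[0,1\]
#'   (uncorrected/erroneous data); values must still lie in \[-0.5, 1.5\].
#' @return The validated input, invisibly.
#' @name hdx-contracts
NULL

uptake_cols <- c("protein", "peptide", "start", "end", "exposure_s", "rfu")
control_cols <- c("protein", "peptide", "start", "end", "rfu_back", "rfu_fwd")

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(what, " is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "hdx_format_error")
  }
}

#' @rdname hdx-contracts
#' @export
validate_peptide_map <- function(map, protein_sequence = NULL) {
  require_columns(map, c("protein", "peptide", "start", "end"), "peptide map")
  if (nrow(map) < 1) abort("peptide map has no peptides",
                           class = "hdx_structural_error")
  bad <- which(map$end < map$start)
  if (length(bad) > 0) {
    abort(paste0("end < start for peptide row(s): ",
                 paste(bad, collapse = ", ")),
          class = "hdx_structural_error")
  }
  bad <- which(nchar(map$peptide) != map$end - map$start + 1L)
  if (length(bad) > 0) {
    abort(paste0("sequence length disagrees with [start, end] for row(s): ",
                 paste(bad, collapse = ", ")),
          class = "hdx_structural_error")
  }
  purrr::walk(map$peptide, split_sequence)
  if (!is.null(protein_sequence)) {
    for (i in seq_len(nrow(map))) {
      full <- protein_sequence[[map$protein[i]]]
      frag <- substr(full, map$start[i], map$end[i])
      if (!identical(frag, map$peptide[i])) {
        abort(paste0("peptide row ", i, " (", map$peptide[i],
                     ") does not match protein ", map$protein[i],
                     " at [", map$start[i], ", ", map$end[i], "]"),
              class = "hdx_structural_error")
      }
    }
  }
  invisible(map)
}

#' @rdname hdx-contracts
#' @export
validate_uptake <- function(uptake, protein_sequence = NULL,
                            allow_out_of_range = FALSE) {
  require_columns(uptake, uptake_cols, "uptake table")
  validate_peptide_map(peptide_map(uptake), protein_sequence)
  if (any(uptake$exposure_s <= 0)) {
    abort("exposure times must be > 0 seconds", class = "hdx_structural_error")
  }
  lim <- if (allow_out_of_range) c(-0.5, 1.5) else c(0, 1)
  bad <- which(uptake$rfu < lim[1] | uptake$rfu > lim[2] | !is.finite(uptake$rfu))
  if (length(bad) > 0) {
    abort(paste0("RFU outside [", lim[1], ", ", lim[2], "] at row(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "hdx_value_error")
  }
  grids <- uptake %>%
    group_by(.data$protein, .data$peptide, .data$start, .data$end) %>%
    summarise(grid = paste(sort(.data$exposure_s), collapse = ","),
              .groups = "drop")
  per_protein <- grids %>%
    group_by(.data$protein) %>%
    summarise(n_grids = dplyr::n_distinct(.data$grid), .groups = "drop")
  if (any(per_protein$n_grids > 1)) {
    abort("peptides within a protein have inconsistent exposure-time grids",
          class = "hdx_structural_error")
  }
  invisible(uptake)
}

#' @rdname hdx-contracts
#' @export
validate_controls <- function(controls, protein_sequence = NULL) {
  require_columns(controls, control_cols, "control table")
  validate_peptide_map(peptide_map(controls), protein_sequence)
  if (anyDuplicated(controls[c("protein", "peptide", "start", "end")]) > 0) {
    abort("control table has more than one row for a peptide",
          class = "hdx_structural_error")
  }
  rng_bad <- with(controls, rfu_back < 0 | rfu_back > 1 | rfu_fwd < 0 | rfu_fwd > 1)
  if (any(rng_bad)) {
    abort("control RFU values must lie in [0, 1]", class = "hdx_value_error")
  }
  if (any(controls$rfu_back <= controls$rfu_fwd)) {
    abort("rfu_back must exceed rfu_fwd for every peptide",
          class = "hdx_degenerate_controls_error")
  }
  if ("provenance" %in% names(controls)) {
    ok <- c("experimental", "sampled", "predicted_coil", "predicted_ai")
    if (!all(controls$provenance %in% ok)) {
      abort(paste0("provenance must be one of: ", paste(ok, collapse = ", ")),
            class = "hdx_value_error")
    }
  }
  invisible(controls)
}

#' @rdname hdx-contracts
#' @export
validate_profile <- function(profile) {
  require_columns(profile, c("protein", "residue", "aa", "lnp"),
                  "protection profile")
  if (!identical(profile$residue, seq_len(nrow(profile)))) {
    abort("profile residues must run 1..protein length",
          class = "hdx_structural_error")
  }
  if (any(profile$aa == "P" & !is.na(profile$lnp))) {
    abort("prolines must be masked (lnp = NA)", class = "hdx_structural_error")
  }
  if (any(profile$lnp < 0, na.rm = TRUE)) {
    abort("lnp must be >= 0 for unmasked residues", class = "hdx_value_error")
  }
  invisible(profile)
}

#' Extract the peptide map of an uptake or control table
#'
#' @param x A data frame carrying `protein`, `peptide`, `start`, `end` columns
#'   (an uptake table, a control table, or a map itself).
#' @return A tibble with one row per distinct peptide, ordered by protein,
#'   start, end.
#' @export
peptide_map <- function(x) {
  require_columns(x, c("protein", "peptide", "start", "end"), "table")
  x %>%
    distinct(.data$protein, .data$peptide, .data$start, .data$end) %>%
    arrange(.data$protein, .data$start, .data$end, .data$peptide) %>%
    as_tibble()
}

same_map <- function(a, b) {
  ma <- peptide_map(a)
  mb <- peptide_map(b)
  nrow(ma) == nrow(mb) &&
    isTRUE(all.equal(as.list(ma), as.list(mb), check.attributes = FALSE))
}
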