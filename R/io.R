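#' Read and write uptake tables
#'
#' The canonical on-disk dialect is long-format CSV with columns `protein`,
#' `peptide` (or `sequence`), `start`, `end`, `exposure_s`, `rfu`.  A
#' wide-format dialect (one column per exposure time, named `rfu_<seconds>` or
#' bare seconds, configurable via `time_prefix`) is accepted for exports in
#' the style of vendor tools and plain text-file archives; both are normalized
#' to the same long tibble.
#'
#' Reading deduplicates exposure times, merges duplicated
#' (`peptide`,`start`,`end`) rows by averaging their RFU, and validates the
#' result (see [validate_uptake()]).  Round trips through
#' `write_uptake()`/`read_uptake()` are lossless at 6-decimal precision.
#'
#' @param path File path.
#' @param dialect `"long"` (default) or `"wide"`.
#' @param time_prefix For the wide dialect: prefix stripped from exposure-time
#'   column names (default `"rfu_"`; use `""` for bare-second headers).
#' @param allow_out_of_range Permit RFU in \[-0.5, 1.5\] (uncorrected data).
#' @param uptake An uptake tibble.
#' @return `read_uptake()` returns a validated long uptake tibble;
#'   `write_uptake()` returns `path` invisibly.
#' @export
read_uptake <- function(path, dialect = c("long", "wide"), time_prefix = "rfu_",
                        allow_out_of_range = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path),
                                class = "hdx_format_error")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("sequence" %in% names(df) && !"peptide" %in% names(df)) {
    df <- rename(df, peptide = "sequence")
  }
  if (dialect == "wide") {
    id_cols <- c("protein", "peptide", "start", "end")
    require_columns(df, id_cols, "wide uptake table")
    value_cols <- setdiff(names(df), id_cols)
    df <- df %>%
      tidyr::pivot_longer(all_of(value_cols), names_to = "exposure_s",
                          values_to = "rfu") %>%
      mutate(exposure_s = as.numeric(sub(paste0("^", time_prefix), "",
                                         .data$exposure_s)))
    if (anyNA(df$exposure_s)) {
      abort("wide uptake table has exposure columns that do not parse as seconds",
            class = "hdx_format_error")
    }
  }
  require_columns(df, uptake_cols, "uptake table")
  out <- df %>%
    select(all_of(uptake_cols)) %>%
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) %>%
    group_by(.data$protein, .data$peptide, .data$start, .data$end,
             .data$exposure_s) %>%
    summarise(rfu = mean(.data$rfu), .groups = "drop") %>%
    arrange(.data$protein, .data$start, .data$end, .data$peptide,
            .data$exposure_s)
  validate_uptake(out, allow_out_of_range = allow_out_of_range)
  out
}

#' @rdname read_uptake
#' @export
write_uptake <- function(uptake, path, dialect = c("long", "wide"),
                         time_prefix = "rfu_") {
  dialect <- match.arg(dialect)
  out <- uptake %>% mutate(rfu = round(.data$rfu, 6))
  if (dialect == "wide") {
    out <- out %>%
      tidyr::pivot_wider(id_cols = c("protein", "peptide", "start", "end"),
                         names_from = "exposure_s", values_from = "rfu",
                         names_prefix = time_prefix)
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write per-peptide control tables
#'
#' CSV with columns `protein`, `peptide`, `start`, `end`, `rfu_back`,
#' `rfu_fwd` and optionally `provenance`.
#'
#' @param path File path.
#' @param controls A control tibble.
#' @return `read_controls()` returns a validated control tibble.
#' @export
read_controls <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path),
                                class = "hdx_format_error")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("sequence" %in% names(df) && !"peptide" %in% names(df)) {
    df <- rename(df, peptide = "sequence")
  }
  require_columns(df, control_cols, "control table")
  if (!"provenance" %in% names(df)) df$provenance <- "experimental"
  df <- df %>%
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) %>%
    select(all_of(c(control_cols, "provenance"))) %>%
    arrange(.data$protein, .data$start, .data$end, .data$peptide)
  validate_controls(df)
  as_tibble(df)
}

#' @rdname read_controls
#' @export
write_controls <- function(controls, path) {
  out <- controls %>%
    mutate(rfu_back = round(.data$rfu_back, 6), rfu_fwd = round(.data$rfu_fwd, 6))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write protection profiles
#'
#' Tab-separated with columns `residue`, `aa`, `lnp`, `mask` (plus `protein`).
#' Masked residues (prolines, excluded N-terminal positions) carry `lnp = NA`
#' and `mask = TRUE`.
#'
#' @param path File path.
#' @param profile A protection-profile tibble.
#' @return `read_profile()` returns a validated profile tibble.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path),
                                class = "hdx_format_error")
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(df, c("protein", "residue", "aa", "lnp"), "protection profile")
  df <- df %>%
    mutate(residue = as.integer(.data$residue)) %>%
    select(all_of(c("protein", "residue", "aa", "lnp"))) %>%
    arrange(.data$residue)
  validate_profile(df)
  as_tibble(df)
}

#' @rdname read_profile
#' @export
write_profile <- function(profile, path) {
  out <- profile %>%
    mutate(lnp = round(.data$lnp, 6), mask = is.na(.data$lnp))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
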