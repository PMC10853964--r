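#' Default exposure-time grid of the synthetic studies
#'
#' Seven exposure times spanning 15 s to 8 h, the grid typical of automated
#' HDX-MS acquisitions.
#'
#' @return Numeric vector of seconds.
#' @export
default_times <- function() c(15, 60, 300, 1800, 3600, 14400, 28800)

#' Build the control-error impact study
#'
#' Generates the full synthetic study of how errors in back/forward-exchange
#' controls corrupt downstream protection-factor optimization.  For each
#' synthetic protein: a smooth random lnP profile and overlapping peptide map
#' are generated, true uptake is simulated from the polyexponential forward
#' model, per-peptide controls are drawn from truncated-normal libraries and
#' used to corrupt the data to its observed (erroneous) form.  Then, for every
#' combination of error threshold and target (back only, forward only, both)
#' plus one error-free reconstruction, errors are injected into the controls
#' and the data reconstituted with the modified controls.
#'
#' At the defaults (3 proteins, thresholds 2/5/10/20) this yields
#' `3 * (3 * 4 + 1) = 39` reconstituted profiles; in general
#' `n_proteins * (3 * length(thresholds) + 1)`.
#'
#' @param n_proteins Number of synthetic proteins (default 3).
#' @param thresholds Error thresholds in RFU percentage points
#'   (default `c(2, 5, 10, 20)`).
#' @param times Exposure-time grid in seconds; default [default_times()].
#' @param protein_length Residues per synthetic protein (default 100).
#' @param n_peptides Peptides per map (default 50).
#' @param library_size Size of each control library (default 10000).
#' @param back_mean,back_sd,fwd_mean,fwd_sd Control-library parameters.
#' @param conditions Labeling conditions for the intrinsic rates.
#' @param seed Integer seed; every stochastic step derives a child seed from
#'   it, making the whole bundle reproducible.
#' @return An object of class `"hdx_error_study"`: a list with `proteins`
#'   (nested tibble of per-protein truth: profile, map, rates, true uptake,
#'   controls, erroneous uptake) and `datasets` (nested tibble of
#'   reconstituted uptake tables per protein x threshold x target, the
#'   error-free reconstruction carrying `threshold = 0`, `target = "none"`),
#'   plus the parameters.
#' @export
build_error_study <- function(n_proteins = 3, thresholds = c(2, 5, 10, 20),
                              times = default_times(), protein_length = 100,
                              n_peptides = 50, library_size = 10000,
                              back_mean = 0.70, back_sd = 0.08,
                              fwd_mean = 0.05, fwd_sd = 0.02,
                              conditions = exchange_conditions(),
                              seed = 1) {
  stopifnot(n_proteins >= 1, all(thresholds > 0))
  targets <- c("back_only", "fwd_only", "both")
  back_lib <- sample_control_library(library_size, "back", back_mean, back_sd,
                                     seed = child_seed(seed, 101))
  fwd_lib <- sample_control_library(library_size, "fwd", fwd_mean, fwd_sd,
                                    seed = child_seed(seed, 102))
  proteins <- purrr::map(seq_len(n_proteins), function(ip) {
    id <- paste0("protein_", ip)
    profile <- generate_protection_profile(protein_length,
                                           seed = child_seed(seed, ip, 1),
                                           protein = id)
    sequence <- paste(profile$aa, collapse = "")
    map <- generate_peptide_map(sequence, n_peptides,
                                seed = child_seed(seed, ip, 2), protein = id)
    rates <- intrinsic_rates(sequence, conditions)
    uptake_true <- simulate_uptake(map, profile, rates, times)
    controls <- assign_controls(map, back_lib, fwd_lib,
                                seed = child_seed(seed, ip, 3))
    uptake_err <- apply_controls(uptake_true, controls, mode = "corrupt")
    tibble(protein = id, profile = list(profile), map = list(map),
           rates = list(rates), uptake_true = list(uptake_true),
           controls = list(controls), uptake_err = list(uptake_err))
  }) %>% bind_rows()

  specs <- bind_rows(
    tibble(threshold = 0, target = "none"),
    tidyr::expand_grid(threshold = thresholds, target = targets))
  datasets <- purrr::pmap(
    tidyr::expand_grid(ip = seq_len(n_proteins), is = seq_len(nrow(specs))),
    function(ip, is) {
      row <- proteins[ip, ]
      thr <- specs$threshold[is]
      tgt <- specs$target[is]
      ctl <- row$controls[[1]]
      if (thr > 0) {
        ctl <- inject_errors(ctl, thr, tgt,
                             seed = child_seed(seed, ip, 10 + is))
      }
      recon <- apply_controls(row$uptake_err[[1]], ctl, mode = "correct",
                              clip = FALSE)
      tibble(protein = row$protein, threshold = thr, target = tgt,
             controls_used = list(ctl), uptake = list(recon))
    }) %>% bind_rows()

  structure(list(proteins = proteins, datasets = datasets,
                 params = list(n_proteins = n_proteins, thresholds = thresholds,
                               times = times, protein_length = protein_length,
                               n_peptides = n_peptides,
                               library_size = library_size,
                               back = c(mean = back_mean, sd = back_sd),
                               fwd = c(mean = fwd_mean, sd = fwd_sd),
                               seed = seed)),
            class = "hdx_error_study")
}

#' @export
print.hdx_error_study <- function(x, ...) {
  cat("<hdx_error_study>", nrow(x$proteins), "proteins,",
      nrow(x$datasets), "reconstituted profiles\n")
  invisible(x)
}

#' Evaluate the error study by protection-factor optimization
#'
#' Runs [optimize_lnp()] on every reconstituted dataset of an error study and
#' reports, for each (threshold, target) combination, the drop in accuracy
#' `dR2 = R2(error-free fit vs true lnP) - R2(erroneous fit vs true lnP)`
#' as mean and standard deviation over proteins.  Optimizer failures are
#' recorded, excluded from the means, and warned about.
#'
#' @param study An `"hdx_error_study"` object.
#' @param thresholds,targets Optional subsets to evaluate (the error-free
#'   reconstruction is always fitted).
#' @param ... Passed to [optimize_lnp()] (e.g. `max_iter`, `restarts`,
#'   `smoothness`).
#' @param seed Optional seed for the optimizer restarts.
#' @return A tibble `threshold`, `target`, `mean_dr2`, `sd_dr2`, `n_proteins`
#'   of class `"hdx_study_eval"`, with the per-dataset detail (`protein`,
#'   `threshold`, `target`, `r2`, `dr2`) in attribute `"details"`.
#'   Supports [autoplot()].
#' @export
evaluate_study <- function(study, thresholds = NULL, targets = NULL, ...,
                           seed = 1) {
  stopifnot(inherits(study, "hdx_error_study"))
  sel <- study$datasets
  if (!is.null(thresholds)) {
    sel <- sel %>% filter(.data$threshold %in% c(0, thresholds))
  }
  if (!is.null(targets)) {
    sel <- sel %>% filter(.data$target %in% c("none", targets))
  }
  truth <- setNames(study$proteins$profile, study$proteins$protein)
  rates <- setNames(study$proteins$rates, study$proteins$protein)

  fit_one <- function(protein, uptake) {
    tryCatch(
      optimize_lnp(uptake, rates[[protein]],
                   reference = truth[[protein]],
                   seed = child_seed(seed, which(names(truth) == protein)),
                   ...)$r2_vs_reference,
      error = function(e) NA_real_)
  }
  details <- sel %>%
    mutate(r2 = purrr::map2_dbl(.data$protein, .data$uptake, fit_one)) %>%
    select(all_of(c("protein", "threshold", "target", "r2")))
  if (anyNA(details$r2)) {
    warn(paste0(sum(is.na(details$r2)),
                " optimization(s) failed and were excluded"))
  }
  free <- details %>%
    filter(.data$target == "none") %>%
    select(all_of(c("protein", "r2"))) %>%
    rename(r2_free = "r2")
  details <- details %>%
    left_join(free, by = "protein") %>%
    mutate(dr2 = .data$r2_free - .data$r2)
  summary <- details %>%
    filter(.data$target != "none") %>%
    group_by(.data$threshold, .data$target) %>%
    summarise(mean_dr2 = mean(.data$dr2, na.rm = TRUE),
              sd_dr2 = sd(.data$dr2, na.rm = TRUE),
              n_proteins = sum(!is.na(.data$dr2)), .groups = "drop")
  attr(summary, "details") <- details
  class(summary) <- c("hdx_study_eval", class(summary))
  summary
}

#' @rdname evaluate_study
#' @param object An `"hdx_study_eval"` tibble (for `autoplot`).
#' @export
autoplot.hdx_study_eval <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$threshold), y = .data$mean_dr2,
                               fill = .data$target)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_dr2 - .data$sd_dr2,
                   ymax = .data$mean_dr2 + .data$sd_dr2),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
    ggplot2::labs(x = "control error threshold (% RFU)",
                  y = expression(Delta * R^2), fill = NULL) +
    ggplot2::theme_minimal()
}
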