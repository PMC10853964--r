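# Synthetic proteins, peptide maps, control libraries and error injection:
# the raw material for the control-error impact study.

# Background amino-acid composition for generated proteins (rough average
# globular-protein frequencies; proline kept at a realistic ~4-5%).
AA_FREQ <- c(A = 8.3, R = 5.5, N = 4.1, D = 5.5, C = 1.4, Q = 3.9, E = 6.8,
             G = 7.1, H = 2.3, I = 6.0, L = 9.7, K = 5.8, M = 2.4, F = 3.9,
             P = 4.7, S = 6.6, T = 5.3, W = 1.1, Y = 2.9, V = 6.9)

#' Generate a random protein sequence
#'
#' Draws residues from average globular-protein composition.  The first
#' residue is never proline (a digest N-terminal proline would be atypical and
#' its amide is masked anyway).
#'
#' @param length Number of residues (>= 20).
#' @param seed Optional integer seed.
#' @return One-letter sequence string.
#' @export
generate_protein_sequence <- function(length, seed = NULL) {
  stopifnot(length >= 20)
  with_seed_opt(seed, {
    aa <- sample(names(AA_FREQ), length, replace = TRUE, prob = AA_FREQ)
    while (aa[1] == "P") aa[1] <- sample(names(AA_FREQ), 1, prob = AA_FREQ)
    paste(aa, collapse = "")
  })
}

#' Generate a smooth random protection profile
#'
#' Simulates per-residue natural-log protection factors as a stationary AR(1)
#' (segment-wise correlated) process mapped into `range`, emulating the way
#' protection varies smoothly along secondary-structure elements.  Prolines of
#' the generated (or supplied) sequence and residue 1 are masked.
#'
#' @param length Protein length (>= 20); ignored when `sequence` is given.
#' @param seed Optional integer seed.
#' @param roughness Lag-1 autocorrelation of the underlying process, in
#'   (0, 1); higher values give smoother profiles.  Default 0.9.
#' @param range lnP range, default \[0, 14\].
#' @param sequence Optional sequence to use instead of generating one.
#' @param protein Protein id for the output tibble.
#' @return A protection-profile tibble (`protein`, `residue`, `aa`, `lnp`).
#' @export
generate_protection_profile <- function(length = 100, seed = NULL,
                                        roughness = 0.9, range = c(0, 14),
                                        sequence = NULL, protein = "synthetic") {
  with_seed_opt(seed, {
    if (is.null(sequence)) sequence <- generate_protein_sequence(length)
    aa <- split_sequence(sequence)
    n <- length(aa)
    z <- numeric(n)
    z[1] <- rnorm(1)
    innov_sd <- sqrt(1 - roughness^2)
    for (i in 2:n) z[i] <- roughness * z[i - 1] + rnorm(1, sd = innov_sd)
    lnp <- clamp(mean(range) + diff(range) / 4 * z, range[1], range[2])
    lnp[aa == "P"] <- NA_real_
    lnp[1] <- NA_real_
    tibble(protein = protein, residue = seq_len(n), aa = aa, lnp = lnp)
  })
}

#' Generate an overlapping peptide map
#'
#' Builds a proteolytic-style peptide map: a tiling pass of overlapping
#' peptides guarantees that every residue is covered, and the remaining
#' peptides are drawn with random starts and lengths, giving the redundant,
#' unevenly overlapping coverage typical of pepsin digests.
#'
#' @param sequence Protein sequence (one-letter string).
#' @param n_peptides Total number of peptides (default 50).
#' @param length_range Peptide length range, default \[6, 18\].
#' @param seed Optional integer seed.
#' @param protein Protein id.
#' @return A peptide-map tibble.
#' @export
generate_peptide_map <- function(sequence, n_peptides = 50,
                                 length_range = c(6, 18), seed = NULL,
                                 protein = "synthetic") {
  aa <- split_sequence(sequence)
  n <- length(aa)
  stopifnot(n >= length_range[2], n_peptides >= 2)
  with_seed_opt(seed, {
    tile_len <- min(12, length_range[2])
    step <- max(2, tile_len %/% 2)
    starts <- unique(c(seq(1, n - tile_len + 1, by = step), n - tile_len + 1))
    tiles <- tibble(start = as.integer(starts),
                    end = as.integer(starts + tile_len - 1L))
    n_rand <- max(0, n_peptides - nrow(tiles))
    lens <- sample(seq(length_range[1], length_range[2]), n_rand, replace = TRUE)
    st <- vapply(lens, function(l) sample.int(n - l + 1L, 1L), integer(1))
    rand <- tibble(start = st, end = st + lens - 1L)
    spans <- bind_rows(tiles, rand) %>%
      distinct(.data$start, .data$end) %>%
      arrange(.data$start, .data$end)
    map <- tibble(protein = protein,
                  peptide = substring(sequence, spans$start, spans$end),
                  start = spans$start, end = spans$end)
    validate_peptide_map(map, setNames(sequence, protein))
    map
  })
}

#' Sample a library of exchange-control values
#'
#' Draws `n` RFU values from a normal distribution truncated to \[0,1\],
#' emulating libraries of back/forward-exchange control values built from
#' normal fits to pooled experimental control histograms.
#'
#' @param n Library size (the study default is 10000).
#' @param kind `"back"` or `"fwd"`.
#' @param mean,sd Parameters of the underlying normal; `mean` must lie in
#'   (0, 1).  Package defaults: back 0.70/0.08, fwd 0.05/0.02.
#' @param seed Optional integer seed.
#' @return A tibble with column `value`, carrying `kind`, `mean`, `sd` as
#'   attributes.
#' @export
sample_control_library <- function(n = 10000, kind = c("back", "fwd"),
                                   mean = NULL, sd = NULL, seed = NULL) {
  kind <- match.arg(kind)
  mean <- mean %||% if (kind == "back") 0.70 else 0.05
  sd <- sd %||% if (kind == "back") 0.08 else 0.02
  if (mean <= 0 || mean >= 1) {
    abort("library mean must lie strictly inside (0, 1)",
          class = "hdx_parameter_error")
  }
  stopifnot(n >= 1, sd > 0)
  with_seed_opt(seed, {
    # inverse-CDF draw from the [0,1]-truncated normal
    lo <- pnorm(0, mean, sd)
    hi <- pnorm(1, mean, sd)
    values <- qnorm(runif(n, lo, hi), mean, sd)
    out <- tibble(value = clamp(values))
    attr(out, "kind") <- kind
    attr(out, "mean") <- mean
    attr(out, "sd") <- sd
    out
  })
}

#' Randomly assign control values to peptides
#'
#' Draws one back and one forward control per peptide, independently and with
#' replacement, from the supplied libraries (levels of back and forward
#' exchange for individual peptides are uncorrelated, so independent draws are
#' appropriate).  Pairs violating `back > fwd` are redrawn.
#'
#' @param map Peptide-map tibble.
#' @param back_lib,fwd_lib Libraries from [sample_control_library()].
#' @param seed Optional integer seed.
#' @param max_redraw Redraw budget per offending pair before erroring.
#' @return A control tibble with `provenance = "sampled"`.
#' @export
assign_controls <- function(map, back_lib, fwd_lib, seed = NULL,
                            max_redraw = 1000) {
  validate_peptide_map(map)
  stopifnot(nrow(back_lib) > 0, nrow(fwd_lib) > 0)
  with_seed_opt(seed, {
    n <- nrow(map)
    back <- sample(back_lib$value, n, replace = TRUE)
    fwd <- sample(fwd_lib$value, n, replace = TRUE)
    for (i in which(back <= fwd)) {
      tries <- 0
      while (back[i] <= fwd[i]) {
        tries <- tries + 1
        if (tries > max_redraw) {
          abort("could not draw back > fwd within the redraw budget",
                class = "hdx_infeasible_controls_error")
        }
        back[i] <- sample(back_lib$value, 1)
        fwd[i] <- sample(fwd_lib$value, 1)
      }
    }
    out <- map %>% mutate(rfu_back = back, rfu_fwd = fwd,
                          provenance = "sampled")
    validate_controls(out)
    out
  })
}

#' Inject controlled errors into a control table
#'
#' Perturbs control values by a fixed RFU offset with a random sign per value
#' (a fair coin, so no net drift), emulating experimental error in control
#' acquisition.  Thresholds are absolute RFU offsets: a "10%" threshold moves
#' a value by 0.10 RFU units up or down.  Results are clamped to \[0,1\];
#' pairs left with `back <= fwd` are pushed apart symmetrically by a minimal
#' gap and counted.
#'
#' @param controls A control tibble.
#' @param threshold Error threshold in RFU percentage points (>= 0); the study
#'   grid is 2, 5, 10, 20.
#' @param target Which controls receive errors: `"both"`, `"back_only"` or
#'   `"fwd_only"`.
#' @param seed Optional integer seed.
#' @param min_gap Minimal `back - fwd` gap enforced after injection.
#' @return A control tibble; attributes `"n_clamped"` (values clamped at 0 or
#'   1) and `"n_degenerate"` (pairs pushed apart) report the adjustments.
#' @export
inject_errors <- function(controls, threshold,
                          target = c("both", "back_only", "fwd_only"),
                          seed = NULL, min_gap = 0.01) {
  target <- match.arg(target)
  stopifnot(threshold >= 0)
  validate_controls(controls)
  delta <- threshold / 100
  with_seed_opt(seed, {
    out <- controls
    n <- nrow(out)
    n_clamped <- 0L
    if (target %in% c("both", "back_only")) {
      sgn <- sample(c(-1, 1), n, replace = TRUE)
      v <- out$rfu_back + sgn * delta
      n_clamped <- n_clamped + sum(v < 0 | v > 1)
      out$rfu_back <- clamp(v)
    }
    if (target %in% c("both", "fwd_only")) {
      sgn <- sample(c(-1, 1), n, replace = TRUE)
      v <- out$rfu_fwd + sgn * delta
      n_clamped <- n_clamped + sum(v < 0 | v > 1)
      out$rfu_fwd <- clamp(v)
    }
    bad <- which(out$rfu_back <= out$rfu_fwd)
    for (i in bad) {
      mid <- (out$rfu_back[i] + out$rfu_fwd[i]) / 2
      out$rfu_back[i] <- clamp(mid + min_gap / 2)
      out$rfu_fwd[i] <- clamp(mid - min_gap / 2)
      if (out$rfu_back[i] <= out$rfu_fwd[i]) {  # both pinned at a boundary
        out$rfu_back[i] <- clamp(out$rfu_fwd[i] + min_gap)
      }
    }
    attr(out, "n_clamped") <- n_clamped
    attr(out, "n_degenerate") <- length(bad)
    out
  })
}
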