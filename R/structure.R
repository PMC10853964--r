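# Structures are plain atom tibbles: one row per heavy atom with columns
# `residue` (1-based, contiguous), `aa` (one-letter), `atom` (PDB atom name;
# backbone N/CA/C/O), `x`, `y`, `z` in Angstrom.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

THREE_TO_ONE <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Read a structure from a PDB file
#'
#' Reads heavy atoms of the first model's first protein chain into the atom
#' tibble used throughout the decoy-ranking machinery.  Requires the bio3d
#' package.
#'
#' @param path Path to a PDB file.
#' @return An atom tibble (`residue`, `aa`, `atom`, `x`, `y`, `z`).
#' @export
read_structure <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("reading PDB files requires the bio3d package")
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elesy != "H", ]
  at <- at[at$chain == at$chain[1], ]
  resno <- at$resno
  out <- tibble(residue = as.integer(factor(resno, levels = unique(resno))),
                aa = unname(THREE_TO_ONE[at$resid]),
                atom = at$elety, x = at$x, y = at$y, z = at$z)
  if (anyNA(out$aa)) {
    warn("non-standard residues dropped from structure")
    out <- out %>% filter(!is.na(.data$aa))
  }
  out
}

unit <- function(v) v / sqrt(sum(v^2))

#' Build a synthetic helical-hairpin structure
#'
#' Generates backbone coordinates (N, CA, C, O) for a compact two-helix
#' hairpin with ideal alpha-helical geometry, used as the reference fold for
#' synthetic decoy-ranking experiments where no crystal structure is
#' available.  The object is synthetic and labeled as such; it reproduces the
#' geometric features the protection model reads (packed contacts in the
#' helix cores, sparse contacts at termini and in the turn).
#'
#' @param sequence One-letter sequence (>= 12 residues).
#' @return An atom tibble.
#' @export
synthetic_structure <- function(sequence) {
  aa <- split_sequence(sequence)
  n <- length(aa)
  stopifnot(n >= 12)
  half <- n %/% 2
  ca <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    if (i <= half) {
      th <- i * 100 * pi / 180
      ca[i, ] <- c(2.3 * cos(th), 2.3 * sin(th), 1.5 * i)
    } else {
      j <- i - half
      th <- -j * 100 * pi / 180
      ca[i, ] <- c(9 + 2.3 * cos(th), 2.3 * sin(th), 1.5 * (half - j + 1))
    }
  }
  rows <- purrr::map(seq_len(n), function(i) {
    to_prev <- if (i > 1) unit(ca[i - 1, ] - ca[i, ]) else -unit(ca[i + 1, ] - ca[i, ])
    to_next <- if (i < n) unit(ca[i + 1, ] - ca[i, ]) else -unit(ca[i - 1, ] - ca[i, ])
    npos <- ca[i, ] + 1.46 * to_prev
    cpos <- ca[i, ] + 1.52 * to_next
    perp <- pracma_cross(to_next, c(0, 0, 1))
    if (sum(perp^2) < 1e-8) perp <- pracma_cross(to_next, c(0, 1, 0))
    opos <- cpos + 1.23 * unit(perp)
    tibble(residue = i, aa = aa[i],
           atom = BACKBONE_ATOMS,
           x = c(npos[1], ca[i, 1], cpos[1], opos[1]),
           y = c(npos[2], ca[i, 2], cpos[2], opos[2]),
           z = c(npos[3], ca[i, 3], cpos[3], opos[3]))
  })
  bind_rows(rows)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

backbone_xyz <- function(s) {
  bb <- s %>%
    filter(.data$atom %in% BACKBONE_ATOMS) %>%
    mutate(atom = factor(.data$atom, levels = BACKBONE_ATOMS)) %>%
    arrange(.data$residue, .data$atom)
  as.matrix(bb[c("x", "y", "z")])
}

#' Backbone RMSD after optimal superposition
#'
#' Least-squares (Kabsch) superposition of the backbone atoms of two
#' structures followed by the root-mean-square deviation, in Angstrom.
#'
#' @param a,b Atom tibbles with equal residue counts and matching backbone
#'   atoms.
#' @return A nonnegative number (Angstrom).
#' @export
backbone_rmsd <- function(a, b) {
  A <- backbone_xyz(a)
  B <- backbone_xyz(b)
  if (!identical(dim(A), dim(B))) {
    abort("structures have mismatched backbone atom counts",
          class = "hdx_alignment_error")
  }
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  s <- svd(t(B) %*% A)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((A %*% R - B)^2)))
}

#' Generate decoys by graded coordinate perturbation
#'
#' Produces alternative conformations of a reference structure by applying
#' smooth, residue-correlated random displacement fields of graded magnitude,
#' yielding a spread of backbone RMSDs that spans the native/non-native
#' labeling threshold.  A toy stand-in for fragment-assembly decoy
#' generators.
#'
#' @param reference Atom tibble of the reference structure.
#' @param n Number of decoys (>= 2).
#' @param scale_schedule Displacement scales in Angstrom, recycled across
#'   decoys (default `seq(0, 6, length.out = n)`).
#' @param seed Optional integer seed.
#' @return A nested tibble `decoy`, `scale`, `structure` (list of atom
#'   tibbles).
#' @export
perturb_decoys <- function(reference, n, scale_schedule = NULL, seed = NULL) {
  stopifnot(n >= 2)
  scales <- rep_len(scale_schedule %||% seq(0, 6, length.out = n), n)
  n_res <- max(reference$residue)
  with_seed_opt(seed, {
    structures <- purrr::map(seq_len(n), function(i) {
      # 3 low-frequency sine modes per coordinate axis
      disp <- matrix(0, n_res, 3)
      for (ax in 1:3) {
        for (m in 1:3) {
          amp <- rnorm(1, sd = scales[i] / sqrt(6))
          ph <- runif(1, 0, 2 * pi)
          disp[, ax] <- disp[, ax] +
            amp * sin(2 * pi * m * seq_len(n_res) / n_res + ph)
        }
      }
      s <- reference
      s$x <- s$x + disp[s$residue, 1]
      s$y <- s$y + disp[s$residue, 2]
      s$z <- s$z + disp[s$residue, 3]
      s
    })
    tibble(decoy = seq_len(n), scale = scales, structure = structures)
  })
}

#' Label decoys as native or non-native by backbone RMSD
#'
#' A decoy is native when its optimal-superposition backbone RMSD to the
#' reference is strictly below `threshold` (default 2.5 Angstrom).
#'
#' @param decoys Decoy tibble from [perturb_decoys()] (or with a `structure`
#'   list column).
#' @param reference Atom tibble of the reference structure.
#' @param threshold Angstrom; strict inequality.
#' @return The decoy tibble with `rmsd` and logical `native` columns added.
#' @export
label_decoys <- function(decoys, reference, threshold = 2.5) {
  decoys %>%
    mutate(rmsd = purrr::map_dbl(.data$structure, backbone_rmsd, b = reference),
           native = .data$rmsd < threshold)
}

#' Phenomenological protection factors from a structure
#'
#' Estimates per-residue lnP from two structural descriptors of each
#' residue's amide nitrogen: `lnP_i = beta_contacts * N_c(i) +
#' beta_hbonds * N_h(i)`, where `N_c` counts heavy atoms within
#' `contact_cutoff` of the amide nitrogen (residues i-1, i, i+1 excluded)
#' and `N_h` counts backbone carbonyl oxygens within `hbond_cutoff` of the
#' nitrogen (same exclusion), a geometric hydrogen-bond criterion that needs
#' no explicit hydrogens.  Prolines and residue 1 are masked; residues
#' missing an amide nitrogen are masked with a warning.
#'
#' @param structure Atom tibble.
#' @param beta_contacts,beta_hbonds Model weights (defaults 0.35 and 2.0).
#' @param contact_cutoff,hbond_cutoff Distance cutoffs in Angstrom (defaults
#'   6.5 and 2.4).
#' @param protein Protein id for the output profile.
#' @return A protection-profile tibble.
#' @export
protection_from_structure <- function(structure, beta_contacts = 0.35,
                                      beta_hbonds = 2.0, contact_cutoff = 6.5,
                                      hbond_cutoff = 2.4,
                                      protein = "structure") {
  n <- max(structure$residue)
  aa <- structure %>%
    distinct(.data$residue, .data$aa) %>%
    arrange(.data$residue) %>%
    pull(.data$aa)
  heavy <- as.matrix(structure[c("x", "y", "z")])
  res_of <- structure$residue
  is_o <- structure$atom == "O"
  lnp <- rep(NA_real_, n)
  missing_n <- integer(0)
  for (i in seq_len(n)) {
    if (i == 1 || aa[i] == "P") next
    ni <- which(res_of == i & structure$atom == "N")
    if (length(ni) == 0) {
      missing_n <- c(missing_n, i)
      next
    }
    np <- heavy[ni[1], ]
    d2 <- (heavy[, 1] - np[1])^2 + (heavy[, 2] - np[2])^2 +
      (heavy[, 3] - np[3])^2
    far <- abs(res_of - i) > 1
    n_c <- sum(far & d2 <= contact_cutoff^2)
    n_h <- sum(far & is_o & d2 <= hbond_cutoff^2)
    lnp[i] <- beta_contacts * n_c + beta_hbonds * n_h
  }
  if (length(missing_n) > 0) {
    warn(paste0("residue(s) missing an amide nitrogen masked: ",
                paste(missing_n, collapse = ", ")))
  }
  tibble(protein = protein, residue = seq_len(n), aa = aa, lnp = lnp)
}

# Midrank (Mann-Whitney) AUC of scores where LOWER score means more
# native-like; labels are logical (TRUE = native).
auc_lower_better <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    abort("AUC needs both native and non-native decoys",
          class = "hdx_structural_error")
  }
  r <- rank(-scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points <- function(scores, labels) {
  ord <- order(scores)
  s <- scores[ord]
  l <- labels[ord]
  tibble(threshold = c(-Inf, s),
         tpr = c(0, cumsum(l) / sum(l)),
         fpr = c(0, cumsum(!l) / sum(!l)))
}

#' Rank decoys by agreement of simulated uptake with a reference dataset
#'
#' For every labeled decoy, derives a protection profile from its structure,
#' simulates peptide uptake under the forward model, and scores it by the
#' overall RMSE (RFU) against the reference uptake table.  Lower RMSE means
#' more native-like; the ranking's power to separate native from non-native
#' decoys is summarized by the ROC curve and its AUC (midrank tie handling):
#' the probability that a randomly chosen native decoy outranks a randomly
#' chosen non-native one.
#'
#' @param reference_uptake Long uptake tibble the decoys are scored against.
#' @param decoys Labeled decoy tibble (from [label_decoys()]).
#' @param map Peptide map used for simulation (normally the reference map).
#' @param rates Intrinsic-rate tibble for the protein.
#' @param ... Passed to [protection_from_structure()] (betas, cutoffs).
#' @return The decoy tibble with a `score` column, of class
#'   `"hdx_decoy_ranking"`, with attributes `"auc"` and `"roc"` (tibble of
#'   ROC points).  Decoys whose profile cannot produce uptake are excluded
#'   with a warning.  Supports [autoplot()].
#' @export
rank_decoys <- function(reference_uptake, decoys, map, rates, ...) {
  if (!"native" %in% names(decoys)) {
    abort("decoys must be labeled first (see label_decoys())",
          class = "hdx_structural_error")
  }
  times <- sort(unique(reference_uptake$exposure_s))
  score_one <- function(s) {
    tryCatch({
      prof <- protection_from_structure(s, protein = map$protein[1], ...)
      sim <- simulate_uptake(map, prof, rates, times)
      uptake_rmse(sim, reference_uptake)
    }, error = function(e) NA_real_)
  }
  out <- decoys %>%
    mutate(score = purrr::map_dbl(.data$structure, score_one))
  if (anyNA(out$score)) {
    warn(paste0(sum(is.na(out$score)),
                " decoy(s) could not be simulated and were excluded"))
    out <- out %>% filter(!is.na(.data$score))
  }
  attr(out, "auc") <- auc_lower_better(out$score, out$native)
  attr(out, "roc") <- roc_points(out$score, out$native)
  class(out) <- c("hdx_decoy_ranking", class(out))
  out
}

#' @rdname rank_decoys
#' @param object An `"hdx_decoy_ranking"` (for `autoplot`).
#' @export
autoplot.hdx_decoy_ranking <- function(object, ...) {
  roc <- attr(object, "roc")
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey") +
    ggplot2::annotate("text", x = 0.75, y = 0.1,
                      label = paste0("AUC = ", signif(attr(object, "auc"), 3))) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}
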