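ref_structure <- function(n = 40, seed = 201) {
  seqn <- generate_protein_sequence(n, seed = seed)
  synthetic_structure(seqn)
}

rotation_matrix <- function(ax, ay, az) {
  rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  rx %*% ry %*% rz
}

transform_structure <- function(s, R, shift) {
  xyz <- as.matrix(s[c("x", "y", "z")]) %*% t(R)
  s$x <- xyz[, 1] + shift[1]
  s$y <- xyz[, 2] + shift[2]
  s$z <- xyz[, 3] + shift[3]
  s
}

test_that("superposition RMSD removes rigid motion and is symmetric", {
  s <- ref_structure()
  expect_equal(backbone_rmsd(s, s), 0)
  moved <- transform_structure(s, rotation_matrix(0.4, -1.1, 2.2),
                               c(5, -3, 12))
  expect_lt(backbone_rmsd(s, moved), 1e-9)
  d <- perturb_decoys(s, 2, scale_schedule = c(3, 3), seed = 202)
  expect_equal(backbone_rmsd(s, d$structure[[2]]),
               backbone_rmsd(d$structure[[2]], s), tolerance = 1e-12)
})

test_that("RMSD matches a brute-force rotation grid on a 3-atom toy", {
  a <- tibble::tibble(residue = 1L, aa = "A", atom = c("N", "CA", "C"),
                      x = c(0, 1.5, 2.4), y = c(0, 0, 1.1), z = c(0, 0.2, 0))
  b <- tibble::tibble(residue = 1L, aa = "A", atom = c("N", "CA", "C"),
                      x = c(0.2, 1.4, 2.8), y = c(0.1, -0.3, 1.0),
                      z = c(-0.1, 0.4, 0.3))
  got <- backbone_rmsd(a, b)
  A <- as.matrix(a[c("x", "y", "z")])
  B <- as.matrix(b[c("x", "y", "z")])
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  ang <- seq(0, 2 * pi, length.out = 60)
  best <- Inf
  for (ax in ang) for (ay in ang[1:30]) for (az in ang) {
    R <- rotation_matrix(ax, ay, az)
    best <- min(best, mean(rowSums((A %*% R - B)^2)))
  }
  expect_lt(got, sqrt(best) + 1e-9)
  expect_equal(got, sqrt(best), tolerance = 0.05)
})

test_that("superposition agrees with the bio3d reference implementation", {
  skip_if_not_installed("bio3d")
  s <- ref_structure(30, seed = 203)
  d <- perturb_decoys(s, 2, scale_schedule = c(2.5, 2.5), seed = 204)$structure[[1]]
  a <- hdxamend:::backbone_xyz(s)
  b <- hdxamend:::backbone_xyz(d)
  ref_rmsd <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
  expect_equal(backbone_rmsd(s, d), ref_rmsd, tolerance = 1e-4)
})

test_that("decoy labeling applies a strict RMSD threshold", {
  s <- ref_structure(30, seed = 205)
  d <- perturb_decoys(s, 6, scale_schedule = c(0, 1, 2, 3, 4, 6), seed = 206)
  lab <- label_decoys(d, s)
  expect_true(lab$native[1])           # exact duplicate: RMSD 0
  expect_equal(lab$native, lab$rmsd < 2.5)
  # a decoy exactly at the threshold is non-native
  lab2 <- label_decoys(d, s, threshold = lab$rmsd[3])
  expect_false(lab2$native[3])
  # controlled perturbation scale orders the RMSDs on average
  expect_gt(cor(lab$scale, lab$rmsd, method = "spearman"), 0.8)
})

test_that("perturbation is seeded and scale 0 is an exact duplicate", {
  s <- ref_structure(25, seed = 207)
  d1 <- perturb_decoys(s, 4, seed = 208)
  d2 <- perturb_decoys(s, 4, seed = 208)
  expect_identical(d1$structure, d2$structure)
  expect_equal(d1$structure[[1]], s)
})

test_that("structural protection counts contacts and hydrogen bonds", {
  # isolated extended chain: no non-neighbour atom within the cutoff
  far <- tibble::tibble(residue = rep(1:4, each = 2), aa = "A",
                        atom = rep(c("N", "O"), 4),
                        x = rep(c(0, 2), 4) + rep((0:3) * 50, each = 2),
                        y = 0, z = 0)
  p0 <- protection_from_structure(far)
  expect_equal(p0$lnp[2:4], c(0, 0, 0))
  expect_true(is.na(p0$lnp[1]))

  # one contact atom and one N...O pair placed by hand near residue 3's N
  toy <- tibble::tibble(
    residue = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 1L),
    aa = c("A", "A", "K", "K", "L", "L", "V", "V", "A"),
    atom = c("N", "CA", "N", "CA", "N", "CA", "N", "CA", "O"),
    x = c(0, 1, 100, 101, 200, 201, 300, 301, 202),
    y = c(0, 0, 0, 0, 0, 0, 0, 0, 0),
    z = c(0, 0, 0, 0, 0, 0, 0, 0, 0))
  # residue 3's N at (200,0,0): residue-1 O at (202,0,0) is 2.0 A away ->
  # one contact and one hydrogen bond; nothing else within 6.5 A
  p <- protection_from_structure(toy)
  expect_equal(p$lnp[3], 0.35 * 1 + 2.0 * 1)
  expect_equal(p$lnp[2], 0)
  # doubling both betas doubles lnp
  p2 <- protection_from_structure(toy, beta_contacts = 0.7, beta_hbonds = 4)
  expect_equal(p2$lnp[3], 2 * p$lnp[3])
  # prolines masked
  toy_p <- dplyr::mutate(toy, aa = ifelse(residue == 3, "P", aa))
  expect_true(is.na(protection_from_structure(toy_p)$lnp[3]))
})

test_that("AUC equals exhaustive pair counting and honors ties", {
  scores <- c(0.01, 0.02, 0.3, 0.4)
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(hdxamend:::auc_lower_better(scores, labels), 1)

  withr::with_seed(209, {
    s10 <- runif(10)
    l10 <- sample(c(TRUE, FALSE), 10, TRUE, prob = c(0.4, 0.6))
    pairs <- expand.grid(i = which(l10), j = which(!l10))
    brute <- mean(ifelse(s10[pairs$i] < s10[pairs$j], 1,
                         ifelse(s10[pairs$i] == s10[pairs$j], 0.5, 0)))
    expect_equal(hdxamend:::auc_lower_better(s10, l10), brute)
    # invariance under strictly monotone transforms
    expect_equal(hdxamend:::auc_lower_better(exp(3 * s10), l10), brute)
    # permutation null averages one half
    nulls <- vapply(1:2000, function(i) {
      hdxamend:::auc_lower_better(s10, sample(l10))
    }, numeric(1))
    expect_lt(abs(mean(nulls) - 0.5), 0.02)
  })
})

test_that("AUC cross-checks against pROC", {
  skip_if_not_installed("pROC")
  withr::with_seed(210, {
    s <- runif(40)
    l <- runif(40) + 0.4 * s > 0.7  # noisy association
    skip_if_not(sum(l) > 0 && sum(!l) > 0)
    ours <- hdxamend:::auc_lower_better(s, l)
    theirs <- as.numeric(pROC::auc(pROC::roc(response = l, predictor = s,
                                             quiet = TRUE,
                                             direction = ">")))
    expect_equal(ours, theirs, tolerance = 1e-12)
  })
})

test_that("decoy ranking separates native from non-native folds", {
  prof0 <- generate_protection_profile(40, seed = 211)
  seqn <- paste(prof0$aa, collapse = "")
  s <- synthetic_structure(seqn)
  dec <- label_decoys(perturb_decoys(s, 30, seed = 212), s)
  skip_if_not(sum(dec$native) > 1 && sum(!dec$native) > 1)
  prof <- protection_from_structure(s)
  rates <- intrinsic_rates(seqn)
  map <- generate_peptide_map(seqn, 15, seed = 213, protein = "structure")
  u_ref <- simulate_uptake(map, prof, rates, default_times())
  rk <- rank_decoys(u_ref, dec, map, rates)
  expect_true(all(rk$score >= 0))
  expect_equal(rk$score[1], 0, tolerance = 1e-12)  # duplicate of reference
  expect_gt(attr(rk, "auc"), 0.7)
  roc <- attr(rk, "roc")
  expect_equal(c(roc$tpr[1], roc$fpr[1]), c(0, 0))
  expect_equal(c(dplyr::last(roc$tpr), dplyr::last(roc$fpr)), c(1, 1))
  expect_s3_class(autoplot(rk), "ggplot")
})

test_that("PDB files round trip through the atom-tibble representation", {
  skip_if_not_installed("bio3d")
  s <- ref_structure(20, seed = 214)
  pdb_lines <- sprintf(
    "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
    seq_len(nrow(s)),
    ifelse(nchar(s$atom) < 4, paste0(" ", s$atom), s$atom),
    names(hdxamend:::THREE_TO_ONE)[match(s$aa, hdxamend:::THREE_TO_ONE)],
    s$residue, s$x, s$y, s$z, substr(s$atom, 1, 1))
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_lines, "END"), path)
  got <- read_structure(path)
  expect_equal(nrow(got), nrow(s))
  expect_equal(got$aa, s$aa)
  expect_equal(got[c("x", "y", "z")], s[c("x", "y", "z")], tolerance = 1e-3)
  expect_lt(backbone_rmsd(got, s), 1e-3)
})
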