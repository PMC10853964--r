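make_flat_system <- function(seqn, k = 1, lnp = 0) {
  n <- nchar(seqn)
  aa <- strsplit(seqn, "")[[1]]
  profile <- tibble::tibble(protein = "p", residue = seq_len(n), aa = aa,
                            lnp = ifelse(aa == "P", NA, lnp))
  profile$lnp[1] <- NA
  rates <- tibble::tibble(residue = seq_len(n), aa = aa,
                          k_int = ifelse(aa == "P", NA, k))
  list(profile = profile, rates = rates)
}

test_that("single-reporter peptide follows the one-exponential closed form", {
  s <- make_flat_system("AK", k = 1, lnp = 0)
  expect_equal(peptide_rfu(1, 2, s$profile, s$rates, t = log(2)), 0.5,
               tolerance = 1e-12)
  # hand value at t = 0.6931 s
  expect_equal(peptide_rfu(1, 2, s$profile, s$rates, t = 0.6931),
               1 - exp(-0.6931), tolerance = 1e-12)
})

test_that("saturation and full-protection limits hold", {
  s <- make_flat_system("AKLVGS", k = 2, lnp = 0)
  expect_equal(peptide_rfu(1, 6, s$profile, s$rates, t = 1e9), 1,
               tolerance = 1e-9)
  prot <- make_flat_system("AKLVGS", k = 2, lnp = 60)
  expect_lt(peptide_rfu(1, 6, prot$profile, prot$rates, t = 1e6), 1e-12)
})

test_that("uniform rates and protection reduce to 1 - exp(-kt/P)", {
  s <- make_flat_system("AKLVGSAKLV", k = 0.37, lnp = 3.2)
  t <- c(15, 600, 28800)
  expect_equal(peptide_rfu(1, 10, s$profile, s$rates, t),
               1 - exp(-0.37 * t / exp(3.2)), tolerance = 1e-9)
})

test_that("RFU increases in t and decreases in each lnp", {
  withr::with_seed(11, {
    n_strict_t <- 0
    n_strict_p <- 0
    for (i in 1:200) {
      n <- sample(4:12, 1)
      seqn <- paste(sample(c("A", "K", "L", "V", "G", "S"), n, TRUE),
                    collapse = "")
      s <- make_flat_system(seqn)
      s$profile$lnp[-1] <- runif(n - 1, 0, 12)
      s$rates$k_int[-1] <- 10^runif(n - 1, -2, 2)
      t1 <- 10^runif(1, 0, 3)
      f1 <- peptide_rfu(1, n, s$profile, s$rates, t1)
      f_later <- peptide_rfu(1, n, s$profile, s$rates, t1 * 3)
      expect_gte(f_later, f1)
      if (f1 < 1 - 1e-9) {  # strict except at floating-point saturation
        expect_gt(f_later, f1)
        n_strict_t <- n_strict_t + 1
      }
      j <- sample(2:n, 1)
      s2 <- s
      s2$profile$lnp[j] <- s2$profile$lnp[j] + 1
      f_prot <- peptide_rfu(1, n, s2$profile, s2$rates, t1)
      expect_gte(f1, f_prot)
      u_j <- s$rates$k_int[j] * t1 * exp(-s$profile$lnp[j])
      if (u_j > 1e-10 && u_j < 30) {
        expect_gt(f1, f_prot)
        n_strict_p <- n_strict_p + 1
      }
    }
    expect_gt(n_strict_t, 50)
    expect_gt(n_strict_p, 50)
  })
})

test_that("a peptide's RFU is the mean of its residues' deuterium fractions", {
  sys <- make_system(n_res = 40, n_pep = 10, seed = 21)
  masked <- is.na(sys$profile$lnp)
  t <- 600
  idx <- reporting_residues(5, 24, masked)
  whole <- peptide_rfu(5, 24, sys$profile, sys$rates, t)
  # each reporter's fraction via a 2-mer whose only reporter is that residue
  per_res <- vapply(idx, function(j) {
    peptide_rfu(j - 1L, j, sys$profile, sys$rates, t)
  }, numeric(1))
  expect_equal(whole, mean(per_res), tolerance = 1e-12)

  # recombining two sub-peptides by reporter count reproduces the parent
  left_idx <- reporting_residues(5, 14, masked)
  right_idx <- reporting_residues(14, 24, masked)  # overlap makes the union
  skip_if_not(setequal(c(left_idx, right_idx), idx),
              "sub-peptide reporters must partition the parent's")
  left <- peptide_rfu(5, 14, sys$profile, sys$rates, t)
  right <- peptide_rfu(14, 24, sys$profile, sys$rates, t)
  expect_equal(whole,
               (length(left_idx) * left + length(right_idx) * right) /
                 length(idx),
               tolerance = 1e-12)
})

test_that("simulate_uptake agrees cell-wise with peptide_rfu and is monotone", {
  sys <- make_system(n_res = 60, n_pep = 20, seed = 22)
  u <- sys$uptake
  row <- u[u$start == sys$map$start[3] & u$end == sys$map$end[3] &
             u$exposure_s == 300, ]
  expect_equal(row$rfu,
               peptide_rfu(sys$map$start[3], sys$map$end[3], sys$profile,
                           sys$rates, 300))
  trend <- u %>%
    dplyr::group_by(peptide, start, end) %>%
    dplyr::summarise(mono = all(diff(rfu) >= 0), .groups = "drop")
  expect_true(all(trend$mono))
})

test_that("hand-computed toy dataset matches to 1e-9", {
  s <- make_flat_system("AKLVG")
  s$profile$lnp <- c(NA, 1, 2, 3, 4)
  s$rates$k_int <- c(NA, 0.5, 1, 2, 4)
  map <- tibble::tibble(protein = "p", peptide = c("AKL", "LVG"),
                        start = c(1L, 3L), end = c(3L, 5L))
  times <- c(10, 100)
  u <- simulate_uptake(map, s$profile, s$rates, times)
  by_hand <- function(idx, t) {
    mean(1 - exp(-s$rates$k_int[idx] * t / exp(s$profile$lnp[idx])))
  }
  expect_equal(u$rfu[u$peptide == "AKL"],
               vapply(times, by_hand, numeric(1), idx = 2:3),
               tolerance = 1e-9)
  expect_equal(u$rfu[u$peptide == "LVG"],
               vapply(times, by_hand, numeric(1), idx = 4:5),
               tolerance = 1e-9)
})

test_that("peptides without reporters raise a no-reporter error", {
  s <- make_flat_system("APLV")
  expect_error(peptide_rfu(1, 2, s$profile, s$rates, 60),
               class = "hdx_no_reporter_error")
  map <- tibble::tibble(protein = "p", peptide = "AP", start = 1L, end = 2L)
  expect_error(simulate_uptake(map, s$profile, s$rates, c(10, 100)),
               class = "hdx_no_reporter_error")
})
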