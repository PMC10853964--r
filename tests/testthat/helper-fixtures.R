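# Shared fixtures, all generated in code with fixed seeds.

# A tiny hand-written uptake table: 2 peptides x 3 times.
tiny_uptake <- function() {
  tibble::tibble(
    protein = "toy",
    peptide = rep(c("AKLV", "LVGS"), each = 3),
    start = rep(c(1L, 3L), each = 3),
    end = rep(c(4L, 6L), each = 3),
    exposure_s = rep(c(15, 60, 600), 2),
    rfu = c(0.10, 0.30, 0.60, 0.20, 0.45, 0.80))
}

tiny_controls <- function(back = c(0.8, 0.7), fwd = c(0.1, 0.05)) {
  tibble::tibble(
    protein = "toy",
    peptide = c("AKLV", "LVGS"),
    start = c(1L, 3L), end = c(4L, 6L),
    rfu_back = back, rfu_fwd = fwd,
    provenance = "experimental")
}

# A small but realistic simulated protein system.
make_system <- function(n_res = 80, n_pep = 40, seed = 42,
                        times = default_times()) {
  profile <- generate_protection_profile(n_res, seed = seed)
  sequence <- paste(profile$aa, collapse = "")
  map <- generate_peptide_map(sequence, n_pep, seed = seed + 1,
                              protein = "synthetic")
  rates <- intrinsic_rates(sequence)
  uptake <- simulate_uptake(map, profile, rates, times)
  list(profile = profile, sequence = sequence, map = map, rates = rates,
       uptake = uptake, times = times)
}

# A constant-output "oracle" model usable with predict_controls(): a single
# linear layer with zero weights whose biases are the true controls.
constant_control_model <- function(back, fwd) {
  structure(list(
    params = list(list(W = matrix(0, 2, 1), b = c(back, fwd))),
    spec = mlp_spec(hidden = integer(0), epochs = 0, seed = 1),
    standardization = c(mean = 0, sd = 1),
    train_loss = numeric(0), val_loss = numeric(0)),
    class = "hdx_mlp")
}

# Training data where targets are a smooth function of the variance feature.
functional_training_set <- function(n = 300, seed = 99,
                                    proteins = c("trainA", "trainB")) {
  withr::with_seed(seed, {
    v <- runif(n, 0, 0.12)
    tibble::tibble(
      protein = rep_len(proteins, n),
      peptide = "AAAA", start = 1L, end = 4L,
      variance = v,
      rfu_back = 0.55 + 2.5 * v,
      rfu_fwd = 0.02 + 0.8 * v)
  })
}
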