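# Internal helpers shared across modules.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")

clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Split a one-letter sequence into a character vector, validating the alphabet.
split_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(aa), AA1)
  if (length(bad) > 0) {
    abort(paste0("sequence contains non-standard residue letter(s): ",
                 paste(bad, collapse = ", ")),
          class = "hdx_sequence_error")
  }
  aa
}

# Evaluate `expr` under a temporary seed when `seed` is non-NULL; otherwise use
# the ambient RNG stream.  All stochastic entry points funnel through this.
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Deterministic child seed for composite operations (kept well below 2^31).
child_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  off <- sum(c(...) * 10013L^(seq_along(c(...)) - 1L)) %% 1000003L
  (as.integer(seed) %% 1000003L) * 2017L %% 1999999973L + off
}
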