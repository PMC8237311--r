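# Internal helpers shared across modules.

# Seeded evaluation that does not disturb the caller's RNG stream.
with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Shuffled K-fold assignment: integer vector of fold ids, one per sample.
make_folds <- function(n, k, seed) {
  stopifnot(k >= 2, n >= k)
  with_seed_(seed, sample(rep_len(seq_len(k), n)))
}

# Pooled out-of-fold coefficient of determination: one number over all
# held-out predictions, no per-fold weighting.
pooled_r2 <- function(y, y_oof) {
  1 - sum((y - y_oof)^2) / sum((y - mean(y))^2)
}

abort_ <- function(..., class = "varselbench_error") {
  stop(errorCondition(paste0(...), class = c(class, "error")))
}
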