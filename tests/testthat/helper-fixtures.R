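# Fixtures shared across test files; everything is generated in code.

# Assemble a vsb_split directly from train/test matrices, bypassing the
# random splitter, so filter behaviour can be pinned to exact train values.
make_pair <- function(Xtr, ytr, Xte = Xtr, yte = ytr) {
  structure(list(train = vsb_dataset(Xtr, ytr),
                 test = vsb_dataset(Xte, yte),
                 seed = 0L),
            class = "vsb_split")
}

# A small preprocessed linear fixture: n samples, p_inf informative columns
# with the given coefficients, p_noise pure-noise columns; returns the
# autoscaled split (no probe spiking unless asked).
linear_pair <- function(n = 120, p_inf = 2, p_noise = 3,
                        coefficients = c(3, 2), noise_sd = 0.5,
                        spike = FALSE, seed = 42, split_seed = 5) {
  spec <- synthetic_spec(n_samples = n, n_informative = p_inf,
                         n_noise = p_noise, coefficients = coefficients,
                         noise_sd = noise_sd, seed = seed)
  gen <- generate_synthetic(spec)
  list(pair = preprocess(gen$dataset, spike = spike, seed = split_seed),
       truth = gen$truth)
}

# Noiseless exact-linear training dataset (already standardized columns).
noiseless_train <- function(n = 80, p = 3, seed = 9) {
  withr::with_seed(seed, {
    X <- scale(matrix(rnorm(n * p), n))
    colnames(X) <- paste0("v", seq_len(p))
    y <- drop(X %*% seq_len(p))
    vsb_dataset(X, y)
  })
}
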