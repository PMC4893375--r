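# Small synthetic feature/label sets for regressor unit tests (no Monte
# Carlo involved): band-like positive measurements, normalized through the
# package chain, with labels that are smooth functions of the measurement.
make_synthetic_training <- function(n, K = 10, seed = 1) {
  set.seed(seed)
  depth <- runif(n)                      # latent "oxygenation-like" driver
  vol <- runif(n, 0, 0.1)                # latent "blood-volume-like" driver
  wl <- seq_len(K)
  r <- t(vapply(seq_len(n), function(i) {
    0.2 + 0.5 * plogis((wl - 5 * depth[i] - 3)) * exp(-vol[i] * wl) +
      rnorm(K, 0, 0.002)
  }, numeric(K)))
  r[r <= 0] <- 1e-4
  training_set(normalize_features(r), data.frame(s = depth, v_hb = vol))
}

# tiny end-to-end Monte Carlo dataset shared by evaluation/image tests
tiny_grid <- c(470, 500, 540, 560, 600, 660)
tiny_bands <- function() band_system(tiny_grid, diag(6), tiny_grid, "tiny6")

make_tiny_dataset <- function(n, seed, ranges = load_model_ranges("colon"),
                              n_photons = 1500) {
  simulate_labeled_dataset(ranges, n, tiny_grid,
                           default_extinction_table(),
                           n_photons = n_photons, seed = seed)
}
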