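#' Summarize absolute estimation errors
#'
#' Median and interquartile bounds of |estimate - truth| in percentage
#' points (type-7 linear-interpolation quantiles). Pairs with missing
#' estimates (e.g. undefined Beer-Lambert fits) are dropped from the
#' summary; `n_test` counts the pairs used.
#'
#' @param truth,estimate numeric vectors of fractions, equal length.
#' @param target label for the summarized quantity (`"s"` or `"v_hb"`).
#' @return one-row data frame with `target`, `median_abs_error`, `q25`,
#'   `q75` (percentage points) and `n_test`.
#' @export
error_summary <- function(truth, estimate, target = "s") {
  if (length(truth) == 0 || length(truth) != length(estimate)) {
    stop("truth and estimate must be non-empty vectors of equal length")
  }
  ok <- !is.na(estimate) & !is.na(truth)
  err <- abs(estimate[ok] - truth[ok]) * 100
  if (length(err) == 0) stop("no valid truth/estimate pairs")
  q <- quantile(err, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(target = target, median_abs_error = q[2],
             q25 = q[1], q75 = q[3], n_test = length(err))
}

#' Simulate a labeled reflectance dataset from a tissue model
#'
#' Draws tissue samples from the parameter ranges and runs the Monte Carlo
#' forward simulation for each — the raw material for training and testing
#' the inverse models.
#'
#' @param ranges a [parameter_ranges][load_model_ranges] object.
#' @param n number of samples.
#' @param wavelength_grid simulation wavelengths (nm).
#' @param table a [chromophore_table][load_extinction_table].
#' @param n_photons photon packets per wavelength.
#' @param seed integer seed (drives both the tissue draw and the MC
#'   streams; use different seeds for train and test sets).
#' @param ... passed on to [batch_simulate()] (e.g. `cache_dir`,
#'   `progress_every`).
#' @return list with `samples`, `labels` (data frame `s`, `v_hb`),
#'   `wavelength_nm`, `r` and `variance` matrices.
#' @export
simulate_labeled_dataset <- function(ranges, n,
                                     wavelength_grid = default_wavelength_grid(),
                                     table = default_extinction_table(),
                                     n_photons = 1e6, seed = 1, ...) {
  samples <- sample_tissue(ranges, n, seed = seed)
  config <- simulation_config(n_photons = n_photons, seed = seed)
  sim <- batch_simulate(samples, wavelength_grid, table, config, ...)
  list(samples = samples, labels = tissue_labels(samples),
       wavelength_nm = wavelength_grid, r = sim$r, variance = sim$variance)
}

#' Band-integrate a simulated dataset, inject noise and normalize
#'
#' The adapter between forward-simulated spectra and the regressors.
#' Returns the noisy band matrix alongside the normalized features: the
#' Beer-Lambert baseline consumes band values, the learned regressors
#' consume features.
#'
#' @param dataset a dataset from [simulate_labeled_dataset()].
#' @param bands a [band_system()].
#' @param snr signal-to-noise ratio for [add_noise()] (Inf = noiseless).
#' @param seed integer seed for the noise draw.
#' @return list with `features`, `bands_noisy` and `labels`.
#' @export
prepare_features <- function(dataset, bands, snr, seed) {
  B <- band_integrate(dataset$r, bands)
  Bn <- add_noise(B, snr, seed = seed)
  list(features = normalize_features(Bn), bands_noisy = Bn,
       labels = dataset$labels)
}

fit_method <- function(method, ts, hp, bands) {
  switch(method,
         rf = train_rf(ts, hp, bands = bands),
         svr = train_svr(ts, bands = bands),
         knn = train_knn(ts, bands = bands),
         stop("unknown method: ", method))
}

# One experimental condition: train at snr_train, test at snr_test, all
# requested methods on byte-identical test data. Returns report rows.
run_condition <- function(train_ds, test_ds, bands, snr_train, snr_test,
                          methods, hp, seed, table) {
  tr <- prepare_features(train_ds, bands, snr_train, seed = seed)
  te <- prepare_features(test_ds, bands, snr_test, seed = seed + 1L)
  ts <- training_set(tr$features, tr$labels)
  rows <- list()
  for (method in methods) {
    if (method == "beer_lambert") {
      s_hat <- beer_lambert_estimate(te$bands_noisy, bands, table)
      summ <- error_summary(te$labels$s, s_hat, "s")
      # v_hb cannot be measured by the baseline: no row is emitted for it
    } else {
      model <- fit_method(method, ts, hp, bands)
      pred <- predict(model, te$features, bands = bands)
      summ <- rbind(error_summary(te$labels$s, pred$s_hat, "s"),
                    error_summary(te$labels$v_hb, pred$v_hb_hat, "v_hb"))
    }
    summ$method <- method
    rows[[method]] <- summ
  }
  out <- do.call(rbind, rows)
  out$snr_train <- snr_train; out$snr_test <- snr_test
  out$n_train <- nrow(train_ds$labels)
  out$seed <- seed
  rownames(out) <- NULL
  out[, c("method", "target", "snr_train", "snr_test", "n_train", "n_test",
          "median_abs_error", "q25", "q75", "seed")]
}

#' Write an experiment report as CSV with a YAML provenance sidecar
#'
#' The CSV holds the report rows; `<path>.yaml` records the seeds and
#' conditions needed to re-run every row exactly.
#'
#' @param report a report data frame from [noise_sweep()],
#'   [domain_switch()], [sample_size_curve()] or [method_comparison()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  prov <- list(seeds = sort(unique(report$seed)),
               methods = sort(unique(report$method)),
               snr_train = unique(report$snr_train),
               snr_test = unique(report$snr_test),
               n_train = unique(report$n_train),
               written = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  yaml::write_yaml(lapply(prov, function(x) {
    if (is.numeric(x)) ifelse(is.finite(x), x, "Inf") else x
  }), paste0(path, ".yaml"))
  invisible(path)
}

#' Noise sweep experiment
#'
#' Sweeps the injected signal-to-noise ratio on the test data, either with
#' matched training noise (`train_snr = "matched"`: train and test share
#' each SNR) or with a fixed training SNR (probing train/test noise
#' mismatch). The random forest and the Beer-Lambert baseline (plus any
#' further methods requested) are evaluated on identical test sets.
#'
#' @param train_ds,test_ds datasets from [simulate_labeled_dataset()].
#' @param bands a [band_system()].
#' @param test_snrs SNR grid; the default brackets every regime of
#'   interest, from heavily degraded (2) to noiseless (Inf).
#' @param train_snr `"matched"` or a fixed numeric SNR.
#' @param methods methods to evaluate (`"rf"`, `"svr"`, `"knn"`,
#'   `"beer_lambert"`).
#' @param hp [rf_hyperparams()] for the forest.
#' @param seed integer seed for noise injection and training.
#' @param table a [chromophore_table][load_extinction_table].
#' @return experiment report data frame, one row per
#'   (SNR, method, target).
#' @export
noise_sweep <- function(train_ds, test_ds, bands,
                        test_snrs = c(2, 5, 10, 20, 50, 100, Inf),
                        train_snr = "matched",
                        methods = c("rf", "beer_lambert"),
                        hp = rf_hyperparams(), seed = 1,
                        table = default_extinction_table()) {
  rows <- lapply(seq_along(test_snrs), function(i) {
    snr_te <- test_snrs[i]
    snr_tr <- if (identical(train_snr, "matched")) snr_te else train_snr
    run_condition(train_ds, test_ds, bands, snr_tr, snr_te,
                  methods, hp, seed = seed + 10L * i, table = table)
  })
  do.call(rbind, rows)
}

#' Domain switch experiment
#'
#' Trains on one tissue model and tests on another (or the same), probing
#' robustness to model misspecification — e.g. colon-model training applied
#' to generic-model tissue whose blood volume fractions reach far outside
#' the training range.
#'
#' @param train_ranges,test_ranges [parameter_ranges][load_model_ranges]
#'   objects; pass the same object for a within-model control.
#' @param n_train,n_test sample counts.
#' @param wavelength_grid,table,n_photons forwarded to
#'   [simulate_labeled_dataset()].
#' @param bands a [band_system()].
#' @param snr matched train/test SNR.
#' @param methods,hp,seed as in [noise_sweep()].
#' @return experiment report data frame.
#' @export
domain_switch <- function(train_ranges, test_ranges,
                          n_train = 15000, n_test = 5000,
                          wavelength_grid = default_wavelength_grid(),
                          table = default_extinction_table(),
                          n_photons = 1e6,
                          bands = boxcar_band_system(grid = wavelength_grid),
                          snr = 10,
                          methods = c("rf", "beer_lambert"),
                          hp = rf_hyperparams(), seed = 1) {
  train_ds <- simulate_labeled_dataset(train_ranges, n_train, wavelength_grid,
                                       table, n_photons, seed = seed)
  test_ds <- simulate_labeled_dataset(test_ranges, n_test, wavelength_grid,
                                      table, n_photons, seed = seed + 1000L)
  out <- run_condition(train_ds, test_ds, bands, snr, snr, methods, hp,
                       seed = seed, table = table)
  out$train_model <- train_ranges$name
  out$test_model <- test_ranges$name
  out
}

#' Training-set size curve
#'
#' Re-trains the forest on nested subsets (smaller subsets are contained in
#' larger ones, isolating the sample-size effect) and evaluates each on the
#' same fixed test set.
#'
#' @param train_ds,test_ds datasets from [simulate_labeled_dataset()].
#' @param sizes training-set sizes (capped at the dataset size).
#' @param bands a [band_system()].
#' @param snr matched train/test SNR.
#' @param hp,seed,table as in [noise_sweep()].
#' @return experiment report data frame with an `n_train` column.
#' @export
sample_size_curve <- function(train_ds, test_ds, sizes, bands, snr = 10,
                              hp = rf_hyperparams(), seed = 1,
                              table = default_extinction_table()) {
  sizes <- sort(pmin(sizes, nrow(train_ds$labels)))
  tr <- prepare_features(train_ds, bands, snr, seed = seed)
  te <- prepare_features(test_ds, bands, snr, seed = seed + 1L)
  rows <- lapply(sizes, function(p) {
    idx <- seq_len(p)  # nested subsets by construction
    ts <- training_set(tr$features[idx, , drop = FALSE],
                       tr$labels[idx, , drop = FALSE])
    hp_p <- hp
    # degenerate subset sizes still run, with the leaf bound scaled down
    hp_p$min_samples_leaf <- min(hp$min_samples_leaf, max(1, floor(p / 2)))
    model <- train_rf(ts, hp_p, bands = bands)
    pred <- predict(model, te$features, bands = bands)
    out <- rbind(error_summary(te$labels$s, pred$s_hat, "s"),
                 error_summary(te$labels$v_hb, pred$v_hb_hat, "v_hb"))
    out$method <- "rf"; out$n_train <- p
    out$snr_train <- snr; out$snr_test <- snr; out$seed <- seed
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("method", "target", "snr_train", "snr_test", "n_train", "n_test",
          "median_abs_error", "q25", "q75", "seed")]
}

#' Controlled comparison of regression methods
#'
#' All methods are trained and evaluated on byte-identical feature/test
#' data. Wall-clock seconds per method are recorded for information only.
#'
#' @param train_ds,test_ds datasets from [simulate_labeled_dataset()].
#' @param bands a [band_system()].
#' @param snr matched train/test SNR.
#' @param methods methods to compare.
#' @param hp,seed,table as in [noise_sweep()].
#' @return experiment report data frame with a `seconds` column.
#' @export
method_comparison <- function(train_ds, test_ds, bands, snr = 10,
                              methods = c("rf", "svr", "knn", "beer_lambert"),
                              hp = rf_hyperparams(), seed = 1,
                              table = default_extinction_table()) {
  rows <- lapply(methods, function(m) {
    t0 <- proc.time()[["elapsed"]]
    out <- run_condition(train_ds, test_ds, bands, snr, snr, m, hp,
                         seed = seed, table = table)
    out$seconds <- proc.time()[["elapsed"]] - t0
    out
  })
  do.call(rbind, rows)
}
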