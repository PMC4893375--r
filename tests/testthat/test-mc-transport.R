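tab <- default_extinction_table()

test_that("pure absorber returns no diffuse reflectance", {
  layers <- list(list(mu_a = 30, mu_s = 0, g = 0.9, n_refr = 1.36, d_cm = 0.05),
                 list(mu_a = 10, mu_s = 0, g = 0.9, n_refr = 1.38, d_cm = 0.05))
  res <- simulate_reflectance(layers, simulation_config(n_photons = 5e3, seed = 1))
  expect_identical(res$r_d, 0)
})

test_that("matched refractive indices give zero specular reflection", {
  layers <- list(list(mu_a = 5, mu_s = 100, g = 0.8, n_refr = 1.0, d_cm = 0.1))
  res <- simulate_reflectance(layers, simulation_config(n_photons = 5e3, seed = 1))
  expect_identical(res$r_spec, 0)
  layers2 <- list(list(mu_a = 5, mu_s = 100, g = 0.8, n_refr = 1.4, d_cm = 0.1))
  res2 <- simulate_reflectance(layers2, simulation_config(n_photons = 5e3, seed = 1))
  expect_gt(res2$r_spec, ((1.4 - 1) / (1.4 + 1))^2 * 0.999)
})

test_that("simulations are deterministic in (seed, stream) and vary across them", {
  layers <- list(list(mu_a = 3, mu_s = 120, g = 0.85, n_refr = 1.36, d_cm = 0.08))
  cfg <- simulation_config(n_photons = 2e4, seed = 11)
  a <- simulate_reflectance(layers, cfg, stream = 5)
  b <- simulate_reflectance(layers, cfg, stream = 5)
  expect_identical(a, b)
  c1 <- simulate_reflectance(layers, cfg, stream = 6)
  expect_false(identical(a$r_d, c1$r_d))
  d1 <- simulate_reflectance(layers, simulation_config(n_photons = 2e4, seed = 12),
                             stream = 5)
  expect_false(identical(a$r_d, d1$r_d))
})

test_that("energy is conserved within Monte Carlo tolerance", {
  cfg <- simulation_config(n_photons = 1e5, seed = 21)
  configs <- list(
    list(list(mu_a = 10, mu_s = 90, g = 0.75, n_refr = 1.0, d_cm = 0.02)),
    list(list(mu_a = 1, mu_s = 300, g = 0.95, n_refr = 1.4, d_cm = 0.15)),
    list(list(mu_a = 8, mu_s = 150, g = 0.85, n_refr = 1.36, d_cm = 0.08),
         list(mu_a = 4, mu_s = 120, g = 0.9, n_refr = 1.38, d_cm = 0.06)))
  for (layers in configs) {
    res <- simulate_reflectance(layers, cfg)
    total <- res$r_d + res$r_spec + res$transmittance + res$absorbed + res$lost
    # roulette makes the per-run sum stochastic around unity
    expect_lt(abs(total - 1), 0.005)
  }
})

test_that("diffuse reflectance agrees with the independent slab oracle", {
  # classic benchmark slab: oracle values frozen from
  # mc_slab_oracle(10, 90, 0.75, 1.0, 0.02, 1e6, seed = 12345)
  # (r_d 0.097258, transmittance 0.660932; tabulated radiative-transfer
  # reference r_d 0.09739, t 0.66096)
  res <- simulate_reflectance(
    list(list(mu_a = 10, mu_s = 90, g = 0.75, n_refr = 1.0, d_cm = 0.02)),
    simulation_config(n_photons = 4e6, seed = 42))
  expect_lt(abs(res$r_d - 0.097258), 1e-3)        # 3 significant figures
  expect_lt(abs(res$transmittance - 0.660932), 1.5e-3)

  # index-mismatched slab: frozen from
  # mc_slab_oracle(2, 150, 0.9, 1.4, 0.1, 2e5, seed = 22): r_d 0.21088
  res2 <- simulate_reflectance(
    list(list(mu_a = 2, mu_s = 150, g = 0.9, n_refr = 1.4, d_cm = 0.1)),
    simulation_config(n_photons = 5e5, seed = 43))
  expect_lt(abs(res2$r_d - 0.21088), 3.5e-3)  # combined 3 sigma
})

test_that("oracle helper conserves energy on a fresh configuration", {
  res <- mc_slab_oracle(mu_a = 5, mu_s = 80, g = 0.6, n_refr = 1.3,
                        d_cm = 0.05, n_photons = 2e4, seed = 5)
  expect_lt(abs(res$r_d + res$r_spec + res$transmittance + res$absorbed - 1),
            0.01)
  ours <- simulate_reflectance(
    list(list(mu_a = 5, mu_s = 80, g = 0.6, n_refr = 1.3, d_cm = 0.05)),
    simulation_config(n_photons = 2e5, seed = 6))
  expect_lt(abs(res$r_d - ours$r_d), 3 * sqrt(0.1 * 0.9 / 2e4) + 3 * sqrt(ours$variance))
})

test_that("estimator variance scales as 1/n_photons", {
  layers <- list(list(mu_a = 5, mu_s = 120, g = 0.85, n_refr = 1.36, d_cm = 0.08))
  rd_at <- function(n, k) {
    vapply(seq_len(k), function(i) {
      simulate_reflectance(layers, simulation_config(n_photons = n, seed = 77),
                           stream = i)$r_d
    }, numeric(1))
  }
  v_small <- var(rd_at(1e3, 24))
  v_large <- var(rd_at(1e4, 24))
  ratio <- v_small / v_large
  expect_gt(ratio, 3)    # a decade of photons spans the 10x expectation
  expect_lt(ratio, 33)
  # the reported variance tracks the empirical one
  one <- simulate_reflectance(layers, simulation_config(n_photons = 1e4, seed = 77))
  expect_lt(abs(sqrt(one$variance) / sd(rd_at(1e4, 24)) - 1), 0.6)
})

test_that("optically thick bottom layers saturate the reflectance", {
  mk <- function(d) list(
    list(mu_a = 4, mu_s = 150, g = 0.85, n_refr = 1.36, d_cm = 0.05),
    list(mu_a = 4, mu_s = 150, g = 0.85, n_refr = 1.36, d_cm = d))
  cfg <- simulation_config(n_photons = 1e5, seed = 31)
  a <- simulate_reflectance(mk(1), cfg, stream = 1)
  b <- simulate_reflectance(mk(2), cfg, stream = 2)
  expect_lt(abs(a$r_d - b$r_d), 3 * (sqrt(a$variance) + sqrt(b$variance)))
})

test_that("relabeling identical layers leaves reflectance invariant", {
  half <- list(mu_a = 6, mu_s = 110, g = 0.85, n_refr = 1.36, d_cm = 0.04)
  cfg <- simulation_config(n_photons = 1e5, seed = 51)
  one <- simulate_reflectance(list(modifyList(half, list(d_cm = 0.08))), cfg,
                              stream = 1)
  two <- simulate_reflectance(list(half, half), cfg, stream = 2)
  expect_lt(abs(one$r_d - two$r_d),
            3 * (sqrt(one$variance) + sqrt(two$variance)))
})

test_that("spectra carry hemoglobin signatures only when blood is present", {
  grid <- c(470, 500, 560, 600, 660, 700)
  cfg <- simulation_config(n_photons = 1e4, seed = 61)
  bloodless <- tissue_sample(list(
    layer_properties(0, 0.5, 18.9, 1.286, 0.85, 1.36, 900),
    layer_properties(0, 0.5, 18.9, 1.286, 0.85, 1.38, 600)))
  sp0 <- simulate_spectrum(bloodless, grid, tab, cfg)
  # no hemoglobin features: reflectance follows the gentle monotone decline
  # of the scattering power law, with no absorption dip at 560 nm
  expect_true(all(diff(sp0$r) < 0.02))
  expect_lt((max(sp0$r) - min(sp0$r)) / mean(sp0$r), 0.3)

  perfused <- tissue_sample(list(
    layer_properties(0.10, 0.5, 18.9, 1.286, 0.85, 1.36, 900),
    layer_properties(0.10, 0.5, 18.9, 1.286, 0.85, 1.38, 600)))
  sp1 <- simulate_spectrum(perfused, grid, tab, cfg)
  # strong hemoglobin absorption near 560 nm depresses the green band
  expect_lt(sp1$r[grid == 560], sp1$r[grid == 660])
  expect_lt(sp1$r[grid == 560], sp1$r[grid == 700])

  expect_identical(sp1$r, simulate_spectrum(perfused, grid, tab, cfg)$r)
})

test_that("batch simulation caches and resumes losslessly", {
  rngs <- load_model_ranges("colon")
  samples <- sample_tissue(rngs, 3, seed = 8)
  grid <- c(500, 560, 620)
  cfg <- simulation_config(n_photons = 2e3, seed = 9)
  cache <- file.path(tempfile("mcti_cache"))
  fresh <- batch_simulate(samples, grid, tab, cfg)
  partial <- batch_simulate(samples[1:2], grid, tab, cfg, cache_dir = cache)
  resumed <- batch_simulate(samples, grid, tab, cfg, cache_dir = cache)
  expect_identical(resumed$r, fresh$r)
  expect_identical(partial$r, fresh$r[1:2, ])
  unlink(cache, recursive = TRUE)

  # the stream-seeding contract makes worker count irrelevant
  par2 <- batch_simulate(samples, grid, tab, cfg, n_workers = 2)
  expect_identical(par2$r, fresh$r)
})
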