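tab <- default_extinction_table()

test_that("absorption coefficient follows the hemoglobin mixing law", {
  # no absorber, no absorption; linear in v_hb; affine endpoints in s
  expect_identical(absorption_coefficient(0, 0.5, 500, tab), 0)
  expect_identical(absorption_coefficient(0, 0, 660, tab), 0)

  mu1 <- absorption_coefficient(0.03, 0.4, 540, tab)
  expect_equal(absorption_coefficient(0.06, 0.4, 540, tab), 2 * mu1)

  # manual evaluation against the bundled table row at 500 nm
  raw <- read.csv(system.file("extdata", "hemoglobin_extinction_synthetic.csv",
                              package = "mcti"), comment.char = "#")
  row <- raw[raw$wavelength_nm == 500, ]
  expected <- 0.05 * (120 / 64500) *
    (0.5 * row$eps_hbo2 + 0.5 * row$eps_hb) * log(10)
  expect_equal(absorption_coefficient(0.05, 0.5, 500, tab), expected)

  # s endpoints reduce to the pure-species extinctions
  eps <- extinction_at(tab, 560)
  c_molar <- 120 / 64500
  expect_equal(absorption_coefficient(0.02, 1, 560, tab),
               0.02 * c_molar * eps$eps_hbo2 * log(10))
  expect_equal(absorption_coefficient(0.02, 0, 560, tab),
               0.02 * c_molar * eps$eps_hb * log(10))

  expect_error(absorption_coefficient(-0.1, 0.5, 500, tab), "v_hb")
  expect_error(absorption_coefficient(0.1, 1.5, 500, tab), "s must")
  expect_error(absorption_coefficient(0.1, 0.5, 4000, tab), "range")
})

test_that("reduced scattering follows the power law", {
  expect_equal(reduced_scattering(18.9, 1.286, 500), 18.9)
  expect_equal(reduced_scattering(7, 0, c(450, 500, 720)), rep(7, 3))
  # independent arbitrary-precision evaluation, frozen
  expect_equal(reduced_scattering(18.9, 1.286, 720), 11.825177, tolerance = 1e-6)
  # monotone decreasing in wavelength for positive scattering power
  mu <- reduced_scattering(18.9, 1.286, seq(450, 720, 10))
  expect_true(all(diff(mu) < 0))
  expect_error(reduced_scattering(0, 1.286, 500), "a_mie")
})

test_that("scattering coefficient rescales by the anisotropy", {
  expect_equal(scattering_coefficient(12, 0), 12)
  expect_equal(scattering_coefficient(10, 0.9), 100)
  expect_equal(scattering_coefficient(18.9, 0.875), 151.2)
  expect_error(scattering_coefficient(10, 1), "g must")
})

test_that("optical-property conversion composes the three laws", {
  ly <- layer_properties(v_hb = 0.05, s = 0.7, a_mie = 20, b = 1.286,
                         g = 0.88, n_refr = 1.36, d_um = 805)
  op <- to_optical_properties(ly, 520, tab)
  expect_equal(op$mu_a, absorption_coefficient(0.05, 0.7, 520, tab))
  expect_equal(op$mu_s,
               scattering_coefficient(reduced_scattering(20, 1.286, 520), 0.88))
  expect_equal(op$g, 0.88)
  expect_equal(op$d_cm, 0.0805)  # micrometers to centimeters exactly once

  ly0 <- layer_properties(v_hb = 0, s = 0.5, a_mie = 15, b = 1.1,
                          g = 0, n_refr = 1.4, d_um = 500)
  op0 <- to_optical_properties(ly0, 600, tab)
  expect_identical(op0$mu_a, 0)
  expect_equal(op0$mu_s, reduced_scattering(15, 1.1, 600))
})

test_that("tissue samples enforce one shared oxygenation", {
  l1 <- layer_properties(0.05, 0.5, 18, 1.286, 0.85, 1.36, 700)
  l2 <- layer_properties(0.02, 0.8, 18, 1.286, 0.85, 1.36, 700)
  expect_error(tissue_sample(list(l1, l2)), "share one oxygenation")
  expect_s3_class(tissue_sample(list(l1, l1)), "tissue_sample")
  expect_error(tissue_sample(list()), "at least one layer")
})

test_that("bundled colon config reproduces the published parameter ranges", {
  rng <- load_model_ranges("colon")
  expect_equal(length(rng$layers), 3)
  expect_equal(rng$c_hb_gram_per_liter, 120)
  expect_equal(rng$b_fixed, 1.286)
  for (l in 1:3) {
    expect_equal(rng$layers[[l]]$v_hb, c(0, 0.10))
    expect_equal(rng$layers[[l]]$s, c(0, 1))
    expect_equal(rng$layers[[l]]$a_mie, c(8.7, 29.1))  # 18.9 +/- 10.2
    expect_equal(rng$layers[[l]]$g, c(0.80, 0.95))
  }
  expect_equal(rng$layers[[1]]$n_refr, c(1.36, 1.36))
  expect_equal(rng$layers[[3]]$n_refr, c(1.38, 1.38))
  expect_equal(rng$layers[[1]]$d, c(600, 1010))
  expect_equal(rng$layers[[2]]$d, c(415, 847))
  expect_equal(rng$layers[[3]]$d, c(395, 603))

  gen <- load_model_ranges("generic")
  expect_equal(gen$max_total_thickness_um, 2000)
  for (l in 1:3) {
    expect_equal(gen$layers[[l]]$v_hb, c(0, 1))
    expect_equal(gen$layers[[l]]$n_refr, c(1.33, 1.54))
    expect_equal(gen$layers[[l]]$d, c(0, 2000))
  }
})

test_that("tissue sampling stays in range, shares s, and is deterministic", {
  rng <- load_model_ranges("colon")
  samples <- sample_tissue(rng, 500, seed = 42)
  df <- samples_to_frame(samples)
  expect_true(all(df$layer1_v_hb >= 0 & df$layer1_v_hb <= 0.1))
  expect_true(all(df$layer2_a_mie >= 8.7 & df$layer2_a_mie <= 29.1))
  expect_true(all(df$layer3_d_um >= 395 & df$layer3_d_um <= 603))
  expect_true(all(df$layer1_b == 1.286))
  # shared oxygenation across the three layers
  s_by_layer <- vapply(samples, function(x)
    max(abs(diff(vapply(x$layers, `[[`, numeric(1), "s")))), numeric(1))
  expect_true(all(s_by_layer == 0))

  expect_identical(samples_to_frame(sample_tissue(rng, 500, seed = 42)), df)
  expect_false(identical(samples_to_frame(sample_tissue(rng, 500, seed = 43)), df))
})

test_that("sampled marginals fill their ranges and seeds are independent", {
  rng <- load_model_ranges("colon")
  df <- samples_to_frame(sample_tissue(rng, 2e4, seed = 7))
  # empirical extremes within 1% of the range endpoints
  expect_lt(min(df$layer1_v_hb), 0.001)
  expect_gt(max(df$layer1_v_hb), 0.099)
  expect_lt(min(df$s), 0.01)
  expect_gt(max(df$s), 0.99)
  span <- 29.1 - 8.7
  expect_lt(min(df$layer2_a_mie), 8.7 + 0.01 * span)
  expect_gt(max(df$layer2_a_mie), 29.1 - 0.01 * span)

  # disjoint seeds give statistically independent draws
  df2 <- samples_to_frame(sample_tissue(rng, 1e4, seed = 1234))
  ks <- suppressWarnings(ks.test(df$s[1:1e4], df2$s))
  expect_gt(ks$p.value, 0.01)
})

test_that("generic-model thickness is capped at 2 mm", {
  gen <- load_model_ranges("generic")
  df <- samples_to_frame(sample_tissue(gen, 2000, seed = 3))
  total <- df$layer1_d_um + df$layer2_d_um + df$layer3_d_um
  expect_true(all(total <= 2000 + 1e-6))
  expect_gt(max(total), 1999)  # the cap binds for some draws
})

test_that("truncated-normal scattering alternative stays positive", {
  rng <- load_model_ranges("colon")
  df <- samples_to_frame(sample_tissue(rng, 3000, seed = 9,
                                       a_mie_dist = "truncnorm"))
  expect_true(all(df$layer1_a_mie > 0))
  # normal draw reaches outside the uniform interval
  expect_gt(max(df$layer1_a_mie), 29.1)
})

test_that("extinction interpolation is linear between knots", {
  wl <- tab$wavelength_nm
  i <- which(wl == 520)
  expect_equal(extinction_at(tab, 520)$eps_hbo2, tab$eps_hbo2[i])
  mid <- (wl[i] + wl[i + 1]) / 2
  expect_equal(extinction_at(tab, mid)$eps_hb,
               (tab$eps_hb[i] + tab$eps_hb[i + 1]) / 2)
  # deoxygenated hemoglobin absorbs more at 560 nm
  eps560 <- extinction_at(tab, 560)
  expect_gt(eps560$eps_hb, eps560$eps_hbo2)
  expect_error(extinction_at(tab, 300), "range")
})
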