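#' Construct a multispectral image stack
#'
#' @param stack H x W x K array of raw intensities (one slice per band).
#' @param dark dark-current frame: H x W x K array, or a length-K vector of
#'   per-band scalars.
#' @param flatfield H x W x K reference frame of a uniform white target.
#' @param band_system_ref identifier of the band system the stack was
#'   recorded with.
#' @return a `multispectral_image`.
#' @export
multispectral_image <- function(stack, dark, flatfield, band_system_ref = NULL) {
  stopifnot(length(dim(stack)) == 3)
  K <- dim(stack)[3]
  if (is.null(dim(dark))) {
    stopifnot(length(dark) %in% c(1, K))
    dark <- array(rep(dark, each = prod(dim(stack)[1:2])), dim = dim(stack))
  }
  stopifnot(identical(dim(dark), dim(stack)),
            identical(dim(flatfield), dim(stack)))
  structure(list(stack = stack, dark = dark, flatfield = flatfield,
                 band_system_ref = band_system_ref),
            class = "multispectral_image")
}

#' Dark-current subtraction and flatfield division
#'
#' corrected = (stack - dark) / (flatfield - dark), per pixel and band —
#' removes the light-source spectrum, laparoscope optics and sensor
#' quantum efficiency from the measurement. Pixels where the flatfield
#' does not exceed the dark current in some band are flagged invalid.
#'
#' @param image a [multispectral_image()].
#' @return list with `reflectance` (H x W x K array) and `valid_mask`
#'   (H x W logical); invalid pixels hold `NA`.
#' @export
flatfield_correct <- function(image) {
  stopifnot(inherits(image, "multispectral_image"))
  denom <- image$flatfield - image$dark
  bad <- apply(denom <= 0, c(1, 2), any)
  refl <- (image$stack - image$dark) / denom
  refl[array(bad, dim = dim(refl))] <- NA_real_
  list(reflectance = refl, valid_mask = !bad)
}

#' Specular highlight mask
#'
#' A pixel is masked when any band exceeds `threshold` times that band's
#' robust maximum (99.9th percentile) — mirror-like reflections saturate
#' toward the illumination spectrum and carry no subsurface information.
#' Masks are monotone in the threshold: lowering it can only mask more.
#'
#' @param reflectance H x W x K reflectance array.
#' @param threshold fraction of the per-band robust maximum, in (0, 1].
#' @return H x W logical matrix, `TRUE` where specular.
#' @export
specular_mask <- function(reflectance, threshold = 0.95) {
  stopifnot(threshold > 0, threshold <= 1)
  K <- dim(reflectance)[3]
  robust_max <- vapply(seq_len(K), function(k) {
    quantile(reflectance[, , k], 0.999, na.rm = TRUE, names = FALSE)
  }, numeric(1))
  over <- vapply(seq_len(K), function(k) {
    reflectance[, , k] > threshold * robust_max[k]
  }, matrix(logical(1), dim(reflectance)[1], dim(reflectance)[2]))
  apply(array(over, dim = dim(reflectance)), c(1, 2), any, na.rm = TRUE)
}

#' Block-mean downsampling of an image stack
#'
#' @param reflectance H x W x K array (H, W divisible by `factor`).
#' @param factor integer downsampling factor per axis.
#' @return downsampled array.
#' @export
downsample_stack <- function(reflectance, factor = 2) {
  d <- dim(reflectance)
  stopifnot(d[1] %% factor == 0, d[2] %% factor == 0)
  h <- d[1] / factor; w <- d[2] / factor
  out <- array(NA_real_, c(h, w, d[3]))
  for (k in seq_len(d[3])) {
    m <- reflectance[, , k]
    dim(m) <- c(factor, h, factor, w)
    out[, , k] <- apply(m, c(2, 4), mean)
  }
  out
}

#' Per-pixel parameter estimation from a reflectance stack
#'
#' Applies the feature normalization and a trained regressor to every valid
#' pixel, producing oxygenation and blood-volume-fraction maps.
#'
#' @param reflectance H x W x K reflectance array (band-corrected).
#' @param model an [mcti_regressor][train_rf].
#' @param bands the [band_system()] the stack was recorded with; refused if
#'   it does not match the model.
#' @param valid_mask optional H x W logical of pixels to estimate; invalid
#'   pixels stay `NA`.
#' @return a `parameter_map`: list with `s_map`, `v_hb_map` (H x W) and
#'   `valid_mask`.
#' @export
estimate_map <- function(reflectance, model, bands, valid_mask = NULL) {
  d <- dim(reflectance)
  stopifnot(length(d) == 3)
  if (d[3] != length(bands$centers)) {
    stop("stack band count does not match the band system")
  }
  pix <- matrix(reflectance, nrow = d[1] * d[2], ncol = d[3])
  ok <- rowSums(!is.finite(pix)) == 0 & rowSums(abs(pix)) > 0
  if (!is.null(valid_mask)) ok <- ok & as.vector(valid_mask)
  s_map <- v_map <- rep(NA_real_, d[1] * d[2])
  if (any(ok)) {
    feats <- normalize_features(pix[ok, , drop = FALSE])
    pred <- predict(model, feats, bands = bands)
    s_map[ok] <- pred$s_hat
    v_map[ok] <- pred$v_hb_hat
  }
  structure(list(s_map = matrix(s_map, d[1], d[2]),
                 v_hb_map = matrix(v_map, d[1], d[2]),
                 valid_mask = matrix(ok, d[1], d[2])),
            class = "parameter_map")
}

#' ROI mean time series over a sequence of parameter maps
#'
#' @param maps time-ordered list of [estimate_map()] results (or `NA` for
#'   missing frames, which are preserved as gaps).
#' @param roi_mask H x W logical region of interest.
#' @return data frame with `frame`, `mean_s`, `mean_v_hb`, `n_pixels`;
#'   frames with no valid ROI pixel hold `NA`, never zero.
#' @export
roi_mean_series <- function(maps, roi_mask) {
  rows <- lapply(seq_along(maps), function(t) {
    m <- maps[[t]]
    if (!inherits(m, "parameter_map")) {
      return(data.frame(frame = t, mean_s = NA_real_, mean_v_hb = NA_real_,
                        n_pixels = 0L))
    }
    use <- roi_mask & m$valid_mask
    n <- sum(use)
    data.frame(frame = t,
               mean_s = if (n > 0) mean(m$s_map[use]) else NA_real_,
               mean_v_hb = if (n > 0) mean(m$v_hb_map[use]) else NA_real_,
               n_pixels = n)
  })
  do.call(rbind, rows)
}

#' Specification of a synthetic phantom image stack
#'
#' @param region_layout H x W integer matrix of region labels (1-based,
#'   tiling the image).
#' @param region_samples list of [tissue_sample()] objects, one per label.
#' @param snr band-noise SNR of the synthesized camera (Inf = noiseless).
#' @param specular_fraction fraction of pixels replaced by specular
#'   highlights.
#' @param dark_level per-band dark-current level (scalar or length K).
#' @param flat_level per-band flatfield level above dark (scalar or
#'   length K).
#' @param seed integer seed.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(region_layout, region_samples, snr = 10,
                         specular_fraction = 0, dark_level = 100,
                         flat_level = 3000, seed = 1) {
  stopifnot(is.matrix(region_layout),
            max(region_layout) <= length(region_samples),
            min(region_layout) >= 1,
            specular_fraction >= 0, specular_fraction < 1)
  structure(list(region_layout = region_layout,
                 region_samples = region_samples, snr = snr,
                 specular_fraction = specular_fraction,
                 dark_level = dark_level, flat_level = flat_level,
                 seed = seed),
            class = "phantom_spec")
}

#' Synthesize a multispectral phantom stack with known ground truth
#'
#' Runs the full forward chain for each region's tissue sample (Monte Carlo
#' spectrum, band integration), injects per-pixel band noise at the spec's
#' SNR, embeds the reflectance into raw camera counts as
#' dark + r * (flatfield - dark), and optionally replaces a random pixel
#' subset with saturated specular highlights. Ground-truth parameter maps
#' and the specular positions are returned alongside — the synthetic
#' stand-in for an in-vivo recording that makes the whole imaging path
#' testable.
#'
#' @param spec a [phantom_spec()].
#' @param bands a [band_system()] (e.g. [camera_band_system()]).
#' @param table a [chromophore_table][load_extinction_table].
#' @param config a [simulation_config()] for the per-region spectra.
#' @return list with `image` (a [multispectral_image()]), `truth`
#'   (a `parameter_map` with the ground-truth `s_map` / `v_hb_map`),
#'   `specular` (H x W logical) and `band_reflectance` (noiseless per-region
#'   K-vectors).
#' @export
synthesize_phantom <- function(spec, bands = camera_band_system(),
                               table = default_extinction_table(),
                               config = simulation_config(n_photons = 1e4)) {
  stopifnot(inherits(spec, "phantom_spec"))
  lay <- spec$region_layout
  H <- nrow(lay); W <- ncol(lay); K <- length(bands$centers)
  n_regions <- length(spec$region_samples)

  region_rk <- lapply(seq_len(n_regions), function(g) {
    sp <- simulate_spectrum(spec$region_samples[[g]], bands$grid, table,
                            config, sample_id = g)
    band_integrate(sp, bands)
  })

  refl <- array(NA_real_, c(H, W, K))
  for (g in seq_len(n_regions)) {
    idx <- which(lay == g)
    for (k in seq_len(K)) {
      slice <- refl[, , k]
      slice[idx] <- region_rk[[g]][k]
      refl[, , k] <- slice
    }
  }
  refl <- add_noise(refl, spec$snr, seed = spec$seed)

  truth_s <- matrix(vapply(spec$region_samples,
                           function(x) x$layers[[1]]$s, numeric(1))[lay], H, W)
  truth_v <- matrix(vapply(spec$region_samples,
                           function(x) x$layers[[1]]$v_hb, numeric(1))[lay], H, W)

  dark_k <- rep(spec$dark_level, length.out = K)
  flat_k <- rep(spec$flat_level, length.out = K)
  dark <- aperm(array(dark_k, c(K, H, W)), c(2, 3, 1))
  flat <- dark + aperm(array(flat_k, c(K, H, W)), c(2, 3, 1))

  raw <- dark + refl * (flat - dark)

  specular <- matrix(FALSE, H, W)
  if (spec$specular_fraction > 0) {
    n_spec <- max(1, round(spec$specular_fraction * H * W))
    idx <- with_local_seed(spec$seed + 1L,
                           function() sample.int(H * W, n_spec))
    specular[idx] <- TRUE
    for (k in seq_len(K)) {
      slice <- raw[, , k]
      slice[idx] <- dark_k[k] + 1.5 * flat_k[k]  # saturated highlight
      raw[, , k] <- slice
    }
  }

  img <- multispectral_image(raw, dark, flat, band_system_ref = bands$name)
  truth <- structure(list(s_map = truth_s, v_hb_map = truth_v,
                          valid_mask = !specular),
                     class = "parameter_map")
  list(image = img, truth = truth, specular = specular,
       band_reflectance = region_rk)
}

#' Read / write multispectral stacks as multi-page TIFF
#'
#' One page per band, band order following the band system. Values are
#' scaled by `scale` into the TIFF's \[0, 1\] float range on write and
#' unscaled on read.
#'
#' @param stack H x W x K array.
#' @param path TIFF file path.
#' @param scale intensity corresponding to 1.0 in the file.
#' @return `write_stack_tiff` returns `path` invisibly;
#'   `read_stack_tiff` returns the H x W x K array.
#' @export
write_stack_tiff <- function(stack, path, scale = max(stack)) {
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(k) pmin(pmax(stack[, , k] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- array(NA_real_, c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                           length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    out[, , k] <- pg * scale
  }
  out
}
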