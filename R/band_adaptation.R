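#' Construct a band system from explicit transmission weights
#'
#' @param centers K band center wavelengths (nm).
#' @param transmissions K x m matrix of non-negative weights on the
#'   simulation grid, each row with positive sum.
#' @param grid the m simulation wavelengths (nm).
#' @param name identifier stored with the system.
#' @return a `band_system`.
#' @export
band_system <- function(centers, transmissions, grid, name = "custom") {
  transmissions <- as.matrix(transmissions)
  stopifnot(length(centers) >= 2,
            nrow(transmissions) == length(centers),
            ncol(transmissions) == length(grid))
  if (any(transmissions < 0)) stop("band transmissions must be non-negative")
  if (any(rowSums(transmissions) <= 0)) {
    stop("every band needs positive total transmission on the grid")
  }
  structure(list(centers = centers, transmissions = transmissions,
                 grid = grid, name = name),
            class = "band_system")
}

#' @export
print.band_system <- function(x, ...) {
  cat(sprintf("<band_system> '%s': %d bands, centers %g-%g nm\n",
              x$name, length(x$centers), min(x$centers), max(x$centers)))
  invisible(x)
}

# Compact descriptor used to refuse predictions across mismatched systems.
# Identifies the measurement space (band count and centers), not the
# simulation grid the transmissions were tabulated on: a model trained on
# one camera's bands applies to that camera's measurements regardless of
# which grid produced the training spectra.
band_signature <- function(bands) {
  paste(bands$name, length(bands$centers),
        paste(format(bands$centers, digits = 10), collapse = ","),
        sep = "|")
}

#' Boxcar (sliding-average) band system
#'
#' Equal-weight averaging of all grid points within +/- width/2 of each
#' center — the idealized in-silico camera: by default 22 bands, 470-680 nm
#' in 10 nm steps, each a 10 nm sliding average.
#'
#' @param start_nm,stop_nm first and last band center (nm).
#' @param step_nm center spacing (nm).
#' @param width_nm full band width (nm).
#' @param grid simulation wavelength grid (nm).
#' @return a `band_system`.
#' @export
boxcar_band_system <- function(start_nm = 470, stop_nm = 680, step_nm = 10,
                               width_nm = 10,
                               grid = default_wavelength_grid()) {
  stopifnot(start_nm < stop_nm, width_nm > 0)
  centers <- seq(start_nm, stop_nm, by = step_nm)
  tr <- t(vapply(centers, function(cc) {
    w <- as.numeric(abs(grid - cc) <= width_nm / 2 + 1e-9)
    if (sum(w) == 0) stop("band system extends past the simulation grid")
    w / sum(w)
  }, numeric(length(grid))))
  band_system(centers, tr, grid, name = sprintf("boxcar%d", length(centers)))
}

#' The 8-band multispectral camera band system
#'
#' Gaussian transmission profiles at the camera's center wavelengths
#' 470, 480, 511, 560, 580, 600, 660 and 700 nm, FWHM 20 nm except the
#' 480 nm band (25 nm). Profiles are normalized to unit sum — absolute
#' throughput cancels in the l1 feature normalization anyway.
#'
#' @param grid simulation wavelength grid (nm).
#' @return a `band_system` with 8 bands.
#' @export
camera_band_system <- function(grid = default_wavelength_grid()) {
  centers <- c(470, 480, 511, 560, 580, 600, 660, 700)
  fwhm <- c(20, 25, 20, 20, 20, 20, 20, 20)
  sdev <- fwhm / (2 * sqrt(2 * log(2)))
  tr <- t(mapply(function(cc, sg) {
    w <- exp(-0.5 * ((grid - cc) / sg)^2)
    w / sum(w)
  }, centers, sdev))
  band_system(centers, tr, grid, name = "camera8")
}

#' Serialize / restore a band system as YAML
#'
#' Stores name, centers, grid and the full transmission matrix, so any
#' band system (including custom transmissions) round-trips exactly.
#'
#' @param bands a [band_system()].
#' @param path YAML file path.
#' @return `save_band_system` returns `path` invisibly;
#'   `load_band_system` returns the band system.
#' @export
save_band_system <- function(bands, path) {
  stopifnot(inherits(bands, "band_system"))
  yaml::write_yaml(
    list(name = bands$name, centers = as.numeric(bands$centers),
         grid = as.numeric(bands$grid),
         transmissions = lapply(seq_len(nrow(bands$transmissions)),
                                function(k) as.numeric(bands$transmissions[k, ]))),
    path, precision = 15)
  invisible(path)
}

#' @rdname save_band_system
#' @export
load_band_system <- function(path) {
  cfg <- yaml::read_yaml(path)
  band_system(cfg$centers, do.call(rbind, cfg$transmissions),
              cfg$grid, name = cfg$name)
}

#' Write a feature dataset as CSV
#'
#' One row per observation: normalized features `a1..aK` followed by the
#' labels `s` and `v_hb`.
#'
#' @param features matrix of normalized feature vectors.
#' @param labels data frame with columns `s` and `v_hb`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_feature_set <- function(features, labels, path) {
  df <- as.data.frame(features)
  names(df) <- sprintf("a%d", seq_len(ncol(df)))
  df$s <- labels$s
  df$v_hb <- labels$v_hb
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Integrate a spectrum over a band system
#'
#' r_k = sum_lambda b_k(lambda) r(lambda); linear in the spectrum.
#'
#' @param spectrum a `reflectance_spectrum`, or any list with
#'   `wavelength_nm` and `r`, or a plain numeric vector on the band grid.
#'   A matrix (rows = spectra on the band grid) is integrated row-wise.
#' @param bands a [band_system()].
#' @return numeric vector of K band values (or an n x K matrix).
#' @export
band_integrate <- function(spectrum, bands) {
  stopifnot(inherits(bands, "band_system"))
  if (is.matrix(spectrum)) {
    if (ncol(spectrum) != length(bands$grid)) {
      stop("spectrum matrix does not match the band-system grid")
    }
    return(spectrum %*% t(bands$transmissions))
  }
  if (is.list(spectrum)) {
    if (!isTRUE(all.equal(spectrum$wavelength_nm, bands$grid))) {
      stop("spectrum grid does not match the band-system grid")
    }
    r <- spectrum$r
  } else {
    r <- spectrum
    if (length(r) != length(bands$grid)) {
      stop("spectrum length does not match the band-system grid")
    }
  }
  as.numeric(bands$transmissions %*% r)
}

#' Add signal-proportional Gaussian noise to band measurements
#'
#' Each band value is perturbed by zero-mean Gaussian noise with standard
#' deviation r_k / SNR, computed from the noiseless value — the noise model
#' for camera read-out and motion nuisances. `snr = Inf` is the identity.
#'
#' @param r_k numeric vector of band values, or an n x K matrix.
#' @param snr signal-to-noise ratio, positive (Inf allowed).
#' @param seed integer seed (deterministic given seed); `NULL` uses the
#'   current RNG state.
#' @return noisy measurement of the same shape.
#' @export
add_noise <- function(r_k, snr, seed = NULL) {
  if (is.na(snr) || snr <= 0) stop("snr must be positive (or Inf)")
  if (is.infinite(snr)) return(r_k)
  with_local_seed(seed, function() {
    noise <- rnorm(length(r_k), mean = 0, sd = abs(as.numeric(r_k)) / snr)
    r_k + array(noise, dim = dim(r_k) %||% length(r_k))
  })
}

#' Normalize band measurements into absorption-domain feature vectors
#'
#' Three stages, in order: (1) l1 normalization r'_k = r_k / sum_j r_j —
#' cancels constant multiplicative changes from camera distance, angle and
#' intensity scaling; (2) transformation to absorption a_k = -log r'_k;
#' (3) l2 normalization of a. Non-positive band values (possible after
#' noise injection at low SNR) are clipped to 1e-6 of the measurement's l1
#' mass before the logarithm.
#'
#' @param r_k numeric vector of K >= 2 band values, or an n x K matrix
#'   (rows normalized independently).
#' @return unit-l2-norm feature vector (or matrix of row vectors).
#' @export
normalize_features <- function(r_k) {
  one <- function(r) {
    if (length(r) < 2) stop("need at least two bands")
    l1 <- sum(abs(r))
    if (l1 == 0) stop("all-zero band measurement cannot be normalized")
    r <- pmax(r, 1e-6 * l1)
    a <- -log(r / sum(r))
    a / sqrt(sum(a^2))
  }
  if (is.matrix(r_k)) t(apply(r_k, 1, one)) else one(r_k)
}
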