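#' Absorption coefficient of hemoglobin-perfused tissue
#'
#' mu_a(v_hb, s, lambda) = v_hb * c_hb_molar *
#' (s * eps_HbO2(lambda) + (1 - s) * eps_Hb(lambda)) * ln(10), with
#' c_hb_molar the molar hemoglobin concentration of whole blood. Hemoglobin
#' is assumed to be the only notable absorber in the visible range for
#' internal (non-melanin-bearing) tissue; further chromophores would enter
#' this sum additively.
#'
#' @param v_hb blood volume fraction in \[0, 1\].
#' @param s oxygenation (fraction of oxygen-bound hemoglobin) in \[0, 1\].
#' @param lambda_nm wavelength(s) in nm, within the table range.
#' @param table a [chromophore_table][load_extinction_table].
#' @return absorption coefficient(s) in cm^-1.
#' @export
absorption_coefficient <- function(v_hb, s, lambda_nm, table) {
  if (any(v_hb < 0) || any(v_hb > 1)) stop("v_hb must be in [0, 1]")
  if (any(s < 0) || any(s > 1)) stop("s must be in [0, 1]")
  eps <- extinction_at(table, lambda_nm)
  c_molar <- table$c_hb_gram_per_liter / table$hb_molar_mass_gram_per_mol
  v_hb * c_molar * (s * eps$eps_hbo2 + (1 - s) * eps$eps_hb) * log(10)
}

#' Reduced scattering coefficient by the soft-tissue power law
#'
#' mu_s'(lambda) = a_mie * (lambda / 500 nm)^(-b). Scattering by large
#' ("Mie-regime") particles dominates soft tissue in the visible range,
#' which this single power law captures; `a_mie` is the reduced scattering
#' at the 500 nm reference wavelength.
#'
#' @param a_mie scattering amplitude at 500 nm (cm^-1), positive.
#' @param b scattering power (dimensionless).
#' @param lambda_nm wavelength(s) in nm.
#' @return reduced scattering coefficient(s) in cm^-1.
#' @export
reduced_scattering <- function(a_mie, b, lambda_nm) {
  if (any(a_mie <= 0)) stop("a_mie must be positive")
  a_mie * (lambda_nm / 500)^(-b)
}

#' Scattering coefficient from reduced scattering and anisotropy
#'
#' mu_s = mu_s' / (1 - g), with g the mean cosine of the single-scattering
#' deflection angle (g -> 1 is strongly forward scattering).
#'
#' @param mu_s_prime reduced scattering coefficient (cm^-1).
#' @param g anisotropy factor, 0 <= g < 1.
#' @return scattering coefficient in cm^-1.
#' @export
scattering_coefficient <- function(mu_s_prime, g) {
  if (any(g < 0) || any(g >= 1)) stop("g must satisfy 0 <= g < 1")
  mu_s_prime / (1 - g)
}

#' Construct a single tissue layer
#'
#' @param v_hb blood volume fraction, \[0, 1\].
#' @param s oxygenation, \[0, 1\].
#' @param a_mie scattering amplitude at 500 nm (cm^-1), positive.
#' @param b scattering power.
#' @param g anisotropy, 0 <= g < 1.
#' @param n_refr refractive index, >= 1.
#' @param d_um layer thickness in micrometers, positive.
#' @return a `layer_properties` list.
#' @export
layer_properties <- function(v_hb, s, a_mie, b, g, n_refr, d_um) {
  stopifnot(v_hb >= 0, v_hb <= 1, s >= 0, s <= 1, a_mie > 0,
            g >= 0, g < 1, n_refr >= 1, d_um > 0)
  structure(list(v_hb = v_hb, s = s, a_mie = a_mie, b = b, g = g,
                 n_refr = n_refr, d_um = d_um),
            class = "layer_properties")
}

#' Construct a layered tissue sample
#'
#' An ordered stack of layers, top (illuminated) layer first. Oxygenation is
#' shared by all layers — the layers of one organ draw on a common blood
#' supply, so a single `s` describes the whole stack.
#'
#' @param layers list of [layer_properties()] objects, top first.
#' @return a `tissue_sample`.
#' @export
tissue_sample <- function(layers) {
  if (length(layers) < 1) stop("a tissue sample needs at least one layer")
  stopifnot(all(vapply(layers, inherits, logical(1), "layer_properties")))
  s_values <- vapply(layers, `[[`, numeric(1), "s")
  if (max(s_values) - min(s_values) > 1e-12) {
    stop("all layers of a tissue sample must share one oxygenation value")
  }
  structure(list(layers = layers), class = "tissue_sample")
}

#' @export
print.tissue_sample <- function(x, ...) {
  cat(sprintf("<tissue_sample> %d layers, s = %.3f\n",
              length(x$layers), x$layers[[1]]$s))
  invisible(x)
}

#' Convert a layer to wavelength-resolved optical properties
#'
#' Combines the absorption and scattering laws into the per-layer input of
#' the photon-transport simulation; thickness is converted from micrometers
#' to centimeters here (and only here).
#'
#' @param layer a [layer_properties()] object.
#' @param lambda_nm a single wavelength in nm.
#' @param table a [chromophore_table][load_extinction_table].
#' @return list with `mu_a`, `mu_s` (cm^-1), `g`, `n_refr`, `d_cm`.
#' @export
to_optical_properties <- function(layer, lambda_nm, table) {
  mu_sp <- reduced_scattering(layer$a_mie, layer$b, lambda_nm)
  list(mu_a = absorption_coefficient(layer$v_hb, layer$s, lambda_nm, table),
       mu_s = scattering_coefficient(mu_sp, layer$g),
       g = layer$g,
       n_refr = layer$n_refr,
       d_cm = layer$d_um * 1e-4)
}

#' Load per-layer parameter ranges from a YAML model config
#'
#' The package bundles `colon_model.yaml` (three-layer colon model, fixed
#' refractive indices, b fixed at 1.286) and `generic_model.yaml` (wide
#' ranges covering e.g. hypervascularized malignancies, total thickness
#' capped at 2 mm).
#'
#' @param path YAML file path, or one of `"colon"` / `"generic"` for the
#'   bundled configs.
#' @return a `parameter_ranges` object.
#' @export
load_model_ranges <- function(path = "colon") {
  if (path %in% c("colon", "generic")) {
    path <- system.file("extdata", paste0(path, "_model.yaml"),
                        package = "mcti", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$layers) || length(cfg$layers) < 1) {
    stop("model config defines no layers")
  }
  layers <- lapply(cfg$layers, function(ly) {
    lapply(ly, function(rng) {
      rng <- as.numeric(rng)
      if (length(rng) == 1) rng <- c(rng, rng)
      if (rng[1] > rng[2]) stop("range minimum exceeds maximum")
      rng
    })
  })
  structure(
    list(name = cfg$name %||% "model",
         c_hb_gram_per_liter = cfg$c_hb_gram_per_liter %||% 120,
         shared_s = isTRUE(cfg$shared_s),
         b_fixed = cfg$b_fixed,
         max_total_thickness_um = as.numeric(cfg$max_total_thickness_um %||% Inf),
         layers = layers),
    class = "parameter_ranges")
}

#' @export
print.parameter_ranges <- function(x, ...) {
  cat(sprintf("<parameter_ranges> '%s', %d layers, c_hb = %g g/L\n",
              x$name, length(x$layers), x$c_hb_gram_per_liter))
  invisible(x)
}

#' Draw random tissue samples from parameter ranges
#'
#' Each per-layer parameter is drawn independently and uniformly from its
#' range, except oxygenation `s`, which is drawn once per sample and shared
#' by all layers. Where the config caps the total stack thickness
#' (`max_total_thickness_um`), layer thicknesses exceeding the cap in sum
#' are rescaled proportionally. The scattering amplitude can alternatively
#' be drawn from a truncated normal centered on the range midpoint
#' (`a_mie_dist = "truncnorm"`, sd = half the range width), for users who
#' read "mean +/- sd" literally; the default keeps every parameter uniform.
#'
#' @param ranges a [parameter_ranges][load_model_ranges] object.
#' @param n_samples number of samples, >= 1.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param a_mie_dist `"uniform"` (default) or `"truncnorm"`.
#' @return list of [tissue_sample()] objects; the label data frame is
#'   available via [tissue_labels()].
#' @export
sample_tissue <- function(ranges, n_samples, seed = 1,
                          a_mie_dist = c("uniform", "truncnorm")) {
  stopifnot(inherits(ranges, "parameter_ranges"), n_samples >= 1)
  a_mie_dist <- match.arg(a_mie_dist)
  n_layers <- length(ranges$layers)

  draw <- function(rng, n) {
    if (rng[1] == rng[2]) rep(rng[1], n) else runif(n, rng[1], rng[2])
  }
  draw_amie <- function(rng, n) {
    if (a_mie_dist == "uniform" || rng[1] == rng[2]) return(draw(rng, n))
    mu <- mean(rng); sdev <- (rng[2] - rng[1]) / 2
    x <- rnorm(n, mu, sdev)
    bad <- x <= 0
    while (any(bad)) {  # truncate at zero: scattering must stay positive
      x[bad] <- rnorm(sum(bad), mu, sdev)
      bad <- x <= 0
    }
    x
  }

  with_local_seed(seed, function() {
    s_shared <- draw(ranges$layers[[1]]$s, n_samples)
    per_layer <- lapply(ranges$layers, function(ly) {
      b_rng <- if (!is.null(ranges$b_fixed)) rep(ranges$b_fixed, 2) else ly$b
      list(v_hb = draw(ly$v_hb, n_samples),
           a_mie = draw_amie(ly$a_mie, n_samples),
           b = draw(b_rng, n_samples),
           g = draw(ly$g, n_samples),
           n_refr = draw(ly$n_refr, n_samples),
           d = draw(ly$d, n_samples))
    })

    lapply(seq_len(n_samples), function(i) {
      d_i <- vapply(per_layer, function(p) p$d[i], numeric(1))
      cap <- ranges$max_total_thickness_um
      if (is.finite(cap) && sum(d_i) > cap) d_i <- d_i * cap / sum(d_i)
      d_i <- pmax(d_i, 1e-9)  # zero-thickness draws become negligible slivers
      layers <- lapply(seq_len(n_layers), function(l) {
        p <- per_layer[[l]]
        layer_properties(v_hb = p$v_hb[i],
                         s = if (ranges$shared_s) s_shared[i] else p$s[i],
                         a_mie = p$a_mie[i], b = p$b[i], g = p$g[i],
                         n_refr = p$n_refr[i], d_um = d_i[l])
      })
      tissue_sample(layers)
    })
  })
}

#' Extract the regression labels of a list of tissue samples
#'
#' The estimation targets are the shared oxygenation `s` and the blood
#' volume fraction of the first (most superficial) layer — the layer that
#' dominates the measurable reflectance signal.
#'
#' @param samples list of [tissue_sample()] objects.
#' @return data frame with columns `s` and `v_hb`.
#' @export
tissue_labels <- function(samples) {
  data.frame(
    s = vapply(samples, function(x) x$layers[[1]]$s, numeric(1)),
    v_hb = vapply(samples, function(x) x$layers[[1]]$v_hb, numeric(1)))
}

#' Flatten tissue samples to a data frame (one row per sample)
#'
#' Columns are named `layer{i}_{param}`; the shared oxygenation is stored
#' once as `s`. The inverse of the CSV convention used by [write_dataset()].
#'
#' @param samples list of [tissue_sample()] objects.
#' @return data frame.
#' @export
samples_to_frame <- function(samples) {
  n_layers <- length(samples[[1]]$layers)
  out <- data.frame(s = vapply(samples, function(x) x$layers[[1]]$s, numeric(1)))
  for (l in seq_len(n_layers)) {
    for (p in c("v_hb", "a_mie", "b", "g", "n_refr", "d_um")) {
      out[[sprintf("layer%d_%s", l, p)]] <-
        vapply(samples, function(x) x$layers[[l]][[p]], numeric(1))
    }
  }
  out
}
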