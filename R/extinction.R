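#' Load a hemoglobin molar extinction coefficient table
#'
#' Reads a CSV with columns `wavelength_nm`, `eps_hbo2`, `eps_hb` giving the
#' molar extinction coefficients (L mol^-1 cm^-1) of oxygenated and
#' de-oxygenated hemoglobin on a strictly increasing wavelength grid, and
#' attaches the hemoglobin concentration used to convert fractions of blood
#' to absorption. Lines starting with `#` are treated as comments.
#'
#' @param path path to the CSV file. Defaults to the bundled table
#'   (a synthetic reconstruction of the standard published compilation,
#'   see `system.file("extdata", "hemoglobin_extinction_synthetic.csv",
#'   package = "mcti")`).
#' @param c_hb_gram_per_liter hemoglobin mass concentration of whole blood
#'   in g/L. 120 g/L is typical for the colon (150 g/L for generic tissue).
#' @param hb_molar_mass_gram_per_mol molar mass used for the g/L to mol/L
#'   conversion; 64500 g/mol is the constant conventionally paired with the
#'   extinction compilation.
#' @return an object of class `chromophore_table`.
#' @export
load_extinction_table <- function(path = NULL,
                                  c_hb_gram_per_liter = 120,
                                  hb_molar_mass_gram_per_mol = 64500) {
  if (is.null(path)) {
    path <- system.file("extdata", "hemoglobin_extinction_synthetic.csv",
                        package = "mcti", mustWork = TRUE)
  }
  tab <- read.csv(path, comment.char = "#")
  required <- c("wavelength_nm", "eps_hbo2", "eps_hb")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("extinction table is missing column(s): ", paste(missing, collapse = ", "))
  }
  wl <- tab$wavelength_nm
  if (any(diff(wl) <= 0)) {
    stop("extinction table wavelengths must be strictly increasing")
  }
  if (any(tab$eps_hbo2 <= 0) || any(tab$eps_hb <= 0)) {
    stop("extinction coefficients must be positive")
  }
  if (c_hb_gram_per_liter <= 0) stop("c_hb_gram_per_liter must be positive")
  structure(
    list(wavelength_nm = wl,
         eps_hbo2 = tab$eps_hbo2,
         eps_hb = tab$eps_hb,
         c_hb_gram_per_liter = c_hb_gram_per_liter,
         hb_molar_mass_gram_per_mol = hb_molar_mass_gram_per_mol),
    class = "chromophore_table")
}

#' The bundled hemoglobin extinction table
#'
#' Convenience wrapper for [load_extinction_table()] with the packaged CSV.
#'
#' @inheritParams load_extinction_table
#' @return a `chromophore_table`.
#' @export
default_extinction_table <- function(c_hb_gram_per_liter = 120) {
  load_extinction_table(c_hb_gram_per_liter = c_hb_gram_per_liter)
}

#' Interpolate extinction coefficients at query wavelengths
#'
#' Linear interpolation between tabulated knots; querying outside the
#' covered wavelength range is an error (extrapolating extinction spectra
#' is physically meaningless).
#'
#' @param table a `chromophore_table`.
#' @param lambda_nm numeric vector of query wavelengths (nm).
#' @return a list with numeric vectors `eps_hbo2` and `eps_hb`.
#' @export
extinction_at <- function(table, lambda_nm) {
  stopifnot(inherits(table, "chromophore_table"))
  rng <- range(table$wavelength_nm)
  if (any(lambda_nm < rng[1] | lambda_nm > rng[2])) {
    stop(sprintf("wavelength out of table range [%g, %g] nm", rng[1], rng[2]))
  }
  list(
    eps_hbo2 = approx(table$wavelength_nm, table$eps_hbo2, xout = lambda_nm)$y,
    eps_hb = approx(table$wavelength_nm, table$eps_hb, xout = lambda_nm)$y)
}

#' @export
print.chromophore_table <- function(x, ...) {
  cat(sprintf(
    "<chromophore_table> %d wavelengths, %g-%g nm, c_hb = %g g/L\n",
    length(x$wavelength_nm), min(x$wavelength_nm), max(x$wavelength_nm),
    x$c_hb_gram_per_liter))
  invisible(x)
}
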