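# Colorimetry: spectrum -> CIE XYZ -> sRGB rendering of perceived color.

# CIE 1931 2-degree color-matching functions via the multi-lobe piecewise
# Gaussian analytic fit (Wyman, Sloan & Shirley 2013), accurate to ~1% —
# adequate for rendering perceived iridescence.
piecewise_gauss <- function(x, mu, s1, s2) {
  s <- ifelse(x < mu, s1, s2)
  exp(-0.5 * ((x - mu) / s)^2)
}

cmf_x <- function(l) {
  1.056 * piecewise_gauss(l, 599.8, 37.9, 31.0) +
    0.362 * piecewise_gauss(l, 442.0, 16.0, 26.7) -
    0.065 * piecewise_gauss(l, 501.1, 20.4, 26.2)
}
cmf_y <- function(l) {
  0.821 * piecewise_gauss(l, 568.8, 46.9, 40.5) +
    0.286 * piecewise_gauss(l, 530.9, 16.3, 31.1)
}
cmf_z <- function(l) {
  1.217 * piecewise_gauss(l, 437.0, 11.8, 36.0) +
    0.681 * piecewise_gauss(l, 459.0, 26.0, 13.8)
}

# trapezoidal integration on a (possibly non-uniform) grid
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

srgb_gamma <- function(u) {
  ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
}

XYZ_TO_SRGB <- matrix(c(
  3.2406, -1.5372, -0.4986,
  -0.9689, 1.8758, 0.0415,
  0.0557, -0.2040, 1.0570
), nrow = 3, byrow = TRUE)

#' Render a reflectance spectrum as a perceived sRGB color
#'
#' Multiplies the spectrum by the illuminant, integrates against the CIE
#' 1931 2-degree color-matching functions to tristimulus XYZ, adapts the
#' illuminant white to the sRGB (D65) white point, applies the linear
#' XYZ-to-sRGB matrix and gamma-encodes. A flat unit reflectance maps to
#' the white point; out-of-gamut channels are clipped with a notice.
#'
#' @param spectrum Tibble with `wavelength` (nm) and `R` columns, covering
#'   (part of) 380-750 nm.
#' @param illuminant `"E"` (equal energy, default), a numeric vector on the
#'   spectrum's grid, or a function of wavelength.
#' @param clip_notice Emit a message when gamut clipping occurs.
#' @return A tibble with one row: `r`, `g`, `b` in [0, 1] (gamma-encoded
#'   sRGB) and the linear-light `r_lin`, `g_lin`, `b_lin`.
#' @examples
#' flat <- tibble::tibble(wavelength = 380:750, R = 1)
#' spectrum_to_srgb(flat)  # white point
#' @export
spectrum_to_srgb <- function(spectrum, illuminant = "E",
                             clip_notice = TRUE) {
  wl <- spectrum$wavelength
  refl <- if ("R" %in% names(spectrum)) spectrum$R else spectrum[[2]]
  keep <- wl >= 380 & wl <= 750
  if (sum(keep) < 2L) {
    abort("Spectrum does not overlap the visible range 380-750 nm.",
          class = "chromatophore_input_error")
  }
  wl <- wl[keep]; refl <- refl[keep]
  illum <- if (is.function(illuminant)) {
    illuminant(wl)
  } else if (is.numeric(illuminant)) {
    if (length(illuminant) == length(spectrum$wavelength)) {
      illuminant[keep]
    } else rep_len(illuminant, length(wl))
  } else if (identical(illuminant, "E")) {
    rep(1, length(wl))
  } else {
    abort("Unknown illuminant.", class = "chromatophore_input_error")
  }

  norm <- trapz(wl, illum * cmf_y(wl))
  X <- trapz(wl, refl * illum * cmf_x(wl)) / norm
  Y <- trapz(wl, refl * illum * cmf_y(wl)) / norm
  Z <- trapz(wl, refl * illum * cmf_z(wl)) / norm

  # adapt the illuminant white (R = 1) to the sRGB D65 white point
  Xw <- trapz(wl, illum * cmf_x(wl)) / norm
  Zw <- trapz(wl, illum * cmf_z(wl)) / norm
  d65 <- c(0.95047, 1.0, 1.08883)
  xyz <- c(X / Xw * d65[1], Y, Z / Zw * d65[3])

  rgb_lin <- as.numeric(XYZ_TO_SRGB %*% xyz)
  if (any(rgb_lin < 0 | rgb_lin > 1)) {
    if (clip_notice) inform("Out-of-gamut color clipped to [0, 1].")
    rgb_lin <- pmin(pmax(rgb_lin, 0), 1)
  }
  rgb <- srgb_gamma(rgb_lin)
  tibble(r = rgb[1], g = rgb[2], b = rgb[3],
         r_lin = rgb_lin[1], g_lin = rgb_lin[2], b_lin = rgb_lin[3])
}
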