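#' Lorentzian broadening of an excited-state line list
#'
#' Builds a pigment absorption envelope from calculated electronic
#' excitations (wavelength + oscillator strength), the standard
#' post-processing of TD-DFT output: each line becomes a Lorentzian of
#' height proportional to its oscillator strength,
#' `A(lambda) = sum_i f_i * (g/2)^2 / ((lambda - lambda_i)^2 + (g/2)^2)`
#' with `g` the full width at half maximum. Broadening is applied in the
#' wavelength domain by default (the FWHM is stated in nm); an
#' energy-domain option broadens in eV instead.
#'
#' @param states Tibble with columns `wavelength` (nm, > 0) and `strength`
#'   (oscillator strength, >= 0). Line lists are expected to hold at most
#'   200 states (the usual excited-state calculation depth); more triggers
#'   a warning.
#' @param fwhm Full width at half maximum of the broadening kernel, in nm
#'   (default 30) or in eV when `domain = "energy"`.
#' @param grid Wavelength grid (nm), strictly increasing.
#' @param domain `"wavelength"` (default) or `"energy"` (Lorentzian in eV
#'   applied to the photon energy axis).
#' @param normalize If `TRUE`, scale the envelope to unit maximum.
#' @return A tibble of class `absorption_spectrum` with `wavelength` and
#'   `intensity` (arbitrary units, >= 0).
#' @examples
#' states <- tibble::tibble(wavelength = 429, strength = 1)
#' spec <- lorentzian_broaden(states)
#' lambda_max_abs(spec)  # 429
#' @export
lorentzian_broaden <- function(states, fwhm = 30,
                               grid = seq(250, 750, by = 0.5),
                               domain = c("wavelength", "energy"),
                               normalize = FALSE) {
  domain <- match.arg(domain)
  stopifnot(fwhm > 0)
  if (nrow(states) == 0L) {
    abort("Empty excited-state table.", class = "chromatophore_input_error")
  }
  if (any(states$wavelength <= 0) || any(states$strength < 0)) {
    abort("States need positive wavelengths and non-negative strengths.",
          class = "chromatophore_input_error")
  }
  if (nrow(states) > 200L) {
    warn(sprintf("%d excited states; line lists usually hold at most 200.",
                 nrow(states)))
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    abort("Grid must be strictly increasing.",
          class = "chromatophore_input_error")
  }
  half <- fwhm / 2
  intensity <- rep(0, length(grid))
  if (domain == "wavelength") {
    for (i in seq_len(nrow(states))) {
      intensity <- intensity + states$strength[i] * half^2 /
        ((grid - states$wavelength[i])^2 + half^2)
    }
  } else {
    hc <- 1239.84193  # eV * nm
    e_grid <- hc / grid
    e_lines <- hc / states$wavelength
    for (i in seq_len(nrow(states))) {
      intensity <- intensity + states$strength[i] * half^2 /
        ((e_grid - e_lines[i])^2 + half^2)
    }
  }
  if (normalize && max(intensity) > 0) intensity <- intensity / max(intensity)
  out <- tibble(wavelength = grid, intensity = intensity)
  class(out) <- c("absorption_spectrum", class(out))
  out
}

#' Wavelength of maximum absorption
#'
#' @param spectrum Tibble with `wavelength` and `intensity`. Ties (e.g. a
#'   flat spectrum) resolve to the lowest wavelength, with a warning when
#'   the spectrum is entirely flat.
#' @return lambda_max in nm.
#' @export
lambda_max_abs <- function(spectrum) {
  if (nrow(spectrum) == 0L || all(spectrum$intensity == 0)) {
    abort("Cannot locate a maximum in an empty or all-zero spectrum.",
          class = "chromatophore_input_error")
  }
  if (length(unique(spectrum$intensity)) == 1L) {
    warn("Flat spectrum: returning the lowest grid wavelength.")
  }
  spectrum$wavelength[which.max(spectrum$intensity)]
}

#' Two-state titration model
#'
#' Henderson-Hasselbalch mixing of an acidic and a basic chromophore state:
#' `A(pH) = A_acid + (A_base - A_acid) / (1 + 10^(n * (pK - pH)))`.
#' The curve is monotone between the two plateaus and passes through their
#' midpoint at `pH = pK`.
#'
#' @param pH Numeric vector of pH values.
#' @param pK Transition midpoint (pH units).
#' @param A_acid,A_base Plateau absorbances (>= 0).
#' @param n Hill-type slope coefficient, > 0.
#' @return A tibble with `pH` and `absorbance`.
#' @export
titration_model <- function(pH, pK, A_acid, A_base, n = 1) {
  stopifnot(n > 0, is.finite(pK), is.finite(A_acid), is.finite(A_base))
  tibble(pH = pH,
         absorbance = A_acid + (A_base - A_acid) / (1 + 10^(n * (pK - pH))))
}

#' Fit the two-state titration model to a pH series
#'
#' Least-squares fit of [titration_model()] to (pH, absorbance) pairs, e.g.
#' absorbance collected at 430 nm while titrating a pigment. The fit is
#' deterministic: pK is initialized at the pH whose absorbance is closest
#' to half-range, plateaus at the low-/high-pH end values, slope at 1.
#'
#' @param series Tibble with columns `pH` (in [0, 14]) and `absorbance`
#'   (>= 0); at least 4 points spanning both sides of the transition.
#' @return An object of class `titration_fit` with components `pK`,
#'   `A_acid`, `A_base`, `n`, `rss`, `fitted`, `data`. Use [tidy()] /
#'   [glance()] to extract tibbles.
#' @export
fit_titration <- function(series) {
  stopifnot(all(c("pH", "absorbance") %in% names(series)))
  if (nrow(series) < 4L) {
    abort("Need at least 4 titration points to fit.",
          class = "chromatophore_input_error")
  }
  if (any(series$pH < 0 | series$pH > 14)) {
    abort("pH values must lie in [0, 14].",
          class = "chromatophore_input_error")
  }
  rng <- range(series$absorbance)
  if (diff(rng) < 1e-12 * max(1, abs(rng[2]))) {
    abort("Degenerate fit: absorbance series is constant.",
          class = "chromatophore_degenerate_fit")
  }
  ord <- order(series$pH)
  series <- series[ord, ]
  half <- mean(rng)
  pK0 <- series$pH[which.min(abs(series$absorbance - half))]
  start <- list(pK = pK0,
                A_acid = series$absorbance[1L],
                A_base = series$absorbance[nrow(series)],
                n = 1)
  fit <- minpack.lm::nlsLM(
    absorbance ~ A_acid + (A_base - A_acid) / (1 + 10^(n * (pK - pH))),
    data = series, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- as.list(coef(fit))
  structure(list(pK = p$pK, A_acid = p$A_acid, A_base = p$A_base, n = p$n,
                 rss = sum(resid(fit)^2),
                 fitted = as.numeric(stats::fitted(fit)),
                 data = series, nls = fit),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf(
    "<titration_fit> pK = %.3f, A_acid = %.3f, A_base = %.3f, n = %.3f, RSS = %.3g\n",
    x$pK, x$A_acid, x$A_base, x$n, x$rss))
  invisible(x)
}

#' Tidy a titration fit into one row per parameter
#'
#' @param x A `titration_fit`.
#' @param ... Unused.
#' @return A tibble with `term` and `estimate`.
#' @export
tidy.titration_fit <- function(x, ...) {
  tibble(term = c("pK", "A_acid", "A_base", "n"),
         estimate = c(x$pK, x$A_acid, x$A_base, x$n))
}

#' One-row fit summary of a titration fit
#'
#' @param x A `titration_fit`.
#' @param ... Unused.
#' @return A tibble with `pK`, `A_acid`, `A_base`, `n`, `rss`, `n_obs`.
#' @export
glance.titration_fit <- function(x, ...) {
  tibble(pK = x$pK, A_acid = x$A_acid, A_base = x$A_base, n = x$n,
         rss = x$rss, n_obs = nrow(x$data))
}
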