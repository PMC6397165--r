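#' Construct a multilayer stack
#'
#' A stack of homogeneous dielectric layers between an ambient and a
#' substrate half-space. The chromatophore model embeds alternating
#' sheath-cell cytoplasm ("a") and membrane ("b") layers in tissue, so both
#' half-spaces default to the cytoplasm index.
#'
#' @param thickness Numeric vector of layer thicknesses (nm), all > 0.
#' @param index Numeric vector of (real) refractive indices, all >= 1.
#' @param role Optional character labels per layer (e.g. `"a"`/`"b"`).
#' @param n_ambient,n_substrate Half-space refractive indices.
#' @return An object of class `layer_stack`.
#' @export
layer_stack <- function(thickness, index, role = NULL,
                        n_ambient = 1.33, n_substrate = 1.33) {
  stopifnot(length(thickness) == length(index))
  if (any(thickness <= 0)) {
    abort("All layer thicknesses must be positive.",
          class = "chromatophore_input_error")
  }
  if (length(index) > 0 && any(index < 1)) {
    abort("Refractive indices must be >= 1.",
          class = "chromatophore_input_error")
  }
  if (is.null(role)) role <- rep(NA_character_, length(thickness))
  structure(list(
    layers = tibble(thickness = as.numeric(thickness),
                    index = as.numeric(index), role = role),
    n_ambient = n_ambient, n_substrate = n_substrate
  ), class = "layer_stack")
}

#' Alternating cytoplasm/membrane stack
#'
#' Builds an a/b/a/b... stack of `n_pairs` cytoplasm-membrane pairs.
#'
#' @param d_a,d_b Cytoplasm and membrane layer thicknesses (nm); scalars or
#'   vectors of length `n_pairs`.
#' @param n_a,n_b Refractive indices (defaults 1.33 cytoplasm, 1.46 lipid
#'   membrane).
#' @param n_pairs Number of layer pairs.
#' @inheritParams layer_stack
#' @return A `layer_stack` with roles alternating `"a"`, `"b"`.
#' @export
alternating_stack <- function(d_a = 116, d_b = 71, n_a = 1.33, n_b = 1.46,
                              n_pairs = 8, n_ambient = n_a,
                              n_substrate = n_a) {
  stopifnot(n_pairs >= 1)
  d_a <- rep_len(d_a, n_pairs); d_b <- rep_len(d_b, n_pairs)
  thickness <- as.numeric(rbind(d_a, d_b))
  index <- rep(c(n_a, n_b), n_pairs)
  role <- rep(c("a", "b"), n_pairs)
  layer_stack(thickness, index, role, n_ambient, n_substrate)
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("<layer_stack> %d layers, ambient n=%.3f, substrate n=%.3f\n",
              nrow(x$layers), x$n_ambient, x$n_substrate))
  print(x$layers, ...)
  invisible(x)
}

#' Ideal two-beam constructive-interference wavelength
#'
#' The classic multilayer interference condition for an alternating
#' two-component stack: `m * lambda = 2 * (n_a d_a cos(theta_a) +
#' n_b d_b cos(theta_b))`, with internal angles obtained from the ambient
#' incidence angle by Snell's law. Thinner layers (an expanding
#' chromatophore spreading its cytoplasm) shift the reflected color to the
#' blue; thicker layers (relaxation) shift it to the red.
#'
#' @param n_a,d_a,n_b,d_b Layer indices and thicknesses (nm).
#' @param angle Incidence angle in the ambient medium, degrees in [0, 90).
#' @param m Interference order, integer >= 1.
#' @param n_ambient Ambient refractive index.
#' @return The m-th order constructive wavelength in nm.
#' @examples
#' ideal_lambda_max(1, 100, 1, 150)        # 500 nm
#' ideal_lambda_max(1.33, 116, 1.46, 71)   # chromatophore defaults
#' @export
ideal_lambda_max <- function(n_a, d_a, n_b, d_b, angle = 0, m = 1,
                             n_ambient = 1.33) {
  stopifnot(m >= 1, angle >= 0, angle < 90, n_a >= 1, n_b >= 1)
  sin0 <- sin(angle * pi / 180)
  sa <- n_ambient * sin0 / n_a
  sb <- n_ambient * sin0 / n_b
  if (sa >= 1 || sb >= 1) {
    abort("Total internal reflection: no propagating wave in a layer.",
          class = "chromatophore_input_error")
  }
  2 * (n_a * d_a * sqrt(1 - sa^2) + n_b * d_b * sqrt(1 - sb^2)) / m
}

# Characteristic-matrix reflectance/transmittance at one wavelength for one
# polarization ("s" or "p"). Returns c(R, T).
tmm_one <- function(n_layers, d_layers, n0, ns, lambda, sin0, pol) {
  kx <- n0 * sin0
  cos_of <- function(n) sqrt(as.complex(1 - (kx / n)^2))
  eta <- function(n, cth) if (pol == "s") n * cth else n / cth

  c0 <- cos_of(n0); cs <- cos_of(ns)
  eta0 <- eta(n0, c0); etas <- eta(ns, cs)

  B <- 1 + 0i; C <- etas
  # recurse from the substrate side up through the layers
  for (j in rev(seq_along(n_layers))) {
    cj <- cos_of(n_layers[j])
    ej <- eta(n_layers[j], cj)
    delta <- 2 * pi * n_layers[j] * d_layers[j] * cj / lambda
    Bn <- cos(delta) * B + 1i * sin(delta) / ej * C
    Cn <- 1i * ej * sin(delta) * B + cos(delta) * C
    B <- Bn; C <- Cn
  }
  r <- (eta0 * B - C) / (eta0 * B + C)
  t <- 2 * eta0 / (eta0 * B + C)
  R <- Mod(r)^2
  T <- Re(etas) / Re(eta0) * Mod(t)^2
  c(R = R, T = T)
}

#' Transfer-matrix reflectance spectrum of a multilayer
#'
#' Full-wave characteristic-matrix recursion over the stack, for s, p, or
#' unpolarized light (mean of s and p). For a lossless (real-index) stack,
#' reflectance and transmittance satisfy R + T = 1 to machine precision.
#' An empty stack returns the bare ambient/substrate Fresnel result.
#'
#' @param stack A [layer_stack()].
#' @param wavelengths Strictly increasing grid in nm (default 380-750 at
#'   1 nm, the visible range).
#' @param angle Incidence angle in degrees.
#' @param polarization `"unpolarized"` (default), `"s"`, or `"p"`.
#' @return A tibble of class `reflectance_spectrum` with columns
#'   `wavelength`, `R`, `T`.
#' @examples
#' s <- alternating_stack(d_a = 116, d_b = 71)
#' spec <- transfer_matrix_reflectance(s)
#' lambda_peak(spec)
#' @export
transfer_matrix_reflectance <- function(stack,
                                        wavelengths = seq(380, 750, by = 1),
                                        angle = 0,
                                        polarization = c("unpolarized", "s", "p")) {
  polarization <- match.arg(polarization)
  stopifnot(inherits(stack, "layer_stack"), all(wavelengths > 0),
            angle >= 0, angle < 90)
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    abort("Wavelength grid must be strictly increasing.",
          class = "chromatophore_input_error")
  }
  nl <- stack$layers$index; dl <- stack$layers$thickness
  sin0 <- sin(angle * pi / 180)
  pols <- if (polarization == "unpolarized") c("s", "p") else polarization
  rt <- vapply(wavelengths, function(lam) {
    m <- vapply(pols, function(p) {
      tmm_one(nl, dl, stack$n_ambient, stack$n_substrate, lam, sin0, p)
    }, numeric(2))
    rowMeans(m)
  }, numeric(2))
  out <- tibble(wavelength = wavelengths,
                R = unname(rt[1, ]), T = unname(rt[2, ]))
  class(out) <- c("reflectance_spectrum", class(out))
  out
}

#' Wavelength of peak reflectance
#'
#' @param spectrum A tibble with `wavelength` and `R` (or a second numeric
#'   column). Ties resolve to the lowest wavelength.
#' @return The peak wavelength in nm.
#' @export
lambda_peak <- function(spectrum) {
  val <- if ("R" %in% names(spectrum)) spectrum$R else spectrum[[2]]
  if (nrow(spectrum) == 0L || all(val == 0)) {
    abort("Cannot locate a peak in an empty or all-zero spectrum.",
          class = "chromatophore_input_error")
  }
  spectrum$wavelength[which.max(val)]
}

#' Truncated-normal layer-thickness distribution
#'
#' Measured chromatophore layer heights: cytoplasm layers average
#' 116 +/- 102 nm and sheath-cell membrane layers 71 +/- 14 nm (mean +/- sd).
#' Because the cytoplasm sd exceeds its mean, draws are truncated below at
#' a positive bound (default 10 nm) by resampling.
#'
#' @param mean,sd Distribution parameters in nm (sd >= 0).
#' @param lower Truncation bound, > 0.
#' @return A list of class `thickness_distribution`.
#' @export
thickness_distribution <- function(mean, sd, lower = 10) {
  stopifnot(sd >= 0, lower > 0)
  if (lower > mean + 5 * sd) {
    abort("Impossible truncation: lower bound far above mean + 5 sd.",
          class = "chromatophore_input_error")
  }
  structure(list(mean = mean, sd = sd, lower = lower),
            class = "thickness_distribution")
}

# Mean of a normal truncated below at `lower` (closed form).
truncnorm_mean <- function(mean, sd, lower) {
  if (sd == 0) return(mean)
  a <- (lower - mean) / sd
  mean + sd * dnorm(a) / (1 - pnorm(a))
}

rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lower])
  }
  out[seq_len(n)]
}

#' Sample an alternating stack from thickness distributions
#'
#' Draws `n_pairs` cytoplasm and membrane thicknesses from truncated-normal
#' distributions and assembles them into an alternating stack.
#' Deterministic for a fixed seed.
#'
#' @param dist_a,dist_b [thickness_distribution()] objects for cytoplasm and
#'   membrane layers.
#' @param n_pairs Number of a/b pairs, >= 1.
#' @param n_a,n_b Layer refractive indices.
#' @param seed Integer RNG seed.
#' @return A `layer_stack`.
#' @export
sample_stack <- function(dist_a = thickness_distribution(116, 102),
                         dist_b = thickness_distribution(71, 14),
                         n_pairs = 8, n_a = 1.33, n_b = 1.46, seed = 1L) {
  stopifnot(n_pairs >= 1)
  withr::with_seed(seed, {
    d_a <- rtruncnorm_lower(n_pairs, dist_a$mean, dist_a$sd, dist_a$lower)
    d_b <- rtruncnorm_lower(n_pairs, dist_b$mean, dist_b$sd, dist_b$lower)
  })
  alternating_stack(d_a, d_b, n_a, n_b, n_pairs)
}

#' Thin the layers of an expanding chromatophore
#'
#' Actuation spreads the pigment cell into a flattened disc; a layer
#' conserving volume while expanding `areal_factor`-fold in area thins by
#' the same factor. Optionally the membrane ("b") layers are held fixed,
#' since a lipid bilayer has a set thickness.
#'
#' @param stack A `layer_stack`.
#' @param areal_factor Areal expansion factor >= 1 (the fully distended
#'   chromatocyte reaches ~15x).
#' @param membranes_fixed If `TRUE`, only `"a"` (cytoplasm) layers thin.
#' @return The expanded `layer_stack`.
#' @export
expand_layers <- function(stack, areal_factor, membranes_fixed = FALSE) {
  stopifnot(inherits(stack, "layer_stack"))
  if (areal_factor < 1) {
    abort("areal_factor must be >= 1.", class = "chromatophore_input_error")
  }
  scale_row <- if (membranes_fixed) {
    !is.na(stack$layers$role) & stack$layers$role == "a"
  } else rep(TRUE, nrow(stack$layers))
  stack$layers$thickness[scale_row] <-
    stack$layers$thickness[scale_row] / areal_factor
  stack
}
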