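# Synthetic-data generators: inputs with the statistical structure each
# pipeline stage assumes, so the whole analysis is testable without raw
# data downloads. Every generator is deterministic under a fixed seed and
# emits its ground truth alongside the data.

#' Generate a random proteome
#'
#' Random amino-acid sequences with configurable K/R frequency, so the
#' expected tryptic peptide yield spans a wide range: the mean yield is
#' approximately `1 + (L - 1) * p_kr * (1 - p_p)`.
#'
#' @param n Number of proteins, >= 1.
#' @param length_range Integer range of sequence lengths (uniform draw).
#' @param p_kr Combined probability of K or R per residue.
#' @param p_p Probability of proline per residue (feeds the proline rule).
#' @param seed Integer seed.
#' @return A tibble with `id`, `description`, `sequence`.
#' @export
make_proteome <- function(n, length_range = c(100L, 600L),
                          p_kr = 0.11, p_p = 0.05, seed = 1L) {
  if (n < 1) abort("n must be >= 1.", class = "chromatophore_input_error")
  stopifnot(p_kr >= 0, p_p >= 0, p_kr + p_p <= 1)
  others <- setdiff(AA_ALPHABET, c("K", "R", "P", "X"))
  probs <- c(K = p_kr / 2, R = p_kr / 2, P = p_p,
             setNames(rep((1 - p_kr - p_p) / length(others), length(others)),
                      others))
  withr::with_seed(seed, {
    len_vals <- seq.int(length_range[1], length_range[2])
    lens <- len_vals[sample.int(length(len_vals), n, replace = TRUE)]
    seqs <- vapply(lens, function(L) {
      paste(sample(names(probs), L, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
  })
  tibble(id = sprintf("SYN%04d", seq_len(n)),
         description = sprintf("synthetic protein %d", seq_len(n)),
         sequence = seqs)
}

#' Generate a synthetic spectral-count table
#'
#' Draws per-sample spectral counts multinomially with sampling probability
#' proportional to `a_p * k_p`: larger proteins yield more observable
#' peptides, which is exactly the bias the peptide scaling of the abundance
#' index inverts. Per-sample totals are `depth * loading multiplier`,
#' emulating unequal protein loading between samples.
#'
#' @param proteome Tibble from [make_proteome()] (or any `id` + `sequence`
#'   tibble).
#' @param a_p True relative abundances, positive, one per protein
#'   (normalized internally to sum to 1).
#' @param depths Named or unnamed vector of per-sample sequencing depths.
#' @param loading Per-sample loading multipliers (same length as `depths`).
#' @param params [digest_params()] used for `k_p`.
#' @param seed Integer seed.
#' @return A count tibble (`protein` + one column per sample) with
#'   attribute `truth`: a tibble of `protein`, `a_p`, `k_p`.
#' @export
make_count_table <- function(proteome, a_p,
                             depths = c(yellow = 10000, red = 10000,
                                        brown = 10000),
                             loading = rep(1, length(depths)),
                             params = digest_params(), seed = 1L) {
  if (length(a_p) != nrow(proteome)) {
    abort("a_p must have one entry per protein.",
          class = "chromatophore_input_error")
  }
  if (length(loading) != length(depths)) {
    abort("loading and depths lengths differ.",
          class = "chromatophore_input_error")
  }
  stopifnot(all(a_p > 0), all(depths >= 1), all(loading > 0))
  a_p <- a_p / sum(a_p)
  if (is.null(names(depths))) {
    names(depths) <- sprintf("sample%d", seq_along(depths))
  }
  k_p <- digest_proteome(proteome, params)$expected_peptides
  prob <- a_p * k_p
  counts <- withr::with_seed(seed, {
    m <- lapply(seq_along(depths), function(s) {
      as.numeric(rmultinom(1, size = round(depths[s] * loading[s]),
                           prob = prob))
    })
    matrix(unlist(m), nrow = nrow(proteome),
           dimnames = list(NULL, names(depths)))
  })
  out <- dplyr::bind_cols(tibble(protein = proteome$id), as_tibble(counts))
  attr(out, "truth") <- tibble(protein = proteome$id, a_p = a_p, k_p = k_p)
  out
}

#' Generate synthetic layer-thickness measurements
#'
#' Truncated-normal draws emulating electron-micrograph layer-height
#' measurements. Defaults correspond to the published study conditions:
#' 292 cytoplasm layers at 116 +/- 102 nm, or (via `dist`) 237 membrane
#' layers at 71 +/- 14 nm.
#'
#' @param dist A [thickness_distribution()].
#' @param n Number of measurements, >= 1.
#' @param seed Integer seed.
#' @return Numeric vector of thicknesses (nm).
#' @export
make_layer_measurements <- function(dist = thickness_distribution(116, 102),
                                    n = 292, seed = 1L) {
  if (n < 1) abort("n must be >= 1.", class = "chromatophore_input_error")
  withr::with_seed(seed,
                   rtruncnorm_lower(n, dist$mean, dist$sd, dist$lower))
}

#' Generate a synthetic pH-titration series
#'
#' Evaluates the two-state [titration_model()] on a pH grid (default
#' spanning 1.9 to 8.9, the experimental titration range) and adds
#' Gaussian noise.
#'
#' @param pK,A_acid,A_base,n Model parameters (see [titration_model()]).
#' @param n_points Number of pH points, >= 4.
#' @param noise_sd Gaussian noise standard deviation (absorbance units).
#' @param pH_range Range of the pH grid.
#' @param seed Integer seed.
#' @return A tibble `pH`, `absorbance` with attribute `truth` (the
#'   parameter list).
#' @export
make_titration_series <- function(pK = 5.65, A_acid = 0.2, A_base = 1.0,
                                  n = 1, n_points = 30, noise_sd = 0,
                                  pH_range = c(1.9, 8.9), seed = 1L) {
  if (n_points < 4) {
    abort("Need at least 4 points.", class = "chromatophore_input_error")
  }
  grid <- seq(pH_range[1], pH_range[2], length.out = n_points)
  out <- titration_model(grid, pK, A_acid, A_base, n)
  if (noise_sd > 0) {
    out$absorbance <- out$absorbance +
      withr::with_seed(seed, rnorm(n_points, 0, noise_sd))
    out$absorbance <- pmax(out$absorbance, 0)
  }
  attr(out, "truth") <- list(pK = pK, A_acid = A_acid, A_base = A_base, n = n)
  out
}

#' Configuration for a synthetic expanding-disc movie
#'
#' Describes a movie of a disc whose area grows up to `expansion_max`-fold
#' (the maximal areal expansion of a fully distended chromatocyte is ~15x)
#' and whose fill color follows the thin-film model: per frame, the layer
#' stack is thinned by the current areal factor, its transfer-matrix
#' reflectance computed and rendered to sRGB. So the disc blue-shifts as it
#' expands.
#'
#' @param width,height Frame size in pixels.
#' @param n_frames Number of frames, >= 1.
#' @param expansion_max Final areal expansion factor (>= 1); the factor
#'   ramps linearly from 1 across the frames.
#' @param base_radius Disc radius (px) at factor 1; radius scales with the
#'   square root of the areal factor.
#' @param d_a,d_b,n_a,n_b,n_pairs Initial stack geometry (nm) and indices.
#' @param angle Illumination incidence angle (degrees).
#' @param noise_sd Additive Gaussian pixel noise sd (0-255 units).
#' @param background Background gray level, 0-255.
#' @param interval Seconds per frame.
#' @return A list of class `synthetic_movie_config`.
#' @export
synthetic_movie_config <- function(width = 80L, height = 80L, n_frames = 10L,
                                   expansion_max = 15, base_radius = 16,
                                   d_a = 116, d_b = 71, n_a = 1.33,
                                   n_b = 1.46, n_pairs = 8, angle = 0,
                                   noise_sd = 0, background = 40,
                                   interval = 0.03) {
  if (n_frames < 1) {
    abort("n_frames must be >= 1.", class = "chromatophore_input_error")
  }
  if (expansion_max < 1 || base_radius < 1 || width < 1 || height < 1) {
    abort("Invalid movie geometry.", class = "chromatophore_input_error")
  }
  structure(as.list(environment()), class = "synthetic_movie_config")
}

#' Render a synthetic expanding-disc movie
#'
#' @param config A [synthetic_movie_config()].
#' @param seed Integer seed (used only for the pixel noise).
#' @return A [frame_stack()] with attribute `ground_truth`: a tibble of
#'   `frame`, `areal_factor`, `R`, `G`, `B` (the noiseless disc color,
#'   0-255).
#' @export
make_movie <- function(config = synthetic_movie_config(), seed = 1L) {
  stopifnot(inherits(config, "synthetic_movie_config"))
  base <- alternating_stack(config$d_a, config$d_b, config$n_a, config$n_b,
                            config$n_pairs)
  factors <- if (config$n_frames == 1L) 1 else {
    seq(1, config$expansion_max, length.out = config$n_frames)
  }
  wl <- seq(380, 750, by = 2)
  colors <- t(vapply(factors, function(f) {
    spec <- transfer_matrix_reflectance(expand_layers(base, f), wl,
                                        angle = config$angle)
    # normalize to peak reflectance so the rendered disc is bright
    spec$R <- spec$R / max(spec$R)
    rgb <- spectrum_to_srgb(spec, clip_notice = FALSE)
    c(rgb$r, rgb$g, rgb$b) * 255
  }, numeric(3)))

  cx <- (config$height + 1) / 2; cy <- (config$width + 1) / 2
  dist2 <- outer((seq_len(config$height) - cx)^2,
                 (seq_len(config$width) - cy)^2, `+`)
  frames <- withr::with_seed(seed, {
    lapply(seq_len(config$n_frames), function(t) {
      r <- config$base_radius * sqrt(factors[t])
      mask <- dist2 <= r^2
      fr <- array(config$background,
                  dim = c(config$height, config$width, 3L))
      for (ch in 1:3) {
        plane <- fr[, , ch]
        plane[mask] <- colors[t, ch]
        fr[, , ch] <- plane
      }
      if (config$noise_sd > 0) {
        fr <- fr + array(rnorm(length(fr), 0, config$noise_sd), dim = dim(fr))
        fr <- pmin(pmax(fr, 0), 255)
      }
      fr
    })
  })
  out <- frame_stack(frames, config$interval)
  attr(out, "ground_truth") <- tibble(
    frame = seq_len(config$n_frames), areal_factor = factors,
    R = colors[, 1], G = colors[, 2], B = colors[, 3])
  out
}
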