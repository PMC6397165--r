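test_that("two-beam condition reproduces hand values and Snell bending", {
  expect_equal(ideal_lambda_max(1, 100, 1, 150), 500)
  expect_equal(ideal_lambda_max(1, 100, 1, 150, m = 2), 250)
  # oblique incidence shortens the optical path (cos < 1)
  expect_lt(ideal_lambda_max(1.33, 116, 1.46, 71, angle = 40),
            ideal_lambda_max(1.33, 116, 1.46, 71))
  expect_error(ideal_lambda_max(1, 100, 1, 150, angle = 60, n_ambient = 2),
               class = "chromatophore_input_error")
})

test_that("two-beam lambda_max is strictly increasing in d and n", {
  base <- ideal_lambda_max(1.33, 116, 1.46, 71)
  expect_gt(ideal_lambda_max(1.33, 117, 1.46, 71), base)
  expect_gt(ideal_lambda_max(1.33, 116, 1.46, 72), base)
  expect_gt(ideal_lambda_max(1.34, 116, 1.46, 71), base)
  expect_gt(ideal_lambda_max(1.33, 116, 1.47, 71), base)
})

test_that("empty stack gives the Fresnel interface result", {
  empty <- layer_stack(numeric(0), numeric(0),
                       n_ambient = 1, n_substrate = 1.5)
  spec <- transfer_matrix_reflectance(empty, c(400, 550, 700))
  expect_equal(spec$R, rep(0.04, 3), tolerance = 1e-12)
  # matched media reflect nothing
  matched <- layer_stack(c(100, 200), c(1.4, 1.4),
                         n_ambient = 1.4, n_substrate = 1.4)
  expect_equal(transfer_matrix_reflectance(matched, 500)$R, 0,
               tolerance = 1e-12)
})

test_that("energy is conserved for lossless stacks at any angle/polarization", {
  stack <- alternating_stack(d_a = c(90, 140, 116), d_b = c(60, 71, 80),
                             n_pairs = 3)
  for (ang in c(0, 25, 50)) {
    for (pol in c("s", "p", "unpolarized")) {
      spec <- transfer_matrix_reflectance(stack, seq(380, 750, 10),
                                          angle = ang, polarization = pol)
      expect_true(all(abs(spec$R + spec$T - 1) < 1e-9))
      expect_true(all(spec$R >= 0 & spec$R <= 1))
    }
  }
})

test_that("reversed stack with swapped half-spaces reflects identically", {
  stack <- layer_stack(c(120, 70, 95, 64), c(1.33, 1.46, 1.33, 1.46),
                       n_ambient = 1.0, n_substrate = 1.5)
  rev_stack <- layer_stack(rev(c(120, 70, 95, 64)),
                           rev(c(1.33, 1.46, 1.33, 1.46)),
                           n_ambient = 1.5, n_substrate = 1.0)
  wl <- seq(380, 750, 5)
  expect_equal(transfer_matrix_reflectance(stack, wl)$R,
               transfer_matrix_reflectance(rev_stack, wl)$R,
               tolerance = 1e-9)
})

test_that("quarter-wave stacks match the closed-form admittance result", {
  for (N in c(2, 5, 10)) {
    n_h <- 1.46; n_l <- 1.33; n0 <- 1.33; ns <- 1.33
    lambda0 <- 550
    stack <- alternating_stack(
      d_a = lambda0 / (4 * n_h), d_b = lambda0 / (4 * n_l),
      n_a = n_h, n_b = n_l, n_pairs = N,
      n_ambient = n0, n_substrate = ns)
    got <- transfer_matrix_reflectance(stack, lambda0)$R
    expect_equal(got, oracle_quarter_wave_R(n0, n_h, n_l, ns, N),
                 tolerance = 1e-9, info = paste("pairs", N))
  }
})

test_that("two-beam and transfer-matrix peaks agree for low contrast", {
  # index contrast 0.13 (1.33 vs 1.46), >= 10 pairs
  stack <- alternating_stack(d_a = 116, d_b = 71, n_pairs = 12)
  spec <- transfer_matrix_reflectance(stack, seq(380, 750, 0.5))
  expect_lte(abs(ideal_lambda_max(1.33, 116, 1.46, 71) -
                   lambda_peak(spec)), 5)
  # a second geometry inside the visible window
  stack2 <- alternating_stack(d_a = 90, d_b = 60, n_pairs = 10)
  spec2 <- transfer_matrix_reflectance(stack2, seq(380, 750, 0.5))
  expect_lte(abs(ideal_lambda_max(1.33, 90, 1.46, 60) -
                   lambda_peak(spec2)), 5)
})

test_that("expansion thins layers and blue-shifts the reflectance peak", {
  stack <- alternating_stack()
  expect_equal(expand_layers(stack, 1)$layers, stack$layers)
  expect_equal(expand_layers(stack, 2)$layers$thickness[1], 58)
  expect_error(expand_layers(stack, 0.5),
               class = "chromatophore_input_error")
  # membranes_fixed leaves b layers alone
  fixed <- expand_layers(stack, 2, membranes_fixed = TRUE)
  expect_equal(fixed$layers$thickness[fixed$layers$role == "b"],
               stack$layers$thickness[stack$layers$role == "b"])
  # two-beam prediction strictly decreases with expansion
  lams <- sapply(seq(1, 15, 1), function(f) {
    ideal_lambda_max(1.33, 116 / f, 1.46, 71 / f)
  })
  expect_true(all(diff(lams) < 0))
})

test_that("full-wave peak is non-increasing along an expansion sweep", {
  stack <- alternating_stack(n_pairs = 12)
  wl <- seq(200, 760, 1)  # extended grid keeps the blue-shifted peak visible
  peaks <- sapply(c(1, 1.5, 2, 3), function(f) {
    lambda_peak(transfer_matrix_reflectance(expand_layers(stack, f), wl))
  })
  expect_true(all(diff(peaks) <= 0))
})

test_that("thickness sampling is seeded, truncated and matches moments", {
  d <- thickness_distribution(116, 0)
  s <- sample_stack(d, thickness_distribution(71, 0), n_pairs = 5, seed = 2)
  expect_equal(s$layers$thickness[s$layers$role == "a"], rep(116, 5))
  expect_equal(s$layers$role, rep(c("a", "b"), 5))
  s1 <- sample_stack(n_pairs = 6, seed = 99)
  s2 <- sample_stack(n_pairs = 6, seed = 99)
  expect_identical(s1$layers, s2$layers)
  expect_true(all(s1$layers$thickness >= 10))
  expect_error(thickness_distribution(10, 1, lower = 100),
               class = "chromatophore_input_error")
  # large-n mean within 3 SE of the closed-form truncated-normal mean
  x <- make_layer_measurements(thickness_distribution(116, 102), 1e4,
                               seed = 4)
  mu_trunc <- chromatophore:::truncnorm_mean(116, 102, 10)
  expect_lt(abs(mean(x) - mu_trunc), 3 * sd(x) / sqrt(length(x)))
})

test_that("spectrum peak finder handles ties and matches a linear scan", {
  sp <- tibble::tibble(wavelength = 380:750,
                       R = exp(-((380:750) - 520)^2 / 200))
  expect_equal(lambda_peak(sp), 520)
  plateau <- tibble::tibble(wavelength = 1:10,
                            R = c(0, 1, 1, 1, 0, 0, 0, 0, 0, 0))
  expect_equal(lambda_peak(plateau), 2)
  set.seed(3)
  rnd <- tibble::tibble(wavelength = 1:100, R = runif(100))
  expect_equal(lambda_peak(rnd), rnd$wavelength[which.max(rnd$R)])
  expect_error(lambda_peak(tibble::tibble(wavelength = 1:3, R = 0)),
               class = "chromatophore_input_error")
})

test_that("stack constructors validate geometry", {
  expect_error(layer_stack(c(100, 0), c(1.3, 1.4)),
               class = "chromatophore_input_error")
  expect_error(layer_stack(100, 0.9),
               class = "chromatophore_input_error")
  s <- alternating_stack(d_a = c(100, 120), d_b = 70, n_pairs = 2)
  expect_equal(s$layers$thickness, c(100, 70, 120, 70))
})
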