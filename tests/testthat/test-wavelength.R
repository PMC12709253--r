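test_that("spectrum of the zero profile vanishes at every wavenumber", {
  s <- seq(0, 10, by = 0.218)
  sp <- power_spectrum(rep(0, length(s)), s, seq(0.4, 2, length.out = 128))
  expect_true(all(sp$G == 0))
})

test_that("single-frame spectra match dense integration; phase pairs are unbiased", {
  # four full wavelengths in the window; oracle: the same integrals on a
  # 20x finer arc grid
  L <- grid_length(92)
  lam0 <- L / 4
  k0 <- 2 * pi / lam0
  kg <- seq(2 * pi / (2 * L), 2 * pi / (L / 4), length.out = 1024)
  s <- seq(0, by = 0.218, length.out = 93)
  sp <- power_spectrum(sin(k0 * s), s, kg)
  s_fine <- seq(0, max(s), by = 0.218 / 20)
  sp_fine <- power_spectrum(sin(k0 * s_fine), s_fine, kg)
  dk <- kg[2] - kg[1]
  expect_lt(abs(kg[which.max(sp$G)] - kg[which.max(sp_fine$G)]), dk + 1e-12)
  # one frame at a fixed phase carries an interference bias of order 1/(k0 T);
  # averaging two frames in phase quadrature cancels it, as a beat average does
  sp_quad <- power_spectrum(cbind(sin(k0 * s), cos(k0 * s)), s, kg)
  expect_lt(abs(kg[which.max(sp_quad$G)] - k0), dk + 1e-12)
})

test_that("beat-averaged argmax is unbiased when the wavelength equals the window", {
  L <- grid_length(46)                   # window realizes L exactly
  fld <- plane_wave_field(length_um = L, wavelength_um = L)
  seg <- segment_beats(fld, 65)
  est <- estimate_wavelength(decompose_beat(fld, seg), seg,
                             average = "all_frames")
  expect_lt(abs(est$k0_per_um - 2 * pi / L), est$k_step_per_um)
})

test_that("wavelength shorter than the window is recovered within 1%", {
  fld <- plane_wave_field(length_um = 22, wavelength_um = 15)
  seg <- segment_beats(fld, 65)
  est <- estimate_wavelength(decompose_beat(fld, seg), seg)
  expect_equal(est$lambda_um, 15, tolerance = 0.01)
  expect_length(est$flags, 0)
  expect_equal(est$sem_um, sd(est$per_beat_lambda_um) / sqrt(est$n_beats))
})

test_that("estimate survives strong uniform angle noise within 2%", {
  fld <- plane_wave_field(noise_level = 0.5, seed = 3)
  seg <- segment_beats(fld, 65)
  est <- estimate_wavelength(decompose_beat(fld, seg), seg)
  expect_equal(est$lambda_um, 10, tolerance = 0.02)
})

test_that("estimate is invariant to the amplitude of the dynamic field", {
  fld <- plane_wave_field(n_frames = 300)
  seg <- segment_beats(fld, 65)
  est1 <- estimate_wavelength(fld, seg)
  fld2 <- ciliawave:::new_tangent_field(7.3 * fld$psi, fld$s_um, fld$t_s)
  est2 <- estimate_wavelength(fld2, seg)
  expect_equal(est1$lambda_um, est2$lambda_um, tolerance = 1e-10)
})

test_that("rescaling arc length and wavelength together preserves the ratio", {
  est_ratio <- function(scale) {
    p <- quiet_params(length_um = 12 * scale, wavelength_um = 10 * scale,
                      ds_um = 0.218 * scale, n_frames = 300)
    fld <- generate_tangent_field(p)
    seg <- segment_beats(fld, 65)
    (12 * scale) / estimate_wavelength(fld, seg)$lambda_um
  }
  expect_equal(est_ratio(1), est_ratio(2), tolerance = 1e-8)
})

test_that("halving the wavenumber grid step does not worsen the estimate", {
  fld <- plane_wave_field(length_um = 15, wavelength_um = 10, n_frames = 300)
  seg <- segment_beats(fld, 65)
  err <- function(k_n) {
    abs(estimate_wavelength(fld, seg, k_n = k_n)$lambda_um - 10)
  }
  coarse_step <- 2 * pi * (1 / (15 / 4) - 1 / 30) / 1023
  coarse_lambda_step <- 10^2 / (2 * pi) * coarse_step
  expect_lte(err(2047), err(1024) + coarse_lambda_step)
})

test_that("analytic spectrum matches quadrature and the trivial cases", {
  expect_equal(analytic_g(seq(0.5, 2, 0.1), 1, 10, amplitude_rad = 0),
               rep(0, 16))
  # peak at k0 when the window holds one wavelength
  kg <- seq(0.2, 2.5, length.out = 2048)
  g <- analytic_g(kg, k0_per_um = 2 * pi / 10, window_um = 10)
  expect_equal(kg[which.max(g)], 2 * pi / 10, tolerance = 2 * (kg[2] - kg[1]))
  # quadrature oracle with an 8-point phase grid (exact for a beat average)
  set.seed(1)
  for (i in 1:5) {
    k0 <- runif(1, 0.4, 1.3); Lw <- runif(1, 8, 22); k <- runif(1, 0.3, 2)
    num <- quadrature_g(k, k0, Lw, 0.5)
    expect_equal(analytic_g(k, k0, Lw, 0.5), num,
                 tolerance = 1e-9)
  }
})

test_that("bias curve is small beyond ratio one and reports the boundary regime", {
  bc <- bias_curve(c(0.5, 1, 2), wavelength_um = 10)
  expect_true(all(abs(bc$rel_error[bc$ratio >= 1]) < 0.01))
  expect_named(bc, c("ratio", "length_um", "lambda_hat_um", "rel_error",
                     "flagged"))
})

test_that("trimming to the interior window shifts the effective window ratio", {
  # with lambda = L, analysing the middle 80% shortens the window below the
  # wavelength and re-introduces a finite-window bias of a few percent
  bc_full <- bias_curve(1, wavelength_um = 10, s_trim = 0)
  bc_trim <- bias_curve(1, wavelength_um = 10, s_trim = 0.1)
  expect_lt(abs(bc_full$rel_error), 0.01)
  expect_gt(abs(bc_trim$rel_error), abs(bc_full$rel_error))
})
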