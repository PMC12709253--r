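test_that("amplitude-zero field is the static arc, identical in every frame", {
  fld <- generate_tangent_field(beat_params(amplitude_rad = 0,
                                            static_curvature_per_um = 0.2,
                                            n_frames = 50))
  expect_equal(fld$psi[, 1], 0.2 * fld$s_um, tolerance = 1e-12)
  expect_true(all(fld$psi == fld$psi[, 1]))
})

test_that("noise-free field equals the closed form at every grid point", {
  p <- quiet_params(length_um = 10, wavelength_um = 10, amplitude_rad = 0.5,
                    frequency_hz = 65, phase_rad = 0.3, n_frames = 200)
  fld <- generate_tangent_field(p)
  expected <- 0.5 * sin(outer(2 * pi * fld$s_um / 10 + 0.3,
                              2 * pi * 65 * fld$t_s, `-`))
  expect_equal(fld$psi, expected, tolerance = 1e-14)
})

test_that("uniform angle noise has the moments of a centered uniform law", {
  p <- quiet_params(noise_level = 0.5, seed = 11)
  noisy <- generate_tangent_field(p)
  clean <- generate_tangent_field(quiet_params())
  eta <- noisy$psi - clean$psi
  half <- 0.5 * p$amplitude_rad           # +/- 0.25 rad
  n <- length(eta)
  sd_u <- half / sqrt(3)
  expect_lt(abs(mean(eta)), 3 * sd_u / sqrt(n))
  expect_equal(sd(eta), sd_u, tolerance = 0.02)
  expect_lte(max(abs(eta)), half)
})

test_that("identical params and seed give bit-identical outputs", {
  p <- quiet_params(noise_level = 0.3, seed = 42, n_frames = 60)
  expect_identical(generate_tangent_field(p)$psi,
                   generate_tangent_field(p)$psi)
  expect_identical(generate_centerlines(p)$x_um,
                   generate_centerlines(p)$x_um)
  p2 <- p; p2$seed <- 43
  expect_false(identical(generate_tangent_field(p)$psi,
                         generate_tangent_field(p2)$psi))
})

test_that("noise-free fields are periodic with period 1/f on the frame grid", {
  fld <- plane_wave_field(frequency_hz = 50, n_frames = 100)  # 20-frame period
  expect_equal(fld$psi[, 1:80], fld$psi[, 21:100], tolerance = 1e-10)
})

test_that("straight-field centerlines form a horizontal segment of length L", {
  p <- beat_params(amplitude_rad = 0, static_curvature_per_um = 0,
                   n_frames = 5)
  cl <- generate_centerlines(p)
  fr <- dplyr::filter(cl, frame == 1)
  expect_equal(fr$y_um, rep(0, nrow(fr)), tolerance = 1e-12)
  expect_lt(abs(max(fr$x_um) - p$length_um), p$ds_um)
})

test_that("constant-curvature centerlines lie on a circle of radius 1/C0", {
  p <- beat_params(amplitude_rad = 0, static_curvature_per_um = 0.2,
                   n_frames = 3)
  cl <- generate_centerlines(p)
  fr <- dplyr::filter(cl, frame == 1)
  # starts at origin heading +x, so the center is at (0, R)
  r <- sqrt(fr$x_um^2 + (fr$y_um - 5)^2)
  expect_lt(max(abs(r - 5)), 1e-6)
})

test_that("tangent field round-trips through centerlines across parameter draws", {
  cases <- list(
    quiet_params(length_um = 10, wavelength_um = 10, n_frames = 30),
    quiet_params(length_um = 15, wavelength_um = 12, amplitude_rad = 0.7,
                 n_frames = 30),
    beat_params(length_um = 12, wavelength_um = 12,
                static_curvature_per_um = 0.2, rotation_rate_rad_s = 0,
                n_frames = 30)
  )
  for (p in cases) {
    fld0 <- generate_tangent_field(p)
    fld1 <- centerline_to_tangent_field(generate_centerlines(p), p$ds_um)
    n <- min(nrow(fld0$psi), nrow(fld1$psi))
    expect_lt(max(abs(fld1$psi[1:n, ] - fld0$psi[1:n, ])), 0.01)
  }
})

test_that("parameter validation names the offending field", {
  expect_error(beat_params(length_um = -1), "length_um",
               class = "ciliawave_parameter_error")
  expect_error(beat_params(noise_level = -0.1), "noise_level",
               class = "ciliawave_parameter_error")
  expect_error(beat_params(n_frames = 1), "n_frames",
               class = "ciliawave_parameter_error")
})

test_that("centerline CSV round-trips through write/read", {
  p <- quiet_params(n_frames = 4)
  cl <- generate_centerlines(p)
  path <- withr::local_tempfile(fileext = ".csv")
  write_centerlines(cl, path)
  back <- read_centerlines(path)
  expect_equal(back$x_um, cl$x_um, tolerance = 1e-12)
  expect_equal(back$frame, cl$frame)
})
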