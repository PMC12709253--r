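test_that("rotation removal leaves a non-rotating record essentially unchanged", {
  fld <- plane_wave_field(n_frames = 400)
  out <- remove_rotation(fld)
  expect_lt(abs(out$rotation_rate_rad_s), 0.3)
  # trend is close to the (zero) mean of the leading oscillation
  expect_lt(max(abs(out$rotation_trend[20:380])), 0.05)
})

test_that("a pure linear trend is reproduced and cancelled by LOESS", {
  s <- seq(0, 10, by = 0.218)
  tt <- (0:499) * 1e-3
  fld <- ciliawave:::new_tangent_field(outer(rep(1, length(s)), tt), s, tt)
  out <- remove_rotation(fld, loess_frac = 0.3)
  inner <- 25:475
  expect_lt(max(abs(out$psi[1, inner])), 0.01)
  expect_equal(out$rotation_rate_rad_s, 1, tolerance = 0.02)
})

test_that("rotation rate of a rotating synthetic beat is recovered within 5%", {
  p <- beat_params(rotation_rate_rad_s = 2, static_curvature_per_um = 0)
  fld <- generate_tangent_field(p)
  rotated <- ciliawave:::new_tangent_field(
    sweep(fld$psi, 2, 2 * fld$t_s, `+`), fld$s_um, fld$t_s)
  out <- remove_rotation(rotated)
  expect_equal(out$rotation_rate_rad_s, 2, tolerance = 0.05)
})

test_that("beat segmentation windows follow integer frame arithmetic", {
  fld <- plane_wave_field(frequency_hz = 50)
  seg <- segment_beats(fld, 50)
  expect_equal(seg$n_beats, 50)
  expect_equal(seg$frames_per_beat, 20)
  expect_true(all(diff(seg$beat_windows$start_frame) == 20))

  seg65 <- segment_beats(fld, 65)        # period 15.38 -> 15-frame windows
  expect_equal(seg65$frames_per_beat, 15)
  expect_equal(seg65$n_beats, 66)
  expect_equal(max(seg65$beat_windows$end_frame), 990)

  expect_error(segment_beats(fld, 400), class = "ciliawave_input_error")
  expect_error(segment_beats(fld, 0.5), class = "ciliawave_parameter_error")
})

test_that("decomposing a time-constant field gives zero dynamics and its slope", {
  s <- seq(0, 10, by = 0.218)
  tt <- (0:99) * 1e-3
  fld <- ciliawave:::new_tangent_field(
    matrix(0.2 * s, nrow = length(s), ncol = length(tt)), s, tt)
  seg <- segment_beats(fld, 65)
  dec <- decompose_beat(fld, seg)
  expect_equal(max(abs(dec$psi_dynamic$psi)), 0)
  expect_equal(dec$static_curvature_per_um, 0.2, tolerance = 1e-12)
})

test_that("zero-mean sinusoid over integer beats has a null static component", {
  fld <- plane_wave_field(frequency_hz = 50)  # 50 exact 20-frame cycles
  seg <- segment_beats(fld, 50)
  dec <- decompose_beat(fld, seg)
  expect_lt(max(abs(dec$psi_static)), 1e-12)
})

test_that("static curvature of a synthetic beat is recovered within 2%", {
  fld <- generate_tangent_field(beat_params(static_curvature_per_um = 0.2))
  seg <- segment_beats(fld, 65)
  dec <- decompose_beat(fld, seg)
  expect_equal(dec$static_curvature_per_um, 0.2, tolerance = 0.02)
})

test_that("static plus dynamic reconstructs the field to machine precision", {
  fld <- generate_tangent_field(beat_params(noise_level = 0.2, seed = 5,
                                            n_frames = 200))
  seg <- segment_beats(fld, 65)
  dec <- decompose_beat(fld, seg)
  expect_equal(dec$psi_dynamic$psi + dec$psi_static, fld$psi,
               tolerance = 1e-14)
})

test_that("decomposition is idempotent on the dynamic field", {
  fld <- plane_wave_field(frequency_hz = 50, n_frames = 200)
  seg <- segment_beats(fld, 50)
  dec <- decompose_beat(fld, seg)
  dec2 <- decompose_beat(dec$psi_dynamic, seg)
  expect_lt(max(abs(dec2$psi_static)), 1e-12)
})

test_that("decompose refuses segmentations without complete windows", {
  fld <- plane_wave_field(n_frames = 100)
  seg <- segment_beats(fld, 65)
  seg$beat_windows <- seg$beat_windows[0, ]
  seg$n_beats <- 0L
  expect_error(decompose_beat(fld, seg), class = "ciliawave_input_error")
})
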