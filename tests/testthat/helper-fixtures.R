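# quick parameter sets used across tests; short records where accuracy allows
quiet_params <- function(...) {
  beat_params(static_curvature_per_um = 0, rotation_rate_rad_s = 0, ...)
}

# a plain-wave tangent field with everything but the traveling wave turned off
plane_wave_field <- function(length_um = 10, wavelength_um = 10,
                             frequency_hz = 65, n_frames = 1000, ...) {
  generate_tangent_field(quiet_params(length_um = length_um,
                                      wavelength_um = wavelength_um,
                                      frequency_hz = frequency_hz,
                                      n_frames = n_frames, ...))
}

# length on the 0.218-um sampling grid, so the realized window equals L
grid_length <- function(n_steps, ds = 0.218) n_steps * ds

# independent oracle for the beat-averaged spectrum: composite-Simpson
# quadrature of the defining integrals (2e4 panels, error ~1e-12 relative),
# averaged over an 8-point phase grid (exact for the second-degree
# trigonometric polynomial a beat average involves)
quadrature_g <- function(k, k0, Lw, a = 1) {
  n <- 20000L
  s <- seq(0, Lw, length.out = n + 1L)
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1) * (Lw / n) / 3
  phases <- 2 * pi * (0:7) / 8
  mean(vapply(phases, function(ph) {
    psi <- a * sin(k0 * s - ph)
    sum(w * psi * cos(k * s))^2 + sum(w * psi * sin(k * s))^2
  }, numeric(1)))
}
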