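#' Parameters of a synthetic traveling-wave beat
#'
#' Bundles the geometric, kinematic and sampling parameters of a simulated
#' axonemal beat. The tangent angle is modelled as a static circular arc plus
#' a traveling sinusoid,
#' \deqn{\psi(s, t) = C_0 s + a \sin(2\pi s/\lambda_0 - 2\pi f t + \phi) + \eta,}
#' optionally corrupted by i.i.d. uniform angle noise \eqn{\eta} on
#' \eqn{\pm(\mathrm{noise\_level} \cdot a)}. Defaults emulate reactivated
#' *Chlamydomonas* axonemes imaged at high speed: 1000 frames at 1 ms,
#' 0.218 um arc-length sampling, ~65 Hz beat, static curvature 0.2 rad/um.
#'
#' @param length_um Axoneme length L (um).
#' @param wavelength_um True wavelength \eqn{\lambda_0} (um).
#' @param amplitude_rad Tangent-angle amplitude a (rad).
#' @param frequency_hz Beat frequency f (Hz).
#' @param static_curvature_per_um Static curvature \eqn{C_0} (rad/um); the
#'   slope of the time-averaged tangent angle versus arc length.
#' @param rotation_rate_rad_s Rigid-body rotation rate \eqn{\Omega} (rad/s)
#'   of the circularly swimming frame.
#' @param phase_rad Initial phase \eqn{\phi} (rad).
#' @param noise_level Relative amplitude of additive uniform angle noise;
#'   0.5 means noise uniform on \eqn{\pm 0.5 a}.
#' @param amplitude_taper Linear amplitude taper: local amplitude is
#'   \eqn{a (1 - \mathrm{taper}(1 - s/L))}, so 0 gives a uniform amplitude and
#'   1 tapers to zero at the base. No measured value constrains this; it is
#'   exposed for sensitivity checks only.
#' @param xy_jitter_um Standard deviation of optional independent Gaussian
#'   jitter added to centerline coordinates (um), emulating tracker noise.
#' @param ds_um Arc-length sample spacing (um).
#' @param dt_s Frame interval (s).
#' @param n_frames Number of frames.
#' @param seed Integer RNG seed used for the noise draws, or `NULL`.
#'
#' @return An object of class `beat_params` (a validated named list).
#' @examples
#' p <- beat_params(length_um = 10, wavelength_um = 10)
#' p$frequency_hz
#' @export
beat_params <- function(length_um = 10,
                        wavelength_um = 10,
                        amplitude_rad = 0.5,
                        frequency_hz = 65,
                        static_curvature_per_um = 0.2,
                        rotation_rate_rad_s = 0,
                        phase_rad = 0,
                        noise_level = 0,
                        amplitude_taper = 0,
                        xy_jitter_um = 0,
                        ds_um = 0.218,
                        dt_s = 0.001,
                        n_frames = 1000,
                        seed = NULL) {
  p <- list(
    length_um = length_um, wavelength_um = wavelength_um,
    amplitude_rad = amplitude_rad, frequency_hz = frequency_hz,
    static_curvature_per_um = static_curvature_per_um,
    rotation_rate_rad_s = rotation_rate_rad_s, phase_rad = phase_rad,
    noise_level = noise_level, amplitude_taper = amplitude_taper,
    xy_jitter_um = xy_jitter_um, ds_um = ds_um, dt_s = dt_s,
    n_frames = n_frames, seed = seed
  )
  validate_beat_params(p)
  structure(p, class = "beat_params")
}

validate_beat_params <- function(p) {
  check_pos <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive finite number.", field),
            class = "ciliawave_parameter_error")
    }
  }
  for (f in c("length_um", "wavelength_um", "ds_um", "dt_s", "frequency_hz")) {
    check_pos(f)
  }
  for (f in c("amplitude_rad", "static_curvature_per_um",
              "rotation_rate_rad_s", "phase_rad", "noise_level",
              "amplitude_taper", "xy_jitter_um")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number.", f),
            class = "ciliawave_parameter_error")
    }
  }
  if (p$noise_level < 0) {
    abort("`noise_level` must be >= 0.", class = "ciliawave_parameter_error")
  }
  if (p$n_frames < 2) {
    abort("`n_frames` must be >= 2.", class = "ciliawave_parameter_error")
  }
  invisible(p)
}

#' @export
print.beat_params <- function(x, ...) {
  cat("<beat_params>\n")
  cat(sprintf("  L = %g um, lambda0 = %g um, a = %g rad, f = %g Hz\n",
              x$length_um, x$wavelength_um, x$amplitude_rad, x$frequency_hz))
  cat(sprintf("  C0 = %g rad/um, Omega = %g rad/s, noise = %g\n",
              x$static_curvature_per_um, x$rotation_rate_rad_s, x$noise_level))
  cat(sprintf("  grid: ds = %g um, dt = %g s, %d frames\n",
              x$ds_um, x$dt_s, as.integer(x$n_frames)))
  invisible(x)
}

#' Configuration for the beat-analysis pipeline
#'
#' Collects the tunable estimator and preprocessing parameters used by
#' [analyze_axoneme()]. All values have working defaults.
#'
#' @param ds_um Arc-length resampling interval (um) for the tangent field.
#' @param loess_frac LOESS span for rotation removal as a fraction of the
#'   record, or `NULL` to derive it as the fraction covering
#'   `loess_beats` beat periods of a provisional frequency estimate.
#' @param loess_beats Number of beat periods the automatic LOESS span covers.
#' @param s_trim Fraction trimmed from each end of the arc length before the
#'   wavelength integrals (0.1 analyses the middle 80%, appropriate for
#'   tracked microscopy traces whose ends are least reliable; 0 uses the full
#'   window, appropriate for simulated beats).
#' @param k_n Number of wavenumber grid points for the spectrum search.
#' @param length_dev_tol Relative deviation from the median frame length
#'   beyond which a frame is flagged as a likely tracking failure.
#' @param smooth_um Arc-length width (um) of the running-mean smoothing
#'   applied before zero-crossing detection in [wave_velocity()].
#' @param seed Integer seed recorded in reports.
#' @return An object of class `beat_config` (a named list).
#' @examples
#' cfg <- beat_config(s_trim = 0.1)
#' @export
beat_config <- function(ds_um = 0.218,
                        loess_frac = NULL,
                        loess_beats = 5,
                        s_trim = 0,
                        k_n = 2048,
                        length_dev_tol = 0.05,
                        smooth_um = 0.5,
                        seed = NULL) {
  cfg <- list(ds_um = ds_um, loess_frac = loess_frac,
              loess_beats = loess_beats, s_trim = s_trim, k_n = k_n,
              length_dev_tol = length_dev_tol, smooth_um = smooth_um,
              seed = seed)
  if (ds_um <= 0) abort("`ds_um` must be positive.",
                        class = "ciliawave_parameter_error")
  if (s_trim < 0 || s_trim >= 0.5) {
    abort("`s_trim` must lie in [0, 0.5).", class = "ciliawave_parameter_error")
  }
  structure(cfg, class = "beat_config")
}

#' Read or write configuration and parameters as YAML
#'
#' @param x A `beat_config` or `beat_params` object.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns
#'   a `beat_config`; `read_beat_params()` a `beat_params`.
#' @export
write_config <- function(x, path) {
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(beat_config, yaml::read_yaml(path))
}

#' @rdname write_config
#' @export
read_beat_params <- function(path) {
  do.call(beat_params, yaml::read_yaml(path))
}
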