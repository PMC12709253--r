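#' Tidy a tangent field into a long tibble
#'
#' @param x A `tangent_field`.
#' @param ... Unused.
#' @return A tibble with columns `s_um`, `t_s`, `psi_rad`.
#' @export
tidy.tangent_field <- function(x, ...) {
  tibble(
    s_um = rep(x$s_um, times = length(x$t_s)),
    t_s = rep(x$t_s, each = length(x$s_um)),
    psi_rad = as.vector(x$psi)
  )
}

#' Tidy a beat decomposition (static profile)
#'
#' @param x A `beat_decomposition`.
#' @param ... Unused.
#' @return A tibble with `s_um` and `psi_static_rad`.
#' @export
tidy.beat_decomposition <- function(x, ...) {
  tibble(s_um = x$s_um, psi_static_rad = x$psi_static)
}

#' @export
glance.beat_decomposition <- function(x, ...) {
  tibble(static_curvature_per_um = x$static_curvature_per_um,
         rotation_rate_rad_s = x$rotation_rate_rad_s %||% NA_real_,
         n_arc_points = length(x$s_um),
         n_frames_used = length(x$frames_used))
}

#' Tidy a spatial power spectrum
#'
#' @param x A `spectrum_g`.
#' @param ... Unused.
#' @return A tibble with `k_per_um`, `lambda_um`, `G`.
#' @export
tidy.spectrum_g <- function(x, ...) {
  tibble(k_per_um = x$k_per_um, lambda_um = 2 * pi / x$k_per_um, G = x$G)
}

#' Tidy a wavelength estimate into per-beat rows
#'
#' @param x A `wavelength_estimate`.
#' @param ... Unused.
#' @return A tibble with `beat` and `lambda_um`.
#' @export
tidy.wavelength_estimate <- function(x, ...) {
  tibble(beat = seq_along(x$per_beat_lambda_um),
         lambda_um = x$per_beat_lambda_um)
}

#' @export
glance.wavelength_estimate <- function(x, ...) {
  tibble(lambda_um = x$lambda_um, sem_um = x$sem_um,
         k0_per_um = x$k0_per_um, n_beats = x$n_beats,
         flagged = length(x$flags) > 0)
}

#' Tidy the crossing test
#'
#' @param x A `crossing_test`.
#' @param ... Unused.
#' @return One-row tibble with the count, statistic and p-values.
#' @export
tidy.crossing_test <- function(x, ...) {
  tibble(n_crossings = x$n_crossings, N = x$N, se = x$se,
         statistic = x$t_stat, df = x$df, p.value = x$p_value,
         p.adjusted = x$p_adjusted, significant = x$significant)
}

#' @export
glance.crossing_test <- function(x, ...) tidy(x)

#' Tidy the slope-significance regression
#'
#' @param x A `slope_significance`.
#' @param ... Unused.
#' @return One-row tibble with slope, intercept, SE and the 2-SE verdict.
#' @export
tidy.slope_significance <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, slope_se = x$slope_se,
         significant = x$significant, n = x$n)
}

#' @export
glance.beat_kinematics <- function(x, ...) {
  tibble(frequency_hz = x$frequency_hz,
         wave_velocity_um_s = x$wave_velocity_um_s,
         lambda_vf_um = x$lambda_vf_um, n_tracks = x$n_tracks)
}

#' One-row summary of an axoneme analysis
#'
#' @param x An `axoneme_report`.
#' @param ... Unused.
#' @return A tibble with the per-axoneme quantities the pipeline reports:
#'   length, wavelength with SEM, frequency, wave velocity, v/f wavelength,
#'   static curvature, rotation rate, beat count and flags.
#' @export
glance.axoneme_report <- function(x, ...) {
  tibble(id = x$id, length_um = x$length_um,
         lambda_um = x$lambda_um, sem_um = x$sem_um,
         frequency_hz = x$frequency_hz,
         wave_velocity_um_s = x$wave_velocity_um_s,
         lambda_vf_um = x$lambda_vf_um,
         static_curvature_per_um = x$static_curvature_per_um,
         rotation_rate_rad_s = x$rotation_rate_rad_s,
         n_beats = x$n_beats, n_tracks = x$n_tracks,
         flags = paste(x$flags, collapse = ";"))
}

#' Plot a tangent field as a kymograph-style heatmap
#'
#' @param object A `tangent_field`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tangent_field <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$t_s, y = .data$s_um,
                               fill = .data$psi_rad)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(name = "psi (rad)") +
    ggplot2::labs(x = "time (s)", y = "arc length (um)",
                  title = "Tangent-angle field")
}

#' Plot a beat decomposition: static profile and dynamic envelope
#'
#' @param object A `beat_decomposition`.
#' @param ... Unused.
#' @return A ggplot of the static tangent-angle profile with its linear
#'   (constant-curvature) fit, plus the min/max envelope of the dynamic
#'   component.
#' @export
autoplot.beat_decomposition <- function(object, ...) {
  dyn <- object$psi_dynamic$psi
  df <- tibble(s_um = object$s_um,
               psi_static = object$psi_static,
               dyn_lo = apply(dyn, 1, min),
               dyn_hi = apply(dyn, 1, max))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s_um)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$dyn_lo,
                                      ymax = .data$dyn_hi),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$psi_static)) +
    ggplot2::geom_abline(slope = object$static_curvature_per_um,
                         intercept = object$psi_static[1], linetype = 2) +
    ggplot2::labs(x = "arc length (um)", y = "tangent angle (rad)",
                  title = "Static profile and dynamic envelope")
}

#' Plot a spatial power spectrum
#'
#' @param object A `spectrum_g`.
#' @param ... Unused.
#' @return A ggplot of G versus wavenumber with the peak marked.
#' @export
autoplot.spectrum_g <- function(object, ...) {
  df <- tidy(object)
  kpk <- df$k_per_um[which.max(df$G)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k_per_um, y = .data$G)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = kpk, linetype = 2) +
    ggplot2::labs(x = "wavenumber k (rad/um)",
                  y = "G (rad^2 um^2)",
                  title = "Finite-window spatial power spectrum")
}

#' Plot per-beat wavelengths
#'
#' @param object A `wavelength_estimate`.
#' @param ... Unused.
#' @return A ggplot of per-beat wavelength with the pooled mean.
#' @export
autoplot.wavelength_estimate <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$beat, y = .data$lambda_um)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$lambda_um, linetype = 2) +
    ggplot2::labs(x = "beat cycle", y = "wavelength (um)",
                  title = sprintf("Per-beat wavelength (mean %.3g +/- %.2g um)",
                                  object$lambda_um, object$sem_um))
}

#' Plot the estimator's systematic-error curve
#'
#' @param bias A tibble from [bias_curve()].
#' @return A ggplot of relative error (%) versus window/wavelength ratio.
#' @export
plot_bias_curve <- function(bias) {
  ggplot2::ggplot(bias, ggplot2::aes(x = .data$ratio,
                                     y = 100 * .data$rel_error)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "window length / wavelength",
                  y = "relative error (%)",
                  title = "Wavelength-estimator systematic error")
}
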