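#' Remove the rigid-body rotation of a circularly swimming axoneme
#'
#' Isolated axonemes swim in circles, so the lab-frame tangent angle drifts.
#' The leading (basal) tangent angle \eqn{\psi(0, t)} oscillates around an
#' increasing trend; that trend is estimated by LOESS regression after
#' unwrapping in time, and subtracted from \eqn{\psi(s, t)} at every arc
#' position, frame by frame. The fitted trend and its least-squares slope
#' (the rotation rate, rad/s) are stored on the returned field.
#'
#' The default span is the fraction of the record covering `loess_beats`
#' beat periods of a provisional frequency estimated from the leading
#' angle's spectrum, so the trend is smooth on the beat timescale.
#'
#' @param field A `tangent_field` with at least 10 frames.
#' @param loess_frac LOESS span in (0, 1), or `NULL` for the automatic span.
#' @param loess_beats Beat periods the automatic span covers.
#' @return A `tangent_field` with the trend subtracted; components
#'   `rotation_trend`, `rotation_rate_rad_s` and `loess_frac` are filled in.
#' @examples
#' fld <- generate_tangent_field(beat_params(n_frames = 200))
#' out <- remove_rotation(fld)
#' out$rotation_rate_rad_s
#' @export
remove_rotation <- function(field, loess_frac = NULL, loess_beats = 5) {
  stopifnot(inherits(field, "tangent_field"))
  n_t <- ncol(field$psi)
  if (n_t < 10) abort("Rotation removal needs at least 10 frames.",
                      class = "ciliawave_input_error")
  tt <- field$t_s
  if (length(unique(tt)) < 2) {
    abort("Degenerate time grid: all frame times equal.",
          class = "ciliawave_input_error")
  }
  theta <- unwrap_s(field$psi[1, ])  # leading angle, unwrapped in time
  if (is.null(loess_frac)) {
    f_prov <- provisional_frequency(theta, field$dt_s)
    duration <- tt[n_t] - tt[1]
    loess_frac <- if (is.na(f_prov)) 0.3 else {
      min(1, max(0.05, loess_beats / (f_prov * duration)))
    }
  }
  fit <- loess(theta ~ tt, span = loess_frac, degree = 2,
               family = "gaussian",
               control = loess.control(surface = "direct"))
  trend <- stats::fitted(fit)
  rate <- unname(coef(lm(trend ~ tt))[2])
  out <- new_tangent_field(sweep(field$psi, 2, trend, `-`),
                           field$s_um, field$t_s,
                           rotation_trend = trend,
                           rotation_rate_rad_s = rate,
                           loess_frac = loess_frac)
  attr(out, "flagged_frames") <- attr(field, "flagged_frames")
  out
}

# coarse spectral peak of the (detrended) leading angle; NA if featureless
provisional_frequency <- function(theta, dt) {
  n <- length(theta)
  tt <- seq_len(n)
  res <- stats::residuals(lm(theta ~ tt))
  pw <- Mod(fft(res))^2
  half <- 2:floor(n / 2)
  i <- half[which.max(pw[half])]
  if (pw[i] <= .Machine$double.eps * sum(pw[half])) return(NA_real_)
  (i - 1) / (n * dt)
}

#' Partition a record into consecutive beat windows
#'
#' Frames are grouped into consecutive windows of `round(1 / (f dt))` frames
#' starting at the first frame; a trailing partial window is discarded.
#' Per-beat averaging over these windows reduces estimator variance.
#'
#' @param field A `tangent_field`.
#' @param frequency_hz Beat frequency (Hz), typically a provisional estimate
#'   from [beat_frequency()].
#' @return A `beat_segmentation`: tibble `beat_windows` with 1-based
#'   inclusive `start_frame`, `end_frame`, plus `n_beats` and
#'   `frames_per_beat`.
#' @examples
#' fld <- generate_tangent_field(beat_params(frequency_hz = 50))
#' segment_beats(fld, 50)$n_beats
#' @export
segment_beats <- function(field, frequency_hz) {
  stopifnot(inherits(field, "tangent_field"))
  n_t <- ncol(field$psi)
  dt <- field$dt_s
  duration <- n_t * dt
  if (frequency_hz <= 1 / duration || frequency_hz >= 1 / (2 * dt)) {
    abort("`frequency_hz` must lie between 1/duration and the Nyquist frequency.",
          class = "ciliawave_parameter_error")
  }
  nper <- round(1 / (frequency_hz * dt))
  if (nper < 3) {
    abort("Beat period shorter than 3 frames: undersampled record.",
          class = "ciliawave_input_error")
  }
  n_beats <- floor(n_t / nper)
  if (n_beats < 1) {
    abort("Record shorter than one beat period.",
          class = "ciliawave_input_error")
  }
  start <- (seq_len(n_beats) - 1L) * nper + 1L
  structure(
    list(beat_windows = tibble(start_frame = start,
                               end_frame = start + nper - 1L),
         n_beats = n_beats, frames_per_beat = nper),
    class = "beat_segmentation"
  )
}

#' @export
print.beat_segmentation <- function(x, ...) {
  cat(sprintf("<beat_segmentation> %d beats x %d frames\n",
              x$n_beats, x$frames_per_beat))
  invisible(x)
}

#' Decompose a tangent field into static and dynamic components
#'
#' The static component \eqn{\bar\psi(s)} is the average tangent angle over
#' complete beat cycles at each arc position (a circular arc for
#' *Chlamydomonas*); the dynamic component is the residual
#' \eqn{\psi_d(s,t) = \psi(s,t) - \bar\psi(s)}. The static curvature is the
#' ordinary least-squares slope of \eqn{\bar\psi(s)} versus s, the static
#' profile being approximately linear. Averaging is restricted to complete
#' beat windows so a partial final cycle does not bias the static profile.
#'
#' @param field A rotation-subtracted `tangent_field` (see
#'   [remove_rotation()]).
#' @param seg A `beat_segmentation` with at least one complete window.
#' @return A `beat_decomposition`: `psi_static` (vector over s),
#'   `psi_dynamic` (`tangent_field`), `static_curvature_per_um`,
#'   `rotation_trend`, plus the grids.
#' @examples
#' fld <- generate_tangent_field(beat_params(n_frames = 200))
#' seg <- segment_beats(fld, 65)
#' decompose_beat(fld, seg)$static_curvature_per_um
#' @export
decompose_beat <- function(field, seg) {
  stopifnot(inherits(field, "tangent_field"),
            inherits(seg, "beat_segmentation"))
  if (seg$n_beats < 1 || nrow(seg$beat_windows) < 1) {
    abort("No complete beat window: record a longer series.",
          class = "ciliawave_input_error")
  }
  if (max(seg$beat_windows$end_frame) > ncol(field$psi)) {
    abort("Beat segmentation extends beyond the recorded frames.",
          class = "ciliawave_input_error")
  }
  used <- unlist(purrr::map2(seg$beat_windows$start_frame,
                             seg$beat_windows$end_frame, seq))
  psi_static <- rowMeans(field$psi[, used, drop = FALSE])
  psi_dyn <- field$psi - psi_static
  slope <- unname(coef(lm(psi_static ~ field$s_um))[2])
  structure(
    list(psi_static = psi_static,
         psi_dynamic = new_tangent_field(psi_dyn, field$s_um, field$t_s),
         static_curvature_per_um = slope,
         rotation_trend = field$rotation_trend,
         rotation_rate_rad_s = field$rotation_rate_rad_s,
         s_um = field$s_um, t_s = field$t_s,
         frames_used = used),
    class = "beat_decomposition"
  )
}

#' @export
print.beat_decomposition <- function(x, ...) {
  cat(sprintf("<beat_decomposition> static curvature %.4g rad/um over %d arc points\n",
              x$static_curvature_per_um, length(x$s_um)))
  invisible(x)
}
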