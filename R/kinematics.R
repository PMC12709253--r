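#' Beat frequency by discrete Fourier transform
#'
#' Computes the temporal power spectrum of the dynamic tangent angle at each
#' arc position, averages the spectra over arc length, and locates the
#' dominant peak. The peak bin is refined by fitting a parabola through the
#' bin and its two neighbours in log power, a standard first-order-unbiased
#' interpolation of a DFT peak. Refinement is skipped when a neighbour bin
#' is numerically empty (an exactly on-grid tone).
#'
#' @param psi_dynamic A `tangent_field` holding the dynamic component
#'   \eqn{\psi_d(s,t)} (or a `beat_decomposition`).
#' @param dt_s Frame interval; taken from the field when omitted.
#' @return Refined beat frequency (Hz).
#' @examples
#' fld <- generate_tangent_field(beat_params(static_curvature_per_um = 0))
#' beat_frequency(fld)
#' @export
beat_frequency <- function(psi_dynamic, dt_s = NULL) {
  if (inherits(psi_dynamic, "beat_decomposition")) {
    psi_dynamic <- psi_dynamic$psi_dynamic
  }
  stopifnot(inherits(psi_dynamic, "tangent_field"))
  psi <- psi_dynamic$psi
  dt <- dt_s %||% psi_dynamic$dt_s
  n <- ncol(psi)
  if (n < 8) abort("Frequency estimation needs at least 8 frames.",
                   class = "ciliawave_input_error")
  # remove the per-s time mean so static offsets do not leak into bin 1
  psi <- psi - rowMeans(psi)
  pw <- colMeans(Mod(t(stats::mvfft(t(psi))))^2)  # averaged over s
  half <- 2:(floor(n / 2) + 1)                    # positive frequencies
  i <- half[which.max(pw[half])]
  if (i == half[1] || i == half[length(half)]) {
    abort("Spectral peak at DC or Nyquist: no resolvable oscillation.",
          class = "ciliawave_input_error")
  }
  if (pw[i] < 10 * stats::median(pw[half])) {
    abort("No prominent spectral peak: no resolvable oscillation.",
          class = "ciliawave_input_error")
  }
  freqs <- (seq_len(n) - 1) / (n * dt)
  parabolic_peak(freqs, pw, i, log_y = TRUE)
}

#' Wave propagation velocity by zero-crossing tracking
#'
#' Locates the zero crossings of the dynamic tangent angle
#' \eqn{\psi_d(s)} in every frame (sign change plus linear interpolation in
#' s, after a light running-mean smoothing over `smooth_um` of arc length to
#' suppress spurious noise crossings), links crossings across consecutive
#' frames by nearest neighbour within a displacement gate, fits a line to
#' arc position versus time for each track, and returns the mean slope over
#' tracks. Positive velocity means base-to-tip propagation. The gate is
#' 1.5x the per-frame displacement expected from a coarse first pass, with a
#' floor of twice the arc-length spacing; tracks shorter than `min_track`
#' frames, and crossings entering or leaving the window, terminate or are
#' discarded.
#'
#' @param psi_dynamic A `tangent_field` with the dynamic component (or a
#'   `beat_decomposition`).
#' @param smooth_um Running-mean width (um) used only for crossing
#'   detection; 0 disables smoothing.
#' @param min_track Minimum frames per retained track.
#' @return A `wave_velocity` object: `wave_velocity_um_s` (mean slope),
#'   `per_track_velocities`, `n_tracks`, and the crossing table.
#' @examples
#' fld <- generate_tangent_field(beat_params(static_curvature_per_um = 0,
#'                                           n_frames = 200))
#' wave_velocity(fld)$wave_velocity_um_s
#' @export
wave_velocity <- function(psi_dynamic, smooth_um = 0.5, min_track = 3) {
  if (inherits(psi_dynamic, "beat_decomposition")) {
    psi_dynamic <- psi_dynamic$psi_dynamic
  }
  stopifnot(inherits(psi_dynamic, "tangent_field"))
  psi <- psi_dynamic$psi
  s <- psi_dynamic$s_um
  tt <- psi_dynamic$t_s
  ds <- psi_dynamic$ds_um
  if (smooth_um > 0) {
    wlen <- max(1L, round(smooth_um / ds))
    if (wlen %% 2 == 0) wlen <- wlen + 1L
    if (wlen > 1 && wlen < length(s)) {
      kern <- rep(1 / wlen, wlen)
      psi <- apply(psi, 2, function(col) {
        sm <- stats::filter(col, kern, sides = 2)
        idx <- is.na(sm)
        sm[idx] <- col[idx]  # keep raw values at the ends
        as.numeric(sm)
      })
    }
  }
  crossings <- lapply(seq_along(tt), function(j) frame_crossings(psi[, j], s))
  tracks1 <- link_crossings(crossings, gate = diff(range(s)) / 8)
  v1 <- track_velocities(tracks1, tt, min_track)
  gate <- max(2 * ds,
              1.5 * abs(stats::median(v1, na.rm = TRUE)) *
                (tt[2] - tt[1]))
  if (!is.finite(gate) || gate <= 0) gate <- 2 * ds
  tracks <- link_crossings(crossings, gate = gate)
  v <- track_velocities(tracks, tt, min_track)
  if (length(v) == 0) {
    abort("No linkable zero-crossing tracks: cannot estimate wave velocity.",
          class = "ciliawave_input_error")
  }
  structure(
    list(wave_velocity_um_s = mean(v),
         per_track_velocities = v,
         n_tracks = length(v),
         gate_um = gate,
         tracks = tracks),
    class = "wave_velocity"
  )
}

#' @export
print.wave_velocity <- function(x, ...) {
  cat(sprintf("<wave_velocity> v = %.4g um/s over %d tracks\n",
              x$wave_velocity_um_s, x$n_tracks))
  invisible(x)
}

# zero crossings of one profile: sign change + linear interpolation in s
frame_crossings <- function(psi, s) {
  sg <- sign(psi)
  flip <- which(sg[-1] * sg[-length(sg)] < 0)
  if (length(flip) == 0) return(numeric())
  s[flip] + (0 - psi[flip]) / (psi[flip + 1] - psi[flip]) * (s[flip + 1] - s[flip])
}

# greedy nearest-neighbour linking of per-frame crossing positions
link_crossings <- function(crossings, gate) {
  tracks <- list()      # finished
  active <- list()      # each: list(frames, pos)
  for (j in seq_along(crossings)) {
    cr <- crossings[[j]]
    matched_cr <- rep(FALSE, length(cr))
    keep <- logical(length(active))
    for (a in seq_along(active)) {
      last <- tail(active[[a]]$pos, 1)
      if (length(cr)) {
        d <- abs(cr - last)
        d[matched_cr] <- Inf
        m <- which.min(d)
        if (length(m) && is.finite(d[m]) && d[m] <= gate) {
          active[[a]]$frames <- c(active[[a]]$frames, j)
          active[[a]]$pos <- c(active[[a]]$pos, cr[m])
          matched_cr[m] <- TRUE
          keep[a] <- TRUE
          next
        }
      }
      tracks[[length(tracks) + 1L]] <- active[[a]]
    }
    active <- active[keep]
    for (m in which(!matched_cr)) {
      active[[length(active) + 1L]] <- list(frames = j, pos = cr[m])
    }
  }
  c(tracks, active)
}

track_velocities <- function(tracks, tt, min_track) {
  v <- purrr::map_dbl(tracks, function(tr) {
    if (length(tr$frames) < min_track) return(NA_real_)
    unname(coef(lm(tr$pos ~ tt[tr$frames]))[2])
  })
  v[is.finite(v)]
}

#' Joint beat kinematics: frequency, wave velocity and v/f wavelength
#'
#' Convenience wrapper computing [beat_frequency()] and [wave_velocity()] on
#' the same dynamic field and forming the conventional wavelength estimate
#' \eqn{\lambda_{v/f} = v/f}, used to cross-validate the Fourier-based
#' estimator.
#'
#' @inheritParams wave_velocity
#' @return A `beat_kinematics` object with `frequency_hz`,
#'   `wave_velocity_um_s`, `lambda_vf_um`, `per_track_velocities`,
#'   `n_tracks`.
#' @examples
#' fld <- generate_tangent_field(beat_params(static_curvature_per_um = 0,
#'                                           n_frames = 300))
#' beat_kinematics(fld)$lambda_vf_um
#' @export
beat_kinematics <- function(psi_dynamic, smooth_um = 0.5, min_track = 3) {
  f <- beat_frequency(psi_dynamic)
  wv <- wave_velocity(psi_dynamic, smooth_um = smooth_um,
                      min_track = min_track)
  structure(
    list(frequency_hz = f,
         wave_velocity_um_s = wv$wave_velocity_um_s,
         lambda_vf_um = wv$wave_velocity_um_s / f,
         per_track_velocities = wv$per_track_velocities,
         n_tracks = wv$n_tracks),
    class = "beat_kinematics"
  )
}

#' @export
print.beat_kinematics <- function(x, ...) {
  cat(sprintf("<beat_kinematics> f = %.4g Hz, v = %.4g um/s, v/f = %.4g um\n",
              x$frequency_hz, x$wave_velocity_um_s, x$lambda_vf_um))
  invisible(x)
}
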