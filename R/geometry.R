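#' Mean axoneme length by arc-length integration
#'
#' Sums segment chord lengths within each frame and averages over frames.
#' Bending does not change arc length, so per-frame lengths of a well-tracked
#' axoneme agree closely.
#'
#' @param series A `centerline_series` (see [as_centerline_series()]).
#' @return Mean length L over frames (um).
#' @examples
#' cl <- generate_centerlines(beat_params(n_frames = 20))
#' axoneme_length(cl)
#' @export
axoneme_length <- function(series) {
  series <- as_centerline_series(series)
  mean(frame_lengths(series)$length_um)
}

frame_lengths <- function(series) {
  dplyr::summarise(
    dplyr::group_by(series, .data$frame),
    length_um = sum(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2)),
    n_points = dplyr::n(),
    .groups = "drop"
  )
}

#' Convert centerline coordinates to a tangent-angle field
#'
#' For each frame: cumulative arc length from segment chords; cubic-spline
#' resampling of x(s), y(s) onto a regular arc-length grid of spacing
#' `ds_um` spanning `[0, L_min]` (the shortest frame length); tangent angle
#' by central differences of the resampled coordinates (one-sided at the
#' ends); unwrapping along arc length so no step between neighbouring
#' samples exceeds pi.
#'
#' Frames with fewer than 4 points are rejected with a warning. Frames whose
#' length deviates from the median by more than `length_dev_tol` are kept but
#' flagged (attribute `flagged_frames`), since length excursions usually mean
#' the tracker lost the filament tip.
#'
#' @param series A `centerline_series`.
#' @param ds_um Arc-length grid spacing (um); must be below L/4.
#' @param length_dev_tol Relative length-deviation threshold for flagging.
#' @return A `tangent_field` object.
#' @examples
#' cl <- generate_centerlines(beat_params(n_frames = 50))
#' fld <- centerline_to_tangent_field(cl)
#' range(fld$s_um)
#' @export
centerline_to_tangent_field <- function(series, ds_um = 0.218,
                                        length_dev_tol = 0.05) {
  series <- as_centerline_series(series)
  info <- frame_lengths(series)
  bad <- info$n_points < 4
  if (any(bad)) {
    warn(sprintf("Rejected %d frame(s) with fewer than 4 points.", sum(bad)))
    if (all(bad)) {
      abort("All frames rejected: fewer than 4 points each.",
            class = "ciliawave_input_error")
    }
    series <- dplyr::filter(series, !.data$frame %in% info$frame[bad])
    info <- info[!bad, ]
  }
  L_min <- min(info$length_um)
  if (ds_um >= L_min / 4) {
    abort("`ds_um` must be smaller than a quarter of the axoneme length.",
          class = "ciliawave_parameter_error")
  }
  med <- stats::median(info$length_um)
  flagged <- info$frame[abs(info$length_um / med - 1) > length_dev_tol]

  frames <- split(series[c("x_um", "y_um", "t_s")], series$frame)
  splines <- lapply(frames, function(fr) {
    s_raw <- c(0, cumsum(sqrt(diff(fr$x_um)^2 + diff(fr$y_um)^2)))
    list(fx = stats::splinefun(s_raw, fr$x_um, method = "fmm"),
         fy = stats::splinefun(s_raw, fr$y_um, method = "fmm"),
         length_um = spline_length(s_raw, fr$x_um, fr$y_um),
         t_s = fr$t_s[1])
  })
  # length by integration along the fitted spline: the raw chord sum
  # underestimates arc length by ~ (kappa ds)^2 / 24 per segment, enough to
  # clip one grid step off the analysis window
  L_min <- min(purrr::map_dbl(splines, "length_um"))
  # the 1e-3-step tolerance lets the grid end land on a boundary the length
  # measurement undershoots by its own discretization error (< 2e-4 um here)
  s_grid <- seq(0, by = ds_um,
                length.out = floor(L_min / ds_um + 1e-3) + 1L)
  psi <- matrix(NA_real_, nrow = length(s_grid), ncol = length(splines))
  t_s <- numeric(length(splines))
  for (j in seq_along(splines)) {
    sp <- splines[[j]]
    t_s[j] <- sp$t_s
    psi[, j] <- unwrap_s(tangent_angle(sp$fx(s_grid), sp$fy(s_grid), ds_um))
  }
  fld <- new_tangent_field(psi, s_grid, t_s)
  attr(fld, "flagged_frames") <- flagged
  fld
}

# arc length by integration: chord sum over an 8x-refined spline evaluation
spline_length <- function(s_raw, x, y, refine = 8L) {
  sf <- seq(0, max(s_raw), length.out = refine * length(s_raw))
  xs <- stats::splinefun(s_raw, x, method = "fmm")(sf)
  ys <- stats::splinefun(s_raw, y, method = "fmm")(sf)
  sum(sqrt(diff(xs)^2 + diff(ys)^2))
}

# tangent angle from central differences; second-order one-sided stencils at
# the ends (a plain forward/backward difference reads the angle half a sample
# inside, biasing the whole profile once the leading angle is used as a
# reference)
tangent_angle <- function(x, y, ds) {
  n <- length(x)
  dx <- c(-3 * x[1] + 4 * x[2] - x[3],
          x[3:n] - x[1:(n - 2)],
          3 * x[n] - 4 * x[n - 1] + x[n - 2])
  dy <- c(-3 * y[1] + 4 * y[2] - y[3],
          y[3:n] - y[1:(n - 2)],
          3 * y[n] - 4 * y[n - 1] + y[n - 2])
  atan2(dy, dx)
}

# unwrap along arc length so successive samples differ by < pi
unwrap_s <- function(psi) {
  psi + cumsum(c(0, -2 * pi * round(diff(psi) / (2 * pi))))
}
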