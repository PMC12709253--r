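#' Simulate a traveling-wave tangent-angle field
#'
#' Evaluates \eqn{\psi(s_i, t_j) = C_0 s_i + a(s_i) \sin(2\pi s_i/\lambda_0 -
#' 2\pi f t_j + \phi) + \eta_{ij}} on a regular arc-length-by-time grid, with
#' \eqn{s_i} spanning `[0, L]` at spacing `ds_um` and \eqn{\eta_{ij}}
#' i.i.d. uniform on \eqn{\pm(\mathrm{noise\_level} \cdot a)}. Noise is
#' applied in angle space, mirroring how the estimator was stress-tested
#' against simulated beats with uniformly distributed angle noise.
#' Reproducible when `params$seed` is set.
#'
#' @param params A [beat_params()] object.
#' @return A `tangent_field` object: matrix `psi` (rows = arc length,
#'   columns = time) with grids `s_um` and `t_s`.
#' @examples
#' fld <- generate_tangent_field(beat_params(n_frames = 100))
#' dim(fld$psi)
#' @export
generate_tangent_field <- function(params) {
  stopifnot(inherits(params, "beat_params"))
  validate_beat_params(params)
  p <- params
  s <- seq(0, by = p$ds_um, length.out = floor(p$length_um / p$ds_um) + 1L)
  t <- (seq_len(p$n_frames) - 1L) * p$dt_s
  amp <- p$amplitude_rad * (1 - p$amplitude_taper * (1 - s / p$length_um))
  k0 <- 2 * pi / p$wavelength_um
  om <- 2 * pi * p$frequency_hz
  psi <- p$static_curvature_per_um * s +
    amp * sin(outer(k0 * s + p$phase_rad, om * t, `-`))
  if (p$noise_level > 0) {
    half <- p$noise_level * p$amplitude_rad
    draw <- function() {
      matrix(stats::runif(length(psi), -half, half), nrow = nrow(psi))
    }
    noise <- if (is.null(p$seed)) draw() else withr::with_seed(p$seed, draw())
    psi <- psi + noise
  }
  new_tangent_field(psi, s, t)
}

new_tangent_field <- function(psi, s_um, t_s, rotation_trend = NULL,
                              rotation_rate_rad_s = NULL, loess_frac = NULL) {
  stopifnot(is.matrix(psi), nrow(psi) == length(s_um),
            ncol(psi) == length(t_s))
  structure(
    list(psi = psi, s_um = s_um, t_s = t_s,
         ds_um = if (length(s_um) > 1) s_um[2] - s_um[1] else NA_real_,
         dt_s = if (length(t_s) > 1) t_s[2] - t_s[1] else NA_real_,
         rotation_trend = rotation_trend,
         rotation_rate_rad_s = rotation_rate_rad_s,
         loess_frac = loess_frac),
    class = "tangent_field"
  )
}

#' @export
print.tangent_field <- function(x, ...) {
  cat(sprintf("<tangent_field> %d arc points x %d frames (ds = %.4g um, dt = %.4g s)\n",
              nrow(x$psi), ncol(x$psi), x$ds_um, x$dt_s))
  if (!is.null(x$rotation_rate_rad_s)) {
    cat(sprintf("  rotation removed: %.4g rad/s\n", x$rotation_rate_rad_s))
  }
  invisible(x)
}

#' Simulate centerline coordinates of a beating axoneme
#'
#' Integrates the synthetic tangent field to per-frame Cartesian coordinates,
#' \eqn{x(s) = \int_0^s \cos(\psi + \Omega t)\,ds'} and
#' \eqn{y(s) = \int_0^s \sin(\psi + \Omega t)\,ds'},
#' with the leading (basal) point at the origin and the rigid-body rotation
#' \eqn{\Omega t} of the circularly swimming frame applied. This inverts the
#' tracking step that produces centerline coordinates from images. Rigid-body
#' translation is not simulated: the analysis operates on shapes after
#' rotation subtraction only.
#'
#' Integration uses circular-arc elements: between consecutive samples the
#' tangent angle is taken as linear in s, so each step advances by the exact
#' chord \eqn{ds\,\mathrm{sinc}(\Delta\psi/2)} at the mid-angle. Unlike a
#' cumulative trapezoid on \eqn{(\cos\psi, \sin\psi)}, this places the points
#' at their true arc spacing (a trapezoid shortens every segment by
#' \eqn{\approx \Delta\psi^2/8}, which downstream length-by-integration
#' then inherits).
#'
#' @param params A [beat_params()] object.
#' @return A `centerline_series` tibble with columns `frame`, `point_index`,
#'   `x_um`, `y_um`, `t_s`, points ordered base to tip within each frame.
#' @examples
#' cl <- generate_centerlines(beat_params(n_frames = 50))
#' dplyr::count(cl, frame)[1:3, ]
#' @export
generate_centerlines <- function(params) {
  stopifnot(inherits(params, "beat_params"))
  fld <- generate_tangent_field(params)
  theta <- sweep(fld$psi, 2, params$rotation_rate_rad_s * fld$t_s, `+`)
  n_s <- nrow(theta); n_t <- ncol(theta)
  ds <- fld$s_um[2] - fld$s_um[1]
  integrate_col <- function(th, trig) {
    dpsi <- diff(th)
    mid <- (th[-1] + th[-length(th)]) / 2
    chord <- ds * sinc(dpsi / 2)
    c(0, cumsum(chord * trig(mid)))
  }
  x <- apply(theta, 2, integrate_col, trig = cos)
  y <- apply(theta, 2, integrate_col, trig = sin)
  if (params$xy_jitter_um > 0) {
    draw <- function() {
      list(dx = matrix(stats::rnorm(n_s * n_t, 0, params$xy_jitter_um), n_s),
           dy = matrix(stats::rnorm(n_s * n_t, 0, params$xy_jitter_um), n_s))
    }
    seed <- if (is.null(params$seed)) NULL else params$seed + 1L
    j <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    x <- x + j$dx; y <- y + j$dy
  }
  out <- tibble(
    frame = rep(seq_len(n_t), each = n_s),
    point_index = rep(seq_len(n_s), times = n_t),
    x_um = as.vector(x),
    y_um = as.vector(y),
    t_s = rep(fld$t_s, each = n_s)
  )
  as_centerline_series(out)
}

#' Validate a centerline series
#'
#' Checks and classes a data frame of digitized centerline coordinates:
#' per-frame ordered (x, y) points in um, leading (basal) point first.
#'
#' @param x A data frame with columns `frame`, `point_index`, `x_um`, `y_um`
#'   and optionally `t_s`.
#' @return A `centerline_series` tibble.
#' @export
as_centerline_series <- function(x) {
  x <- as_tibble(x)
  need <- c("frame", "point_index", "x_um", "y_um")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(paste0("Centerline series is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "ciliawave_input_error")
  }
  if (!"t_s" %in% names(x)) x$t_s <- (x$frame - min(x$frame)) * 1e-3
  if (nrow(x) == 0) abort("Centerline series is empty.",
                          class = "ciliawave_input_error")
  if (any(!is.finite(x$x_um)) || any(!is.finite(x$y_um))) {
    abort("Centerline coordinates must be finite.",
          class = "ciliawave_input_error")
  }
  npts <- dplyr::count(x, .data$frame)$n
  if (any(npts < 2)) {
    abort("Every frame needs at least 2 centerline points.",
          class = "ciliawave_input_error")
  }
  x <- dplyr::arrange(x, .data$frame, .data$point_index)
  class(x) <- c("centerline_series", class(x))
  x
}

#' Write or read a centerline series as CSV
#'
#' The dialect is one header line and columns
#' `frame, point_index, x_um, y_um, t_s`, points ordered base to tip.
#'
#' @param x A `centerline_series` (or compatible data frame).
#' @param path File path.
#' @return `write_centerlines()` returns `path` invisibly;
#'   `read_centerlines()` returns a `centerline_series` tibble.
#' @export
write_centerlines <- function(x, path) {
  x <- as_centerline_series(x)
  readr::write_csv(as_tibble(unclass_series(x)), path)
  invisible(path)
}

#' @rdname write_centerlines
#' @export
read_centerlines <- function(path) {
  as_centerline_series(readr::read_csv(path, show_col_types = FALSE))
}

unclass_series <- function(x) {
  class(x) <- setdiff(class(x), "centerline_series")
  x[c("frame", "point_index", "x_um", "y_um", "t_s")]
}

sinc <- function(x) ifelse(abs(x) < 1e-8, 1, sin(x) / x)
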