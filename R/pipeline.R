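#' Run the full beat-analysis pipeline on one axoneme
#'
#' Composes the stages in the order the analysis requires: geometry
#' (centerline to tangent field), rotation removal, a provisional frequency
#' estimate (seeding the LOESS span and the beat segmentation), static /
#' dynamic decomposition, the Fourier-based wavelength estimate, a final
#' frequency estimate on the dynamic field, and zero-crossing wave
#' velocimetry. Stage failures are rethrown with the stage name attached.
#'
#' @param centerlines A `centerline_series` (or compatible data frame).
#' @param config A [beat_config()].
#' @param id Optional axoneme identifier recorded in the report.
#' @return An `axoneme_report` carrying every stage result plus a one-row
#'   summary (see [glance.axoneme_report()]); fields include `length_um`,
#'   `lambda_um`, `sem_um`, `frequency_hz`, `wave_velocity_um_s`,
#'   `lambda_vf_um`, `static_curvature_per_um`, `rotation_rate_rad_s`,
#'   `n_beats`, `flags`, and provenance (config hash, seed, version).
#' @examples
#' cl <- generate_centerlines(beat_params(rotation_rate_rad_s = 1))
#' rep <- analyze_axoneme(cl)
#' glance(rep)
#' @export
analyze_axoneme <- function(centerlines, config = beat_config(), id = "axoneme") {
  stopifnot(inherits(config, "beat_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] stage `%s` failed: %s", id, name,
                    conditionMessage(e)),
            class = "ciliawave_stage_error", parent = e)
    })
  }
  series <- stage("input", as_centerline_series(centerlines))
  L <- stage("geometry", axoneme_length(series))
  field <- stage("geometry",
                 centerline_to_tangent_field(series, ds_um = config$ds_um,
                                             length_dev_tol = config$length_dev_tol))
  derot <- stage("remove_rotation",
                 remove_rotation(field, loess_frac = config$loess_frac,
                                 loess_beats = config$loess_beats))
  f_prov <- stage("beat_frequency", beat_frequency(derot))
  seg <- stage("segment_beats", segment_beats(derot, f_prov))
  decomp <- stage("decompose", decompose_beat(derot, seg))
  wl <- stage("estimate_wavelength",
              estimate_wavelength(decomp, seg, s_trim = config$s_trim,
                                  k_n = config$k_n))
  f_final <- stage("beat_frequency", beat_frequency(decomp))
  wv <- stage("wave_velocity",
              wave_velocity(decomp, smooth_um = config$smooth_um))
  flags <- c(wl$flags,
             if (length(attr(field, "flagged_frames")))
               "length_deviating_frames" else character())
  structure(
    list(id = id,
         length_um = L,
         wavelength = wl,
         lambda_um = wl$lambda_um,
         sem_um = wl$sem_um,
         frequency_hz = f_final,
         provisional_frequency_hz = f_prov,
         wave_velocity_um_s = wv$wave_velocity_um_s,
         lambda_vf_um = wv$wave_velocity_um_s / f_final,
         static_curvature_per_um = decomp$static_curvature_per_um,
         rotation_rate_rad_s = decomp$rotation_rate_rad_s,
         n_beats = wl$n_beats,
         n_tracks = wv$n_tracks,
         flags = flags,
         decomposition = decomp,
         segmentation = seg,
         config = config,
         provenance = list(config_hash = rlang::hash(unclass(config)),
                           seed = config$seed,
                           version = as.character(utils::packageVersion("ciliawave")))),
    class = "axoneme_report"
  )
}

#' @export
print.axoneme_report <- function(x, ...) {
  cat(sprintf("<axoneme_report> %s\n", x$id))
  cat(sprintf("  L = %.3g um | lambda = %.4g +/- %.2g um (%d beats) | f = %.4g Hz\n",
              x$length_um, x$lambda_um, x$sem_um, x$n_beats, x$frequency_hz))
  cat(sprintf("  v = %.4g um/s | v/f = %.4g um | C0 = %.3g rad/um | Omega = %.3g rad/s\n",
              x$wave_velocity_um_s, x$lambda_vf_um,
              x$static_curvature_per_um, x$rotation_rate_rad_s))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Analyze a batch of axonemes
#'
#' Maps [analyze_axoneme()] over a list of centerline series and binds the
#' one-row summaries.
#'
#' @param series_list Named list of `centerline_series`.
#' @param config A [beat_config()].
#' @return A tibble with one row per axoneme (the [glance()] columns).
#' @export
analyze_batch <- function(series_list, config = beat_config()) {
  ids <- names(series_list) %||% as.character(seq_along(series_list))
  purrr::map2_dfr(series_list, ids,
                  function(cl, id) glance(analyze_axoneme(cl, config, id = id)))
}

#' Validate the wavelength estimator against its design claims
#'
#' Regenerates the three simulation checks that establish the estimator:
#' the systematic-error curve over window/wavelength ratios, the
#' noise-robustness comparison (a noise-free beat versus the same beat with
#' strong uniform angle noise, fixed seed), and the overlay of the analytic
#' beat-averaged spectrum on the numerically integrated one.
#'
#' @param ratios Window-length/wavelength ratios for the bias curve.
#' @param noise_level Relative uniform angle-noise amplitude for the
#'   robustness check (0.5 reproduces the +/-50% stress test).
#' @param seed Seed for the noise draw.
#' @param params Base [beat_params()] for all checks.
#' @return A `validation_report` list: `bias` (tibble), `noise` (list with
#'   the two estimates and their difference in refined-grid steps),
#'   `analytic` (list with both argmax wavenumbers), and `pass` flags.
#' @examples
#' \donttest{
#' v <- validate_estimator(ratios = c(1, 1.5))
#' v$pass
#' }
#' @export
validate_estimator <- function(ratios = c(0.5, 0.75, 1, 1.25, 1.5, 2, 2.5),
                               noise_level = 0.5, seed = 1,
                               params = beat_params()) {
  bias <- bias_curve(ratios, wavelength_um = params$wavelength_um,
                     params = params)

  p0 <- params
  p0$length_um <- p0$wavelength_um
  p0$static_curvature_per_um <- 0; p0$rotation_rate_rad_s <- 0
  p0$noise_level <- 0
  fld0 <- generate_tangent_field(p0)
  seg <- segment_beats(fld0, p0$frequency_hz)
  est0 <- estimate_wavelength(decompose_beat(fld0, seg), seg)
  pn <- p0; pn$noise_level <- noise_level; pn$seed <- seed
  fldn <- generate_tangent_field(pn)
  estn <- estimate_wavelength(decompose_beat(fldn, seg), seg)
  k_step <- est0$k_step_per_um
  dk_noise <- abs(estn$k0_per_um - est0$k0_per_um)

  L <- max(fld0$s_um)
  kg <- wavenumber_grid(L)
  g_ana <- analytic_g(kg, 2 * pi / p0$wavelength_um, L, p0$amplitude_rad)
  sp <- power_spectrum(decompose_beat(fld0, seg)$psi_dynamic$psi,
                       fld0$s_um, kg, average = TRUE)
  k_ana <- kg[which.max(g_ana)]
  k_num <- kg[which.max(sp$G)]

  structure(
    list(bias = bias,
         noise = list(lambda_clean_um = est0$lambda_um,
                      lambda_noisy_um = estn$lambda_um,
                      shift_grid_steps = dk_noise / k_step,
                      noise_level = noise_level, seed = seed),
         analytic = list(k_analytic = k_ana, k_numeric = k_num,
                         step = kg[2] - kg[1]),
         pass = c(
           bias_below_1pct = all(abs(bias$rel_error[bias$ratio >= 1]) < 0.01),
           noise_shift_below_one_step = dk_noise < k_step,
           analytic_peak_matches = abs(k_ana - k_num) <= (kg[2] - kg[1])
         )),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  max |bias| for ratio >= 1: %.3g%%\n",
              100 * max(abs(x$bias$rel_error[x$bias$ratio >= 1]))))
  cat(sprintf("  noise shift: %.3g refined grid steps (noise %.0f%%)\n",
              x$noise$shift_grid_steps, 100 * x$noise$noise_level))
  cat(sprintf("  analytic vs numeric peak: |dk| = %.3g (grid step %.3g)\n",
              abs(x$analytic$k_analytic - x$analytic$k_numeric),
              x$analytic$step))
  cat("  pass:", paste(names(x$pass)[x$pass], collapse = ", "), "\n")
  if (any(!x$pass)) {
    cat("  FAIL:", paste(names(x$pass)[!x$pass], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export a tangent field as CSV plus a JSON grid sidecar
#'
#' Writes the matrix \eqn{\psi(s,t)} (rows = arc length, columns = time) as
#' CSV and the grid metadata as a JSON sidecar next to it.
#'
#' @param field A `tangent_field`.
#' @param path CSV path; the sidecar replaces the extension with `.json`.
#' @return `path`, invisibly.
#' @export
write_tangent_field <- function(field, path) {
  stopifnot(inherits(field, "tangent_field"))
  utils::write.table(field$psi, path, sep = ",", row.names = FALSE,
                     col.names = paste0("t", seq_along(field$t_s)))
  meta <- list(s_um = field$s_um, t_s = field$t_s,
               ds_um = field$ds_um, dt_s = field$dt_s)
  jsonlite::write_json(meta, sub("\\.[^.]*$", ".json", path),
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a tangent field written by [write_tangent_field()]
#'
#' @param path CSV path (expects the `.json` sidecar next to it).
#' @return A `tangent_field`.
#' @export
read_tangent_field <- function(path) {
  psi <- as.matrix(utils::read.table(path, sep = ",", header = TRUE))
  meta <- jsonlite::read_json(sub("\\.[^.]*$", ".json", path),
                              simplifyVector = TRUE)
  dimnames(psi) <- NULL
  new_tangent_field(psi, meta$s_um, meta$t_s)
}

#' Write an analysis report as JSON
#'
#' Serializes the scalar summary, the per-beat wavelengths and the
#' provenance block of an `axoneme_report`.
#'
#' @param report An `axoneme_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "axoneme_report"))
  out <- list(
    id = report$id,
    length_um = report$length_um,
    lambda_um = report$lambda_um,
    sem_um = report$sem_um,
    per_beat_lambda_um = report$wavelength$per_beat_lambda_um,
    frequency_hz = report$frequency_hz,
    wave_velocity_um_s = report$wave_velocity_um_s,
    lambda_vf_um = report$lambda_vf_um,
    static_curvature_per_um = report$static_curvature_per_um,
    rotation_rate_rad_s = report$rotation_rate_rad_s,
    n_beats = report$n_beats,
    n_tracks = report$n_tracks,
    flags = report$flags,
    provenance = report$provenance
  )
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
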