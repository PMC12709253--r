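#' Crossing-count test for comparing two wavelength-length datasets
#'
#' Nonparametric test of whether wavelength-versus-length data from two
#' preparations follow the same underlying curve. A reference curve is built
#' from `dataset_b` by linear interpolation of wavelength over length;
#' the points of `dataset_a` falling inside `dataset_b`'s length range are
#' ordered by length and their residual signs against the reference curve
#' are computed. The statistic counts the number of sign changes n between
#' consecutive points. If the two preparations sample the same curve, the
#' residual signs are exchangeable coin flips, so n is expected to be N/2
#' with standard error \eqn{\sqrt{N}/2}, where N is the number of points
#' used. The test statistic \eqn{t = |n - N/2| / (\sqrt{N}/2)} is referred
#' to a t distribution with N/2 degrees of freedom (rounded down for odd N);
#' p-values are two-sided. Too few crossings mean one dataset sits
#' systematically on one side of the other; too many mean over-alternation.
#'
#' A residual exactly zero is assigned the previous point's sign (leading
#' zeros take the first following non-zero sign) and the result is flagged.
#'
#' @param dataset_a,dataset_b Data frames with columns `length_um` and
#'   `lambda_um` (one row per axoneme); extra columns are ignored.
#' @param m Number of comparisons in the family, for the Bonferroni-adjusted
#'   p-value.
#' @param alpha Significance level used by the `significant` field (applied
#'   to the adjusted p-value).
#' @return A `crossing_test` object with `n_crossings`, `N`, `se`,
#'   `t_stat`, `df`, `p_value`, `p_adjusted`, `significant`, `flags`.
#' @examples
#' a <- tibble::tibble(length_um = 8:17, lambda_um = 8:17 + 2)
#' b <- tibble::tibble(length_um = 8:17, lambda_um = 8:17)
#' crossing_test(a, b)$p_value
#' @export
crossing_test <- function(dataset_a, dataset_b, m = 1, alpha = 0.05) {
  a <- as_tibble(dataset_a); b <- as_tibble(dataset_b)
  for (d in list(a, b)) {
    if (!all(c("length_um", "lambda_um") %in% names(d))) {
      abort("Datasets need columns `length_um` and `lambda_um`.",
            class = "ciliawave_input_error")
    }
  }
  if (nrow(a) < 3 || nrow(b) < 3) {
    abort("Each dataset needs at least 3 points.",
          class = "ciliawave_input_error")
  }
  b <- dplyr::arrange(b, .data$length_um)
  ref <- stats::approxfun(b$length_um, b$lambda_um, ties = mean, rule = 1)
  a <- dplyr::arrange(a, .data$length_um)
  a <- dplyr::filter(a, .data$length_um >= min(b$length_um),
                        .data$length_um <= max(b$length_um))
  N <- nrow(a)
  if (N < 3) {
    abort("Fewer than 3 usable points after restricting to the overlapping length range.",
          class = "ciliawave_input_error")
  }
  resid <- a$lambda_um - ref(a$length_um)
  sg <- sign(resid)
  flags <- character()
  if (any(sg == 0)) {
    flags <- "zero_residual"
    for (i in seq_along(sg)) {
      if (sg[i] == 0 && i > 1) sg[i] <- sg[i - 1]
    }
    for (i in rev(seq_along(sg))) {  # leading zeros take the next sign
      if (sg[i] == 0 && i < length(sg)) sg[i] <- sg[i + 1]
    }
  }
  n <- sum(sg[-1] != sg[-N])
  se <- sqrt(N) / 2
  t_stat <- abs(n - N / 2) / se
  df <- floor(N / 2)
  p <- 2 * pt(-t_stat, df = df)
  p_adj <- bonferroni(p, m)
  structure(
    list(n_crossings = n, N = N, se = se, t_stat = t_stat, df = df,
         p_value = p, p_adjusted = p_adj, m = m,
         significant = p_adj < alpha, flags = flags),
    class = "crossing_test"
  )
}

#' @export
print.crossing_test <- function(x, ...) {
  cat("<crossing_test>\n")
  cat(sprintf("  n = %d crossings of N = %d points (expected %.1f)\n",
              x$n_crossings, x$N, x$N / 2))
  cat(sprintf("  t = %.3f on %d df, p = %.4g (Bonferroni-adjusted %.4g, m = %d)\n",
              x$t_stat, x$df, x$p_value, x$p_adjusted, x$m))
  invisible(x)
}

#' Bonferroni correction
#'
#' Adjusts p-values for a family of `m` comparisons: each p is mapped to
#' `min(1, m * p)` (via [stats::p.adjust()]).
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param m Family size; at least `length(p_values)`.
#' @return Adjusted p-values.
#' @examples
#' bonferroni(c(0.01, 0.5), m = 5)
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].", class = "ciliawave_parameter_error")
  }
  if (m < length(p_values)) {
    abort("`m` must be at least the number of p-values.",
          class = "ciliawave_parameter_error")
  }
  stats::p.adjust(p_values, method = "bonferroni", n = m)
}

#' Regression slope with a two-standard-error significance rule
#'
#' Ordinary least squares of y on x. The correlation is deemed not
#' significant when the slope is less than two standard errors from zero
#' (the 95% confidence-interval rule).
#'
#' @param points Data frame with columns `x` and `y` (or two numeric
#'   vectors via `x`, `y`).
#' @param x,y Optional numeric vectors, used when `points` is missing.
#' @return A `slope_significance` object with `slope`, `intercept`,
#'   `slope_se`, `significant`.
#' @examples
#' slope_significance(data.frame(x = 1:5, y = 2 * (1:5) + 1))$slope
#' @export
slope_significance <- function(points = NULL, x = NULL, y = NULL) {
  if (!is.null(points)) {
    if (!all(c("x", "y") %in% names(points))) {
      abort("`points` needs columns `x` and `y`.",
            class = "ciliawave_input_error")
    }
    x <- points$x; y <- points$y
  }
  if (length(x) < 3) abort("Need at least 3 points.",
                           class = "ciliawave_input_error")
  if (length(unique(x)) < 2) {
    abort("Degenerate predictor: all x equal.",
          class = "ciliawave_input_error")
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)$coefficients
  slope <- unname(sm["x", "Estimate"])
  se <- unname(sm["x", "Std. Error"])
  if (!is.finite(se)) se <- 0  # exact fit: zero residual variance
  structure(
    list(slope = slope, intercept = unname(sm["(Intercept)", "Estimate"]),
         slope_se = se, significant = abs(slope) >= 2 * se,
         n = length(x)),
    class = "slope_significance"
  )
}

#' @export
print.slope_significance <- function(x, ...) {
  cat(sprintf("<slope_significance> m = %.4g +/- %.4g (%ssignificant at 2 SE)\n",
              x$slope, x$slope_se, if (x$significant) "" else "not "))
  invisible(x)
}
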