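#' Fit a value curve to one limb of the (H, K) preference graph
#'
#' Fits `|K|` as a function of H over the points of a single limb
#' (approach: K > 0; avoidance: K < 0). Supported forms:
#'
#' * `power`: `|K| = a * H^b`, least squares via Levenberg-Marquardt,
#'   initialized from a log-log regression; needs at least 3 points and an
#'   H spread of at least `min_h_spread` bits, otherwise it falls back to
#'   the linear form (recorded in `form`).
#' * `linear`: `|K| = a * H` through the origin (closed form; a single
#'   point determines it exactly).
#' * `quadratic`: `|K| = a * H + b * H^2`.
#'
#' Fitted values for the avoidance limb carry sign -1. All H identical is
#' an unfittable limb and errors (except the single-point linear case).
#'
#' @param points Data frame with columns `H` (bits) and `K` (signed mean
#'   keypresses) for one limb.
#' @param form `"power"` (default), `"linear"` or `"quadratic"`.
#' @param limb `"approach"` or `"avoidance"`; inferred from the sign of K
#'   when omitted.
#' @param min_h_spread Minimum H range (bits) for the two-parameter forms
#'   (default 0.1).
#' @param fallback Fall back to the linear form when the requested form is
#'   under-determined (default TRUE); with `fallback = FALSE` such input
#'   errors instead.
#' @return A `value_curve_fit` object: list with `limb`, `form`,
#'   `form_requested`, `params` (a, b), `h_range`, `rms_residual`,
#'   `n_points` and the fitted points. Use [predict()] for signed fitted
#'   K, [tidy()]/[glance()] for tibble summaries.
#' @examples
#' pts <- tibble::tibble(H = c(1, 2, 3), K = c(2, 4, 6))
#' fit_value_curve(pts, form = "linear")$params[["a"]] # 2
#' @export
fit_value_curve <- function(points, form = c("power", "linear", "quadratic"),
                            limb = NULL, min_h_spread = 0.1, fallback = TRUE) {
  form <- match.arg(form)
  points <- tibble::as_tibble(points)[, c("H", "K")]
  points <- points[stats::complete.cases(points), ]
  n <- nrow(points)
  if (n < 1) abort("unfittable limb: no points", class = "lapref_error_unfittable")
  ks <- sign(points$K[points$K != 0])
  if (length(unique(ks)) > 1) abort("points mix limbs: K changes sign")
  if (is.null(limb)) {
    limb <- if (length(ks) && ks[1] < 0) "avoidance" else "approach"
  }
  limb <- match.arg(limb, c("approach", "avoidance"))
  if (any(points$H < 0)) abort("H must be non-negative")

  h <- points$H
  y <- abs(points$K)
  h_spread <- diff(range(h))
  form_requested <- form

  under_determined <- switch(form,
    linear = FALSE,
    quadratic = n < 2 || h_spread <= 0,
    power = n < 3 || h_spread < min_h_spread
  )
  if (under_determined) {
    if (!fallback) {
      abort(sprintf("unfittable limb: %s form under-determined (n = %d, H spread = %.3g)",
                    form, n, h_spread),
            class = "lapref_error_unfittable")
    }
    form <- "linear"
  }
  if (form == "linear" && n > 1 && h_spread <= 0 && stats::var(y) > 0) {
    abort("unfittable limb: all H identical", class = "lapref_error_unfittable")
  }

  params <- switch(form,
    linear = c(a = sum(h * y) / sum(h^2), b = 1),
    quadratic = {
      cf <- coef(lm(y ~ 0 + h + I(h^2)))
      c(a = unname(cf[1]), b = unname(cf[2]))
    },
    power = fit_power_law(h, y)
  )
  fitted <- eval_abs_curve(form, params, h)
  fit <- structure(
    list(
      limb = limb,
      form = form,
      form_requested = form_requested,
      params = params,
      h_range = range(h),
      rms_residual = sqrt(mean((y - fitted)^2)),
      n_points = n,
      points = points
    ),
    class = "value_curve_fit"
  )
  fit
}

# Power-law least squares with log-log initialization; `a` bounded >= 0 so
# avoidance-limb fitted values keep their sign after mirroring.
fit_power_law <- function(h, y) {
  pos <- h > 0 & y > 0
  if (sum(pos) >= 2) {
    cf <- coef(lm(log(y[pos]) ~ log(h[pos])))
    start <- list(a = exp(unname(cf[1])), b = unname(cf[2]))
  } else {
    start <- list(a = max(y, 1e-3), b = 1)
  }
  fit <- try(minpack.lm::nlsLM(
    y ~ a * h^b, start = start,
    lower = c(a = 0, b = -Inf), upper = c(a = Inf, b = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    abort("unfittable limb: power-law fit failed to converge",
          class = "lapref_error_unfittable")
  }
  cf <- coef(fit)
  c(a = unname(cf["a"]), b = unname(cf["b"]))
}

eval_abs_curve <- function(form, params, h) {
  a <- params[["a"]]; b <- params[["b"]]
  switch(form,
    linear = a * h,
    quadratic = a * h + b * h^2,
    power = a * h^b
  )
}

#' Predict signed K from a fitted value curve
#'
#' @param object A `value_curve_fit`.
#' @param h Numeric vector of entropies (bits); defaults to the fitted
#'   points' H.
#' @param ... Unused.
#' @return Signed fitted K (negative for the avoidance limb).
#' @export
predict.value_curve_fit <- function(object, h = NULL, ...) {
  h <- h %||% object$points$H
  s <- if (object$limb == "avoidance") -1 else 1
  s * eval_abs_curve(object$form, object$params, h)
}

#' @export
print.value_curve_fit <- function(x, ...) {
  cat(sprintf(
    "<value_curve_fit> %s limb, form = %s%s\n  |K| = %.4g * H^%.4g%s\n  n = %d, H in [%.3g, %.3g] bits, rms residual = %.4g\n",
    x$limb, x$form,
    if (x$form != x$form_requested) paste0(" (fallback from ", x$form_requested, ")") else "",
    x$params[["a"]],
    if (x$form == "linear") 1 else x$params[["b"]],
    if (x$form == "quadratic") sprintf(" [quadratic: a*H + b*H^2, b = %.4g]", x$params[["b"]]) else "",
    x$n_points, x$h_range[1], x$h_range[2], x$rms_residual
  ))
  invisible(x)
}

#' Local slope of a fitted value curve near the origin
#'
#' The loss-aversion statistic uses the mean slope of each limb's value
#' curve over the fraction of the H range closest to the inflection point
#' or origin — the limb endpoint where |K| is smallest (the limbs meet near
#' K = 0). The mean slope over a window of width `w` is
#' `(f(h0 + w) - f(h0)) / w`, the integral of the derivative divided by the
#' window width. The returned slope is signed by limb: positive for
#' approach, negative for avoidance.
#'
#' @param fit A `value_curve_fit`.
#' @param fraction Fraction of the H range forming the window (default
#'   0.10); must be in (0, 1].
#' @return Local slope in K per bit.
#' @examples
#' fit <- fit_value_curve(tibble::tibble(H = 1:3, K = 2 * (1:3)), form = "linear")
#' local_slope(fit) # 2
#' @export
local_slope <- function(fit, fraction = 0.10) {
  stopifnot(inherits(fit, "value_curve_fit"))
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  width <- diff(fit$h_range)
  if (width <= 0) {
    # single-point linear limb: the through-origin slope is exact
    if (fit$form == "linear") {
      return((if (fit$limb == "avoidance") -1 else 1) * fit$params[["a"]])
    }
    abort("zero-width H range", class = "lapref_error_unfittable")
  }
  w <- fraction * width
  f <- function(h) eval_abs_curve(fit$form, fit$params, h)
  lo <- fit$h_range[1]; hi <- fit$h_range[2]
  # window anchored at the endpoint of smallest |K|, extending inward
  mean_abs_slope <- if (f(lo) <= f(hi)) {
    (f(lo + w) - f(lo)) / w
  } else {
    (f(hi) - f(hi - w)) / w
  }
  (if (fit$limb == "avoidance") -1 else 1) * abs(mean_abs_slope)
}

#' Loss aversion from a pair of fitted limbs
#'
#' Computes the local loss-aversion ratio lambda = |s- / s+| where s- and
#' s+ are the local slopes ([local_slope()]) of the avoidance and approach
#' value curves over the window fraction nearest the origin. A zero
#' approach slope yields `lambda = Inf` with a warning; such subjects are
#' excluded from group statistics by the outlier rule (non-finite values
#' are always flagged).
#'
#' @param fit_minus `value_curve_fit` for the avoidance limb.
#' @param fit_plus `value_curve_fit` for the approach limb.
#' @param fraction Window fraction (default 0.10).
#' @return A one-row tibble: `s_minus`, `s_plus`, `lambda`,
#'   `window_fraction`, `form_minus`, `form_plus`.
#' @examples
#' neg <- fit_value_curve(tibble::tibble(H = 1:3, K = -4.5 * (1:3)), form = "linear")
#' pos <- fit_value_curve(tibble::tibble(H = 1:3, K = 2 * (1:3)), form = "linear")
#' loss_aversion(neg, pos)$lambda # 2.25
#' @export
loss_aversion <- function(fit_minus, fit_plus, fraction = 0.10) {
  if (fit_minus$limb != "avoidance" || fit_plus$limb != "approach") {
    abort("loss_aversion() needs an avoidance fit and an approach fit, in that order")
  }
  s_minus <- local_slope(fit_minus, fraction)
  s_plus <- local_slope(fit_plus, fraction)
  lam <- if (s_plus == 0) {
    warn("zero approach slope: lambda is infinite and will be flagged as an outlier")
    Inf
  } else {
    abs(s_minus / s_plus)
  }
  tibble::tibble(
    s_minus = s_minus, s_plus = s_plus, lambda = lam,
    window_fraction = fraction,
    form_minus = fit_minus$form, form_plus = fit_plus$form
  )
}

#' Estimate loss aversion for every subject in a valuation table
#'
#' Splits each subject's category-level (H, K) points by limb (rows with
#' `limb = "neutral"` never enter curve fitting), fits a value curve per
#' limb and computes lambda = |s-/s+|. With the seven-condition face set
#' the approach limb is typically the single happy category, which the
#' one-parameter through-origin linear form fits exactly; the power form
#' is used whenever a limb has enough H spread to support it.
#'
#' @param valuation Output of [category_valuation()] (any number of
#'   subjects).
#' @param form Requested curve form, passed to [fit_value_curve()].
#' @param fraction Local-slope window fraction (default 0.10).
#' @param min_h_spread Passed to [fit_value_curve()].
#' @return A tibble with one row per subject: `subject_id`, `s_minus`,
#'   `s_plus`, `lambda`, `window_fraction`, `form_minus`, `form_plus`,
#'   `n_minus`, `n_plus`. Subjects missing a limb get `NA` with a warning.
#' @export
estimate_loss_aversion <- function(valuation, form = "power", fraction = 0.10,
                                   min_h_spread = 0.1) {
  if ("valence_class" %in% names(valuation)) {
    # neutral and baseline categories never enter curve fitting
    valuation <- valuation[is.na(valuation$valence_class) |
                             valuation$valence_class %in% c("negative", "positive"), ]
  }
  valuation |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(df, key) {
      neg <- df[df$limb == "avoidance", c("H", "K")]
      pos <- df[df$limb == "approach", c("H", "K")]
      if (nrow(neg) < 1 || nrow(pos) < 1) {
        warn(sprintf("subject %s lacks an %s limb; lambda set to NA",
                     key$subject_id,
                     if (nrow(neg) < 1) "avoidance" else "approach"))
        return(tibble::tibble(
          s_minus = NA_real_, s_plus = NA_real_, lambda = NA_real_,
          window_fraction = fraction, form_minus = NA_character_,
          form_plus = NA_character_, n_minus = nrow(neg), n_plus = nrow(pos)
        ))
      }
      fm <- fit_value_curve(neg, form = form, limb = "avoidance",
                            min_h_spread = min_h_spread)
      fp <- fit_value_curve(pos, form = form, limb = "approach",
                            min_h_spread = min_h_spread)
      dplyr::mutate(loss_aversion(fm, fp, fraction),
                    n_minus = nrow(neg), n_plus = nrow(pos))
    }) |>
    dplyr::ungroup()
}

#' Flag cohort outliers by the 2-standard-deviation rule
#'
#' A value is an outlier when it lies more than `k` sample standard
#' deviations (n - 1 denominator) from the cohort mean, mean and SD taken
#' over all values. Non-finite values are always flagged. A zero-SD cohort
#' (all values equal) flags nothing.
#'
#' @param values Numeric vector (cohort of lambda or NDS values).
#' @param k Number of standard deviations (default 2).
#' @return Logical vector of flags.
#' @examples
#' flag_outliers(c(rep(2, 9), 12)) # only the 12 is flagged
#' @export
flag_outliers <- function(values, k = 2.0) {
  finite <- is.finite(values)
  if (sum(finite) < 3) abort("need at least 3 finite values to flag outliers")
  m <- mean(values[finite])
  s <- sd(values[finite])
  flags <- !finite
  if (s > 0) flags[finite] <- abs(values[finite] - m) > k * s
  flags
}
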