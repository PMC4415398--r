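#' Tidy a fitted value curve
#'
#' @param x A `value_curve_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, plus `limb` and
#'   `form`.
#' @export
tidy.value_curve_fit <- function(x, ...) {
  terms <- switch(x$form,
    linear = "a",
    c("a", "b")
  )
  tibble::tibble(
    term = terms,
    estimate = unname(x$params[terms]),
    limb = x$limb,
    form = x$form
  )
}

#' One-row summary of a fitted value curve
#'
#' @param x A `value_curve_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `limb`, `form`, `form_requested`,
#'   `n_points`, `h_min`, `h_max`, `rms_residual`.
#' @export
glance.value_curve_fit <- function(x, ...) {
  tibble::tibble(
    limb = x$limb, form = x$form, form_requested = x$form_requested,
    n_points = x$n_points, h_min = x$h_range[1], h_max = x$h_range[2],
    rms_residual = x$rms_residual
  )
}

#' Per-subject table of a pipeline run
#'
#' @param x A `lapref_run`.
#' @param ... Unused.
#' @return The cohort tibble (one row per subject with lambda, NDS, age
#'   and exclusion flags).
#' @export
tidy.lapref_run <- function(x, ...) tibble::as_tibble(x$cohort)

#' Association summary of a pipeline run
#'
#' @param x A `lapref_run`.
#' @param ... Unused.
#' @return The three-row association tibble (NDS~LA, NDS~age, LA~age).
#' @export
glance.lapref_run <- function(x, ...) x$associations
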