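#' Plot the (H, K) relative-preference graph
#'
#' Category-level value points for one or more subjects: mean keypress K
#' against choice entropy H, approach limb above zero, avoidance limb
#' below.
#'
#' @param valuation Output of [category_valuation()].
#' @param fits Optional named list of `value_curve_fit` objects to
#'   overlay (evaluated over their fitted H range).
#' @return A ggplot object.
#' @export
plot_value_graph <- function(valuation, fits = NULL) {
  p <- ggplot2::ggplot(valuation, ggplot2::aes(x = .data$H, y = .data$K)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$limb, shape = .data$category),
                        size = 2.5) +
    ggplot2::scale_colour_manual(values = c(
      approach = "#2e7d32", avoidance = "#c62828", neutral = "grey50"
    )) +
    ggplot2::labs(x = "H (bits)", y = "K (mean keypresses)",
                  colour = "limb", shape = "category") +
    ggplot2::theme_minimal()
  if (length(unique(valuation$subject_id)) > 1) {
    p <- p + ggplot2::facet_wrap(~subject_id)
  }
  if (!is.null(fits)) {
    curves <- purrr::imap_dfr(fits, function(f, nm) {
      h <- seq(f$h_range[1], f$h_range[2], length.out = 100)
      tibble::tibble(H = h, K = predict(f, h), limb = f$limb, fit = nm)
    })
    p <- p + ggplot2::geom_line(
      data = curves,
      ggplot2::aes(x = .data$H, y = .data$K, colour = .data$limb,
                   group = .data$fit),
      inherit.aes = FALSE
    )
  }
  p
}

#' Scatter plot of one cohort association
#'
#' @param cohort A `cohort_table`.
#' @param x,y Column names to plot (e.g. `"lambda"` vs `"nds"`, or
#'   `"age"` vs `"nds"`).
#' @param drop_outliers Drop flagged outliers and invalid-imaging
#'   subjects before plotting (default TRUE).
#' @return A ggplot object with the least-squares line.
#' @export
plot_association <- function(cohort, x, y, drop_outliers = TRUE) {
  df <- tibble::as_tibble(cohort)
  if (drop_outliers) {
    keep <- rep(TRUE, nrow(df))
    if ("lambda" %in% c(x, y)) keep <- keep & !df$la_outlier
    if ("nds" %in% c(x, y)) keep <- keep & df$valid_imaging & !df$nds_outlier
    df <- df[keep, ]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    ggplot2::geom_point(size = 2.5, colour = "#1565c0") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.5) +
    ggplot2::theme_minimal()
}

#' Panel plot of a pipeline run
#'
#' The three study scatter plots — NDS against lambda, NDS against age,
#' lambda against age — on the subjects each association uses.
#'
#' @param object A `lapref_run`.
#' @param ... Unused.
#' @return A ggplot object (three facets).
#' @export
autoplot.lapref_run <- function(object, ...) {
  ct <- tibble::as_tibble(object$cohort)
  usable <- function(need_nds, need_la) {
    keep <- rep(TRUE, nrow(ct))
    if (need_nds) keep <- keep & ct$valid_imaging & !ct$nds_outlier
    if (need_la) keep <- keep & !ct$la_outlier & is.finite(ct$lambda)
    ct[keep, ]
  }
  panels <- dplyr::bind_rows(
    dplyr::transmute(usable(TRUE, TRUE), x = .data$lambda, y = .data$nds,
                     panel = "NDS ~ LA"),
    dplyr::transmute(usable(TRUE, FALSE), x = .data$age, y = .data$nds,
                     panel = "NDS ~ age"),
    dplyr::transmute(usable(FALSE, TRUE), x = .data$age, y = .data$lambda,
                     panel = "LA ~ age")
  )
  ggplot2::ggplot(panels, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 2, colour = "#1565c0") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.5) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
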