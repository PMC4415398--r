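#' Assemble the per-subject cohort table
#'
#' Joins ages, loss-aversion estimates and NDS results into one row per
#' subject and applies the cohort-level 2-SD outlier rule to lambda and,
#' over valid-imaging subjects, to NDS. Non-finite lambdas (including
#' subjects with an unfittable limb) are always flagged.
#'
#' @param ages Tibble with `subject_id`, `age`.
#' @param la Tibble from [estimate_loss_aversion()] (needs `subject_id`,
#'   `lambda`).
#' @param nds Tibble with `subject_id`, `nds`, `valid` (one row per
#'   subject; subjects absent from `nds` are treated as invalid imaging).
#' @param k Outlier threshold in standard deviations (default 2).
#' @return A `cohort_table` tibble: `subject_id`, `age`, `lambda`, `nds`,
#'   `la_outlier`, `nds_outlier`, `valid_imaging`.
#' @export
assemble_cohort <- function(ages, la, nds, k = 2.0) {
  out <- ages |>
    dplyr::left_join(dplyr::select(la, "subject_id", "lambda"), by = "subject_id") |>
    dplyr::left_join(dplyr::select(nds, "subject_id", "nds", "valid"),
                     by = "subject_id") |>
    dplyr::mutate(
      valid_imaging = dplyr::coalesce(.data$valid, FALSE),
      valid = NULL,
      la_outlier = flag_outliers(.data$lambda, k = k)
    )
  out$nds_outlier <- FALSE
  vi <- out$valid_imaging
  if (sum(vi) >= 3) out$nds_outlier[vi] <- flag_outliers(out$nds[vi], k = k)
  class(out) <- c("cohort_table", class(out))
  out
}

association_row <- function(name, estimate, statistic, p, n_used, alpha) {
  tibble::tibble(
    name = name, estimate = estimate, test_statistic = statistic,
    p = p, n_used = n_used, alpha = alpha, significant = p < alpha
  )
}

#' Correlate NDS with loss aversion across subjects
#'
#' Pearson correlation between per-subject NDS and lambda over the
#' subjects who are neither lambda nor NDS outliers and have valid
#' imaging. As an isolated test it is assessed at `alpha = 0.05`,
#' two-sided.
#'
#' @param cohort A `cohort_table` from [assemble_cohort()].
#' @param alpha Significance threshold (default 0.05).
#' @return A one-row association tibble (`name = "nds_la"`, `estimate` =
#'   Pearson r, `test_statistic` = its t, `p`, `n_used`, `alpha`,
#'   `significant`), with an `excluded` attribute listing excluded
#'   subjects and reasons.
#' @export
correlate_nds_la <- function(cohort, alpha = 0.05) {
  reasons <- dplyr::transmute(
    cohort, subject_id = .data$subject_id,
    reason = dplyr::case_when(
      !.data$valid_imaging ~ "invalid imaging",
      .data$la_outlier ~ "lambda outlier",
      .data$nds_outlier ~ "NDS outlier",
      TRUE ~ NA_character_
    )
  )
  keep <- cohort[is.na(reasons$reason), ]
  if (nrow(keep) < 3) abort("fewer than 3 usable subjects for NDS~LA correlation")
  if (sd(keep$lambda) == 0 || sd(keep$nds) == 0) {
    abort("degenerate input: constant lambda or NDS", class = "lapref_error_degenerate")
  }
  ct <- cor.test(keep$nds, keep$lambda, method = "pearson",
                 alternative = "two.sided")
  out <- association_row("nds_la", unname(ct$estimate), unname(ct$statistic),
                         ct$p.value, nrow(keep), alpha)
  attr(out, "excluded") <- reasons[!is.na(reasons$reason), ]
  out
}

#' Regress NDS or loss aversion on age
#'
#' Simple linear regression of the chosen measure on age. For
#' `measure = "lam"`, lambda outliers are excluded; for
#' `measure = "nds"`, subjects without valid imaging are excluded (NDS
#' outliers stay in, matching the use of the full valid-imaging set for
#' the age regression). Because two tests are run against age, the
#' default threshold carries a Bonferroni correction: `alpha = 0.05 / 2`.
#'
#' @param cohort A `cohort_table`.
#' @param measure `"nds"` or `"lam"`.
#' @param alpha Significance threshold (default 0.025).
#' @param exclude_nds_outliers Also drop NDS outliers from the NDS~age
#'   regression (default FALSE).
#' @return A one-row association tibble (`estimate` = slope per year,
#'   `test_statistic` = regression F, two-sided `p`), with an `excluded`
#'   attribute.
#' @export
regress_on_age <- function(cohort, measure = c("nds", "lam"), alpha = 0.025,
                           exclude_nds_outliers = FALSE) {
  measure <- match.arg(measure)
  reasons <- dplyr::transmute(
    cohort, subject_id = .data$subject_id,
    reason = if (measure == "lam") {
      dplyr::if_else(.data$la_outlier, "lambda outlier", NA_character_)
    } else {
      dplyr::case_when(
        !.data$valid_imaging ~ "invalid imaging",
        exclude_nds_outliers & .data$nds_outlier ~ "NDS outlier",
        TRUE ~ NA_character_
      )
    }
  )
  keep <- cohort[is.na(reasons$reason), ]
  if (nrow(keep) < 3) abort("fewer than 3 usable subjects for age regression")
  if (sd(keep$age) == 0) abort("degenerate input: constant age",
                               class = "lapref_error_degenerate")
  y <- if (measure == "nds") keep$nds else keep$lambda
  fit <- lm(y ~ age, data = tibble::tibble(y = y, age = keep$age))
  sm <- summary(fit)
  fstat <- unname(sm$fstatistic)
  p <- pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  out <- association_row(if (measure == "nds") "nds_age" else "la_age",
                         unname(coef(fit)["age"]),
                         fstat[1], p, nrow(keep), alpha)
  attr(out, "excluded") <- reasons[!is.na(reasons$reason), ]
  out
}
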