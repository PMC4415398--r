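run_stage <- function(stage, expr) {
  withCallingHandlers(
    expr,
    error = function(e) {
      abort(paste0("pipeline stage '", stage, "' failed"),
            class = "lapref_error_stage", parent = e)
    }
  )
}

#' Run the full loss-aversion / NDS / age pipeline
#'
#' Orchestrates every stage on a simulated (or pre-simulated) cohort:
#' keypress reduction to (K, H) valuations, value-curve fits and lambda
#' estimation, per-subject GLM + contrast + ROI NDS extraction, cohort
#' assembly with outlier flags, and the three associations — NDS~LA
#' (Pearson, alpha 0.05), NDS~age and LA~age (regression, Bonferroni
#' alpha 0.05/2). Rerunning with the same spec reproduces every output
#' byte for byte.
#'
#' @param x A [cohort_spec()] (simulated here) or an existing
#'   `lapref_cohort` from [simulate_cohort()].
#' @param measure Valuation measure, `"keypresses"` or `"viewtime"`.
#' @param form Value-curve form (default `"power"`, with the documented
#'   linear fallback).
#' @param fraction Local-slope window fraction (default 0.10).
#' @param dead_band Neutral-limb dead band on |K| (default 0.05).
#' @param roi ROI hemisphere for NDS (default `"left"`).
#' @param z_threshold Supra-threshold cut for ROI sampling (default
#'   1.96).
#' @param alpha_isolated Alpha for the isolated NDS~LA correlation
#'   (default 0.05).
#' @param alpha_age Bonferroni-corrected alpha for the two age tests
#'   (default 0.025).
#' @param outdir Optional directory: writes `cohort.csv`,
#'   `associations.csv`, `valuation.csv`, `la.csv`, `exclusions.csv` and
#'   a `run_log.json` with the seed, parameters and package version.
#' @return A `lapref_run` object: list with `cohort` (the per-subject
#'   table), `valuation`, `la`, `nds`, `associations`, `exclusions` and
#'   `params`. See [tidy()], [glance()], [autoplot()].
#' @examples
#' \donttest{
#' run <- la_pipeline(cohort_spec(n_subjects = 8, seed = 2))
#' glance(run)
#' }
#' @export
la_pipeline <- function(x = cohort_spec(),
                        measure = c("keypresses", "viewtime"),
                        form = "power", fraction = 0.10, dead_band = 0.05,
                        roi = "left", z_threshold = 1.96,
                        alpha_isolated = 0.05, alpha_age = 0.025,
                        outdir = NULL) {
  measure <- match.arg(measure)
  sim <- if (inherits(x, "cohort_spec")) {
    run_stage("simulate", simulate_cohort(x))
  } else if (inherits(x, "lapref_cohort")) {
    x
  } else {
    abort("x must be a cohort_spec or a lapref_cohort")
  }
  if (is.null(sim$sessions) || is.null(sim$voxels)) {
    abort("cohort must include sessions and voxels (simulate_cohort(include = c('sessions','voxels')))")
  }

  valuation <- run_stage("behavior", {
    trials <- purrr::map_dfr(sim$sessions, "trials")
    category_valuation(trials, measure = measure, dead_band = dead_band)
  })
  la <- run_stage("loss_aversion",
                  estimate_loss_aversion(valuation, form = form,
                                         fraction = fraction))
  nds <- run_stage("nds", {
    design <- build_design_matrix(sim$timeline, tr = sim$spec$tr)
    purrr::imap_dfr(sim$voxels, function(vox, id) {
      if (isTRUE(sim$cohort$motion_artifact[sim$cohort$subject_id == id])) {
        return(tibble::tibble(subject_id = id, nds = NA_real_,
                              n_voxels_used = 0L, n_roi_voxels = NA_integer_,
                              threshold_z = z_threshold, hemisphere = roi,
                              valid = FALSE))
      }
      fit <- fit_glm(vox, design)
      res <- extract_nds(contrast_neg_minus_pos(fit), roi = roi,
                         z_threshold = z_threshold)
      dplyr::bind_cols(tibble::tibble(subject_id = id), res)
    })
  })
  cohort <- run_stage("cohort", {
    ages <- dplyr::select(sim$cohort, "subject_id", "age")
    assemble_cohort(ages, la, nds)
  })
  associations <- run_stage("inference", {
    a1 <- correlate_nds_la(cohort, alpha = alpha_isolated)
    a2 <- regress_on_age(cohort, "nds", alpha = alpha_age)
    a3 <- regress_on_age(cohort, "lam", alpha = alpha_age)
    list(a1, a2, a3)
  })
  exclusions <- purrr::map_dfr(associations, function(a) {
    ex <- attr(a, "excluded")
    if (is.null(ex) || !nrow(ex)) return(NULL)
    dplyr::mutate(ex, association = a$name[1], .before = 1)
  })
  associations <- dplyr::bind_rows(associations)

  params <- list(
    seed = sim$spec$seed, n_subjects = sim$spec$n_subjects,
    measure = measure, form = form, fraction = fraction,
    dead_band = dead_band, roi = roi, z_threshold = z_threshold,
    alpha_isolated = alpha_isolated, alpha_age = alpha_age
  )
  run <- structure(
    list(cohort = cohort, valuation = valuation, la = la, nds = nds,
         associations = associations, exclusions = exclusions,
         params = params, spec = sim$spec),
    class = "lapref_run"
  )
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(as.data.frame(run$cohort), file.path(outdir, "cohort.csv"))
  readr::write_csv(run$associations, file.path(outdir, "associations.csv"))
  readr::write_csv(run$valuation, file.path(outdir, "valuation.csv"))
  readr::write_csv(run$la, file.path(outdir, "la.csv"))
  if (nrow(run$exclusions)) {
    readr::write_csv(run$exclusions, file.path(outdir, "exclusions.csv"))
  }
  log <- c(run$params,
           list(package_version = as.character(utils::packageVersion("lapref")),
                r_version = R.version.string))
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.lapref_run <- function(x, ...) {
  n <- nrow(x$cohort)
  usable <- x$cohort[!x$cohort$la_outlier & is.finite(x$cohort$lambda), ]
  cat(sprintf("<lapref_run> %d subjects (seed %s)\n", n, x$params$seed))
  cat(sprintf("  lambda (non-outliers, n = %d): mean %.2f, SE %.2f\n",
              nrow(usable), mean(usable$lambda),
              sd(usable$lambda) / sqrt(nrow(usable))))
  cat(sprintf("  lambda outliers: %d; invalid imaging: %d\n",
              sum(x$cohort$la_outlier), sum(!x$cohort$valid_imaging)))
  cat("  associations:\n")
  for (i in seq_len(nrow(x$associations))) {
    a <- x$associations[i, ]
    cat(sprintf("    %-7s estimate %8.4f  stat %7.2f  p %.4g  n %d  %s\n",
                a$name, a$estimate, a$test_statistic, a$p, a$n_used,
                if (a$significant) sprintf("significant at %.3g", a$alpha) else "ns"))
  }
  invisible(x)
}
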