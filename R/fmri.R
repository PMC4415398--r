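#' Canonical double-gamma hemodynamic response function
#'
#' `h(t) = g(t; peak, 1) - g(t; undershoot, 1) / ratio` where `g` is the
#' gamma density with unit scale. Defaults (response delay 6 s, undershoot
#' delay 16 s, ratio 6) give the canonical shape peaking about 5 s after
#' stimulus onset with a shallow undershoot resolving by ~25 s.
#'
#' @param t Time in seconds (vectorized); negative times return 0.
#' @param peak Shape of the response gamma (s), default 6.
#' @param undershoot Shape of the undershoot gamma (s), default 16.
#' @param ratio Response-to-undershoot amplitude ratio, default 6.
#' @return The HRF evaluated at `t`, normalized to unit peak.
#' @examples
#' t <- seq(0, 30, by = 0.1)
#' plot(t, hrf_double_gamma(t), type = "l")
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  h <- dgamma(pmax(t, 0), shape = peak, rate = 1) -
    dgamma(pmax(t, 0), shape = undershoot, rate = 1) / ratio
  h[t < 0] <- 0
  tp <- seq(0, peak + undershoot, by = 0.01)
  hp <- dgamma(tp, shape = peak, rate = 1) -
    dgamma(tp, shape = undershoot, rate = 1) / ratio
  h / max(hp)
}

#' Build an HRF-convolved GLM design matrix from a stimulus timeline
#'
#' One regressor per condition present in the timeline except fixation
#' (the implicit baseline): the condition's stimulus indicator (1 while
#' any of its events is on screen, sampled on a fine grid) is convolved
#' with the double-gamma HRF and sampled at volume midpoints
#' `(i - 0.5) * tr`. An intercept and a linear drift column (centered,
#' unit range) are appended.
#'
#' @param timeline A `stimulus_timeline` tibble (columns `onset`,
#'   `duration`, `trial_type`).
#' @param tr Repetition time in seconds (default 2.5).
#' @param n_volumes Number of volumes; defaults to
#'   `floor(total_duration / tr)`.
#' @param hrf Function of time giving the HRF (default
#'   [hrf_double_gamma()]).
#' @param dt Fine sampling grid for the convolution, seconds (default
#'   0.1).
#' @return A `design_matrix`: numeric matrix with one column per modeled
#'   condition plus `intercept` and `drift`, with attributes `tr`,
#'   `conditions` and `frame_times`.
#' @export
build_design_matrix <- function(timeline, tr = 2.5, n_volumes = NULL,
                                hrf = hrf_double_gamma, dt = 0.1) {
  if (tr <= 0) abort("tr must be positive")
  if (nrow(timeline) == 0) abort("empty timeline")
  total <- attr(timeline, "total_duration") %||%
    max(timeline$onset + timeline$duration)
  if (total < 2 * tr) abort("timeline must cover at least two volumes")
  n_volumes <- n_volumes %||% floor(total / tr)

  conds <- setdiff(unique(timeline$trial_type), "fixation")
  if (!length(conds)) abort("timeline has no modeled conditions")
  # canonical condition order where applicable, extras appended
  conds <- c(intersect(face_conditions()$condition, conds),
             setdiff(conds, face_conditions()$condition))

  grid <- seq(0, total + 32, by = dt) # pad for the HRF tail
  kern <- hrf(seq(0, 32, by = dt))
  frame_times <- (seq_len(n_volumes) - 0.5) * tr

  cols <- purrr::map(conds, function(cond) {
    ev <- timeline[timeline$trial_type == cond, ]
    stim <- numeric(length(grid))
    for (i in seq_len(nrow(ev))) {
      on <- grid >= ev$onset[i] & grid < ev$onset[i] + ev$duration[i]
      stim[on] <- 1
    }
    reg <- stats::convolve(stim, rev(kern), type = "open")[seq_along(grid)] * dt
    stats::approx(grid, reg, xout = frame_times, rule = 2)$y
  })
  X <- do.call(cbind, cols)
  colnames(X) <- conds
  drift <- (frame_times - mean(frame_times)) / diff(range(frame_times))
  X <- cbind(X, intercept = 1, drift = drift)
  attr(X, "tr") <- tr
  attr(X, "conditions") <- conds
  attr(X, "frame_times") <- frame_times
  class(X) <- c("design_matrix", class(X))
  X
}

#' Fit the GLM to every voxel of a voxel table
#'
#' Ordinary least squares per voxel against a shared design matrix, with
#' residual variance on `df = n_volumes - n_columns` degrees of freedom.
#'
#' @param voxels A voxel table: tibble with `voxel_id`, `roi_label` and
#'   one `t<i>` column per volume (see [read_voxel_tsv()] /
#'   [simulate_voxel_table()]).
#' @param design A `design_matrix` from [build_design_matrix()].
#' @return A `voxel_glm_fit`: list with `betas` (voxels x regressors
#'   matrix), `sigma2` (residual variances), `df`, `xtx_inv`, `design`
#'   and the voxel metadata.
#' @export
fit_glm <- function(voxels, design) {
  X <- unclass(design)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    abort("design matrix is rank deficient", class = "lapref_error_rank")
  }
  ycols <- grep("^t\\d+$", names(voxels), value = TRUE)
  if (length(ycols) != nrow(X)) {
    abort(sprintf("voxel series length (%d) does not match design rows (%d)",
                  length(ycols), nrow(X)))
  }
  Y <- t(as.matrix(voxels[, ycols])) # volumes x voxels
  B <- qr.coef(qrX, Y)               # regressors x voxels
  resid <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  structure(
    list(
      betas = t(B),
      sigma2 = unname(sigma2),
      df = df,
      xtx_inv = solve(crossprod(X)),
      design = design,
      voxel_id = voxels$voxel_id,
      roi_label = voxels$roi_label
    ),
    class = "voxel_glm_fit"
  )
}

# two-sided tail matching in log space so extreme t keep finite z
t_to_z <- function(t, df) {
  logp <- pt(abs(t), df, lower.tail = FALSE, log.p = TRUE)
  sign(t) * qnorm(logp, lower.tail = FALSE, log.p = TRUE)
}

#' Negative-minus-positive contrast per voxel
#'
#' The neural-differential-sensitivity contrast: mean of the angry,
#' fearful and sad betas minus the happy beta, with its OLS standard
#' error, t statistic and the z deviate obtained by tail-probability
#' matching.
#'
#' @param fit A `voxel_glm_fit` from [fit_glm()].
#' @param negative,positive Condition column names forming the two sides
#'   (defaults: angry/fearful/sad vs happy). Each side is averaged.
#' @return A tibble with one row per voxel: `voxel_id`, `roi_label`,
#'   `beta_neg`, `beta_pos`, `contrast`, `se`, `t`, `z`.
#' @export
contrast_neg_minus_pos <- function(fit,
                                   negative = c("angry", "fearful", "sad"),
                                   positive = "happy") {
  stopifnot(inherits(fit, "voxel_glm_fit"))
  cols <- colnames(fit$betas)
  missing <- setdiff(c(negative, positive), cols)
  if (length(missing)) {
    abort(paste0("condition beta(s) missing from the fit: ",
                 paste(missing, collapse = ", ")))
  }
  cvec <- setNames(numeric(length(cols)), cols)
  cvec[negative] <- 1 / length(negative)
  cvec[positive] <- cvec[positive] - 1 / length(positive)
  beta_neg <- drop(fit$betas[, negative, drop = FALSE] %*%
                     rep(1 / length(negative), length(negative)))
  beta_pos <- drop(fit$betas[, positive, drop = FALSE] %*%
                     rep(1 / length(positive), length(positive)))
  cvar <- drop(t(cvec) %*% fit$xtx_inv %*% cvec)
  se <- sqrt(fit$sigma2 * cvar)
  contrast <- beta_neg - beta_pos
  # exactly-zero residual variance: a nonzero contrast is infinitely certain
  tstat <- ifelse(se > 0, contrast / se,
                  ifelse(contrast == 0, 0, sign(contrast) * Inf))
  tibble::tibble(
    voxel_id = fit$voxel_id,
    roi_label = fit$roi_label,
    beta_neg = unname(beta_neg),
    beta_pos = unname(beta_pos),
    contrast = unname(contrast),
    se = unname(se),
    t = unname(tstat),
    z = t_to_z(unname(tstat), fit$df)
  )
}

#' Extract per-subject neural differential sensitivity (NDS)
#'
#' NDS is the mean negative-minus-positive contrast over
#' region-of-interest voxels whose z exceeds the threshold (default
#' z = 1.96, i.e. p < 0.05). If no ROI voxel survives thresholding the
#' result is marked invalid (`valid = FALSE`, `nds = NA`) and the subject
#' is excluded downstream, as with motion-artifact subjects.
#'
#' @param contrasts Per-voxel contrast tibble from
#'   [contrast_neg_minus_pos()].
#' @param roi `"left"`, `"right"` or `"bilateral"` — which VS/NAc
#'   hemisphere labels to sample.
#' @param z_threshold Supra-threshold cut (default 1.96).
#' @return A one-row tibble: `nds`, `n_voxels_used`, `n_roi_voxels`,
#'   `threshold_z`, `hemisphere`, `valid`.
#' @examples
#' cc <- tibble::tibble(voxel_id = 1:3, roi_label = "VS_NAc_left",
#'                      contrast = c(0.5, 0.7, 0.9), z = c(3, 4, 5))
#' extract_nds(cc, roi = "left")$nds # 0.7
#' @export
extract_nds <- function(contrasts, roi = c("left", "right", "bilateral"),
                        z_threshold = 1.96) {
  roi <- match.arg(roi)
  labels <- switch(roi,
    left = "VS_NAc_left",
    right = "VS_NAc_right",
    bilateral = c("VS_NAc_left", "VS_NAc_right")
  )
  in_roi <- contrasts[contrasts$roi_label %in% labels, ]
  if (nrow(in_roi) == 0) {
    abort(sprintf("no voxels labeled for roi '%s'", roi),
          class = "lapref_error_roi")
  }
  supra <- in_roi[in_roi$z > z_threshold, ]
  tibble::tibble(
    nds = if (nrow(supra)) mean(supra$contrast) else NA_real_,
    n_voxels_used = nrow(supra),
    n_roi_voxels = nrow(in_roi),
    threshold_z = z_threshold,
    hemisphere = roi,
    valid = nrow(supra) > 0
  )
}

#' Read or write a voxel table as TSV
#'
#' Columns: `voxel_id`, `roi_label`, then one column per volume named
#' `t1 ... tN`.
#'
#' @param voxels Voxel table tibble.
#' @param path File path.
#' @return `write_voxel_tsv()` returns `path` invisibly;
#'   `read_voxel_tsv()` the voxel table with a `tr` attribute when the
#'   file carries one in a `# tr:` header comment.
#' @export
write_voxel_tsv <- function(voxels, path) {
  tr <- attr(voxels, "tr")
  body <- readr::format_tsv(as.data.frame(voxels))
  header <- if (!is.null(tr)) sprintf("# tr: %s\n", format(tr)) else ""
  cat(header, body, file = path, sep = "")
  invisible(path)
}

#' @rdname write_voxel_tsv
#' @export
read_voxel_tsv <- function(path) {
  first <- readLines(path, n = 1)
  tr <- NULL
  if (startsWith(first, "# tr:")) {
    tr <- as.numeric(sub("# tr:", "", first))
  }
  voxels <- readr::read_tsv(path, comment = "#", progress = FALSE,
                            show_col_types = FALSE)
  if (!is.null(tr)) attr(voxels, "tr") <- tr
  voxels
}
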