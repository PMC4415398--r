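#' Ground-truth specification for one synthetic subject
#'
#' @param subject_id Identifier.
#' @param age Age in years.
#' @param true_lambda Ground-truth loss aversion (> 0): avoidance effort
#'   per unit negative valence relative to approach effort per unit
#'   positive valence.
#' @param approach_gain Mean keypresses per unit positive valence
#'   (default 20, so a unit-valence happy picture draws ~20 approach
#'   presses and, at `true_lambda = 2`, a unit-negative picture ~40 avoid
#'   presses).
#' @param keypress_noise Count dispersion: 0 = deterministic rounded
#'   means, 1 = Poisson, > 1 = negative binomial with variance
#'   `keypress_noise * mean`.
#' @param nds_true Ground-truth NDS contrast (signal units).
#' @return A `subject_spec` list.
#' @export
subject_spec <- function(subject_id, age = 35, true_lambda = 2,
                         approach_gain = 20, keypress_noise = 1,
                         nds_true = 0.5) {
  if (true_lambda <= 0) abort("true_lambda must be positive")
  if (keypress_noise < 0) abort("keypress_noise must be >= 0")
  structure(
    list(subject_id = as.character(subject_id), age = age,
         true_lambda = true_lambda, approach_gain = approach_gain,
         keypress_noise = keypress_noise, nds_true = nds_true),
    class = "subject_spec"
  )
}

#' Default picture set with latent valences
#'
#' Eight pictures per face category. Latent valences are the category
#' valence (happy +1, angry/fearful/sad -1, neutral 0) plus per-picture
#' jitter drawn Uniform(-jitter, jitter) and centred within category, so
#' the category mean valence is exact while within-category variation
#' keeps the entropy H of keypress patterns non-degenerate.
#'
#' @param n_per_category Pictures per category (default 8 identities).
#' @param jitter Half-width of the uniform per-picture valence jitter
#'   (default 0.2).
#' @param seed Optional integer seed.
#' @return A tibble with `picture_id`, `category`, `valence`.
#' @export
picture_set <- function(n_per_category = 8, jitter = 0.2, seed = NULL) {
  base <- c(angry = -1, fearful = -1, happy = 1, sad = -1, neutral = 0)
  build <- function() {
    purrr::imap_dfr(base, function(v, cond) {
      j <- runif(n_per_category, -jitter, jitter)
      j <- j - mean(j)
      tibble::tibble(
        picture_id = sprintf("%s_face%02d", cond, seq_len(n_per_category)),
        category = cond,
        valence = v + j
      )
    })
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

draw_counts <- function(mu, noise) {
  n <- length(mu)
  if (noise == 0) return(as.integer(round(mu)))
  if (noise <= 1) return(rpois(n, mu))
  out <- integer(n)
  pos <- mu > 0
  # NB parameterized so Var = noise * mu
  out[pos] <- rnbinom(sum(pos), mu = mu[pos], size = mu[pos] / (noise - 1))
  out
}

#' Simulate one subject's keypress session
#'
#' Each picture is one trial. Approach counts are drawn with mean
#' `approach_gain * max(valence, 0)` and avoid counts with mean
#' `approach_gain * true_lambda * max(-valence, 0)`, using the count model
#' set by `keypress_noise` (see [subject_spec()]). Events alternate
#' buttons within a class (1/2 approach, 3/4 avoid) at 250 ms spacing, and
#' per-trial viewing time follows [compute_viewtime()].
#'
#' @param spec A [subject_spec()].
#' @param pictures Picture table from [picture_set()]; by default a
#'   fresh default picture set is drawn inside the session's seeded
#'   random stream.
#' @param seed Optional integer seed; the same seed reproduces the
#'   session.
#' @return A `keypress_session` list with `subject_id`, `trials` (one row
#'   per picture, via [tally_trials()] semantics) and `events` (one row
#'   per keypress).
#' @export
simulate_keypress_session <- function(spec, pictures = NULL, seed = NULL) {
  stopifnot(inherits(spec, "subject_spec"))
  if (!is.null(pictures) && nrow(pictures) == 0) abort("empty picture list")
  build <- function() {
    # default pictures drawn inside the seeded region for reproducibility
    if (is.null(pictures)) pictures <- picture_set()
    mu_app <- spec$approach_gain * pmax(pictures$valence, 0)
    mu_avd <- spec$approach_gain * spec$true_lambda * pmax(-pictures$valence, 0)
    n_app <- draw_counts(mu_app, spec$keypress_noise)
    n_avd <- draw_counts(mu_avd, spec$keypress_noise)
    trials <- tibble::tibble(
      subject_id = spec$subject_id,
      trial_index = seq_len(nrow(pictures)),
      picture_id = pictures$picture_id,
      category = pictures$category,
      n_approach = as.integer(n_app),
      n_avoid = as.integer(n_avd),
      net = as.integer(n_app) - as.integer(n_avd),
      viewtime = compute_viewtime(n_app, n_avd)
    )
    events <- purrr::pmap_dfr(
      trials[, c("trial_index", "picture_id", "category", "n_approach", "n_avoid")],
      function(trial_index, picture_id, category, n_approach, n_avoid) {
        n <- n_approach + n_avoid
        if (n == 0) return(NULL)
        key <- c(rep(c(1L, 2L), length.out = n_approach),
                 rep(c(3L, 4L), length.out = n_avoid))
        tibble::tibble(
          subject_id = spec$subject_id,
          trial_index = trial_index, picture_id = picture_id,
          category = category, key_id = key,
          key_class = c(rep("approach", n_approach), rep("avoid", n_avoid)),
          timestamp_s = 0.25 * seq_len(n)
        )
      }
    )
    structure(list(subject_id = spec$subject_id, trials = trials,
                   events = events),
              class = "keypress_session")
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Simulate an ROI voxel table for one subject
#'
#' Each voxel's series is the HRF-convolved condition design times
#' per-condition amplitudes plus white noise, on top of a baseline and a
#' linear drift. Responsive ROI voxels respond to every face condition and
#' scrambled stimuli with amplitude `base_amp`, except the negative
#' conditions (angry, fearful, sad) which carry `base_amp + nds_true` so
#' that the negative-minus-positive contrast equals `nds_true` exactly.
#' Null voxels (label `none`) have zero response.
#'
#' @param spec A [subject_spec()] (supplies `nds_true`).
#' @param timeline A `stimulus_timeline`.
#' @param n_voxels Total voxels (default 100).
#' @param tr Repetition time in seconds (default 2.5).
#' @param noise_sd White-noise SD in signal units (default 0.5; about 1%
#'   of baseline, small enough that responsive VS/NAc voxels are reliably
#'   supra-threshold at z > 1.96, as in most scanned subjects).
#' @param prop_roi Fraction of voxels inside the ROI, split evenly between
#'   `VS_NAc_left` and `VS_NAc_right` (default 0.6).
#' @param base_amp Common face-response amplitude (default 1).
#' @param baseline Baseline signal level (default 100).
#' @param drift_amp Linear drift amplitude over the run (default 0.5).
#' @param seed Optional integer seed.
#' @return A voxel table: tibble `voxel_id`, `roi_label`, `t1...tN`, with
#'   attributes `tr` and `nds_true`.
#' @export
simulate_voxel_table <- function(spec, timeline, n_voxels = 100, tr = 2.5,
                                 noise_sd = 0.5, prop_roi = 0.6,
                                 base_amp = 1, baseline = 100,
                                 drift_amp = 0.5, seed = NULL) {
  stopifnot(inherits(spec, "subject_spec"))
  if (tr <= 0) abort("tr must be positive")
  conds_present <- unique(timeline$trial_type)
  if (!any(conds_present %in% negative_conditions()) ||
      !any(conds_present %in% positive_conditions())) {
    abort("timeline must include negative and positive face blocks")
  }
  design <- build_design_matrix(timeline, tr = tr)
  conds <- attr(design, "conditions")
  amps <- setNames(numeric(length(conds)), conds)
  amps[intersect(conds, c("angry", "fearful", "sad", "happy", "neutral"))] <- base_amp
  amps[intersect(conds, "scrambled")] <- 0.5 * base_amp
  amps[intersect(conds, negative_conditions())] <-
    amps[intersect(conds, negative_conditions())] + spec$nds_true

  n_roi <- round(prop_roi * n_voxels)
  n_left <- ceiling(n_roi / 2)
  labels <- c(rep("VS_NAc_left", n_left), rep("VS_NAc_right", n_roi - n_left),
              rep("none", n_voxels - n_roi))
  Xc <- unclass(design)[, conds, drop = FALSE]
  drift <- unclass(design)[, "drift"]
  n_vol <- nrow(Xc)
  signal_roi <- drop(Xc %*% amps)

  build <- function() {
    mat <- matrix(rnorm(n_voxels * n_vol, sd = noise_sd), nrow = n_voxels)
    base_row <- baseline + drift_amp * drift
    mat <- sweep(mat, 2, base_row, "+")
    roi <- labels != "none"
    mat[roi, ] <- sweep(mat[roi, , drop = FALSE], 2, signal_roi, "+")
    out <- tibble::as_tibble(mat, .name_repair = ~ paste0("t", seq_len(n_vol)))
    out <- dplyr::bind_cols(
      tibble::tibble(voxel_id = sprintf("v%03d", seq_len(n_voxels)),
                     roi_label = labels),
      out
    )
    attr(out, "tr") <- tr
    attr(out, "nds_true") <- spec$nds_true
    out
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Cohort-level simulation settings
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' 17 subjects aged 20-55; ground-truth loss aversion log-normal around 2
#' (log-SD 0.3) and independent of age, with a heavy-tailed minority
#' (rate 5/17, log-SD 1.5) exercising the 2-SD outlier rule; NDS rising
#' 0.02 contrast units per year of age and coupled to log-lambda
#' (0.7 units per log unit) so the emulated cohort reproduces, in
#' expectation, an NDS~age variance ratio near F ~ 9 and an NDS~LA
#' correlation near 0.64 among non-outliers; and a 2/17 rate of
#' motion-artifact subjects with unusable imaging.
#'
#' @param n_subjects Cohort size (default 17).
#' @param seed Integer seed for every random draw of the cohort.
#' @param age_range Years, default `c(20, 55)`.
#' @param beta_age_nds NDS change per year of age (default 0.02).
#' @param nds_intercept NDS at age 0 (default -0.2, i.e. ~0.5 at the
#'   cohort's mid-thirties mean age).
#' @param beta_la_nds NDS change per unit centred log-lambda (default
#'   0.7).
#' @param beta_age_la Log-lambda change per year of age (default 0: loss
#'   aversion independent of age).
#' @param noise_sd_nds Residual SD of ground-truth NDS (default 0.156).
#' @param lambda_meanlog,lambda_sdlog Log-normal parameters of core
#'   lambda (defaults `log(2)`, 0.3).
#' @param outlier_rate Probability a subject's lambda comes from the
#'   inflated-tail distribution (default 5/17).
#' @param lambda_outlier_sdlog Log-SD of the inflated tail (default 1.5).
#' @param p_motion Probability of a motion-artifact (invalid imaging)
#'   subject (default 2/17).
#' @param approach_gain,keypress_noise Passed to each [subject_spec()].
#' @param jitter Per-picture valence jitter half-width (default 0.2).
#' @param n_blocks Blocks in the simulated run (default 25).
#' @param n_voxels,voxel_noise_sd,tr Voxel-table settings (defaults 100,
#'   0.5, 2.5).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 17, seed = 1,
                        age_range = c(20, 55),
                        beta_age_nds = 0.02, nds_intercept = -0.2,
                        beta_la_nds = 0.7, beta_age_la = 0,
                        noise_sd_nds = 0.156,
                        lambda_meanlog = log(2), lambda_sdlog = 0.3,
                        outlier_rate = 5 / 17, lambda_outlier_sdlog = 1.5,
                        p_motion = 2 / 17,
                        approach_gain = 20, keypress_noise = 1,
                        jitter = 0.2, n_blocks = 25,
                        n_voxels = 100, voxel_noise_sd = 0.5, tr = 2.5) {
  if (n_subjects < 3) abort("n_subjects must be >= 3")
  if (age_range[1] >= age_range[2]) abort("age_range low must be below high")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Simulate a full synthetic cohort
#'
#' Draws per-subject ground truth (age, lambda, NDS, motion flag) and,
#' when requested, each subject's keypress session and ROI voxel table
#' against a shared counterbalanced 25-block timeline. All randomness
#' flows from `spec$seed`; the ground-truth table is identical whichever
#' components are included.
#'
#' @param spec A [cohort_spec()].
#' @param include Components to generate besides the ground-truth table:
#'   any of `"sessions"`, `"voxels"` (default both). `include =
#'   character()` gives the fast table-only path used for calibration
#'   studies.
#' @return A `lapref_cohort` list: `cohort` (tibble of `subject_id`,
#'   `age`, `true_lambda`, `nds_true`, `tail_lambda`, `motion_artifact`),
#'   `pictures`, `timeline`, `sessions` (named list of keypress
#'   sessions), `voxels` (named list of voxel tables), and `spec`.
#' @examples
#' sim <- simulate_cohort(cohort_spec(n_subjects = 5, seed = 1),
#'                        include = "sessions")
#' sim$cohort
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            include = c("sessions", "voxels")) {
  stopifnot(inherits(spec, "cohort_spec"))
  include <- intersect(include, c("sessions", "voxels"))
  withr::with_seed(spec$seed, {
    ids <- sprintf("sub%02d", seq_len(spec$n_subjects))
    age <- round(runif(spec$n_subjects, spec$age_range[1], spec$age_range[2]), 1)
    tail_lambda <- rbinom(spec$n_subjects, 1, spec$outlier_rate) == 1
    sdlog <- ifelse(tail_lambda, spec$lambda_outlier_sdlog, spec$lambda_sdlog)
    age_mid <- mean(spec$age_range)
    loglam <- spec$lambda_meanlog + spec$beta_age_la * (age - age_mid) +
      rnorm(spec$n_subjects, 0, sdlog)
    true_lambda <- exp(loglam)
    nds_true <- spec$nds_intercept + spec$beta_age_nds * age +
      spec$beta_la_nds * (loglam - spec$lambda_meanlog) +
      rnorm(spec$n_subjects, 0, spec$noise_sd_nds)
    motion <- rbinom(spec$n_subjects, 1, spec$p_motion) == 1

    cohort <- tibble::tibble(
      subject_id = ids, age = age, true_lambda = true_lambda,
      nds_true = nds_true, tail_lambda = tail_lambda,
      motion_artifact = motion
    )
    subjects <- purrr::pmap(
      cohort[, c("subject_id", "age", "true_lambda", "nds_true")],
      function(subject_id, age, true_lambda, nds_true) {
        subject_spec(subject_id, age = age, true_lambda = true_lambda,
                     approach_gain = spec$approach_gain,
                     keypress_noise = spec$keypress_noise,
                     nds_true = nds_true)
      }
    )

    pictures <- NULL; timeline <- NULL; sessions <- NULL; voxels <- NULL
    if (length(include)) {
      pictures <- picture_set(jitter = spec$jitter)
      blocks <- generate_block_sequence(spec$n_blocks)
      timeline <- build_timeline(blocks)
    }
    if ("sessions" %in% include) {
      sessions <- purrr::map(subjects, simulate_keypress_session,
                             pictures = pictures)
      names(sessions) <- ids
    }
    if ("voxels" %in% include) {
      voxels <- purrr::map(subjects, simulate_voxel_table,
                           timeline = timeline, n_voxels = spec$n_voxels,
                           tr = spec$tr, noise_sd = spec$voxel_noise_sd)
      names(voxels) <- ids
    }
    structure(
      list(cohort = cohort, pictures = pictures, timeline = timeline,
           sessions = sessions, voxels = voxels, spec = spec),
      class = "lapref_cohort"
    )
  })
}
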