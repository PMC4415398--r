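test_that("picture valences are centred within category with non-zero jitter", {
  pics <- picture_set(seed = 5)
  by_cat <- dplyr::summarise(dplyr::group_by(pics, category),
                             m = mean(valence), s = sd(valence))
  expect_equal(by_cat$m[by_cat$category == "happy"], 1)
  expect_equal(by_cat$m[by_cat$category == "angry"], -1)
  expect_equal(by_cat$m[by_cat$category == "neutral"], 0)
  expect_true(all(by_cat$s > 0))
})

test_that("noiseless sessions put lambda into the avoid/approach count ratio", {
  pics <- tibble::tibble(
    picture_id = c("h1", "h2", "a1", "a2"),
    category = c("happy", "happy", "angry", "angry"),
    valence = c(1, 1, -1, -1)
  )
  sym <- simulate_keypress_session(
    subject_spec("s1", true_lambda = 1, keypress_noise = 0), pics)
  expect_equal(mean(sym$trials$n_avoid[sym$trials$category == "angry"]),
               mean(sym$trials$n_approach[sym$trials$category == "happy"]))
  dbl <- simulate_keypress_session(
    subject_spec("s2", true_lambda = 2, keypress_noise = 0), pics)
  val <- suppressWarnings(category_valuation(dbl$trials))
  expect_equal(val$K[val$category == "angry"],
               -2 * val$K[val$category == "happy"])
})

test_that("sessions are reproducible under a seed and reject empty pictures", {
  spec <- subject_spec("s1", true_lambda = 2)
  a <- simulate_keypress_session(spec, seed = 7)
  b <- simulate_keypress_session(spec, seed = 7)
  expect_identical(a$events, b$events)
  expect_identical(a$trials, b$trials)
  expect_error(simulate_keypress_session(spec, pictures = picture_set(0)),
               "empty")
})

test_that("session events tally back to the session trials", {
  ses <- simulate_keypress_session(subject_spec("s1", true_lambda = 2.5),
                                   seed = 11)
  stubs <- ses$trials[, c("subject_id", "trial_index", "picture_id", "category")]
  re <- tally_trials(ses$events, trials = stubs)
  expect_equal(re$n_approach, ses$trials$n_approach)
  expect_equal(re$n_avoid, ses$trials$n_avoid)
  expect_equal(re$viewtime, ses$trials$viewtime)
})

test_that("noiseless voxel tables are recovered end to end by the GLM chain", {
  tl <- build_timeline(generate_block_sequence(25, seed = 13), seed = 13)
  vox <- simulate_voxel_table(subject_spec("s1", nds_true = 0.5), tl,
                              n_voxels = 30, noise_sd = 0, seed = 1)
  cc <- contrast_neg_minus_pos(fit_glm(vox, build_design_matrix(tl)))
  roi <- cc[cc$roi_label != "none", ]
  expect_equal(roi$contrast, rep(0.5, nrow(roi)), tolerance = 1e-8)
  nds <- extract_nds(cc, roi = "bilateral")
  expect_true(nds$valid)
  expect_equal(nds$nds, 0.5, tolerance = 1e-8)
})

test_that("a zero ground-truth contrast is centred at zero", {
  tl <- build_timeline(generate_block_sequence(25, seed = 14), seed = 14)
  vox <- simulate_voxel_table(subject_spec("s1", nds_true = 0), tl,
                              n_voxels = 200, noise_sd = 1, prop_roi = 1,
                              seed = 3)
  cc <- contrast_neg_minus_pos(fit_glm(vox, build_design_matrix(tl)))
  se_mean <- mean(cc$se) / sqrt(nrow(cc))
  expect_lt(abs(mean(cc$contrast)), 4 * se_mean)
})

test_that("tr and timeline preconditions are enforced", {
  tl <- build_timeline(generate_block_sequence(10, seed = 2), seed = 2)
  expect_error(simulate_voxel_table(subject_spec("s1"), tl, tr = 0), "tr")
  no_pos <- make_block_timeline(c("angry", "fixation", "sad", "fixation"))
  expect_error(simulate_voxel_table(subject_spec("s1"), no_pos),
               "negative and positive")
})

test_that("a noiseless cohort lies exactly on the NDS~age line", {
  spec <- cohort_spec(n_subjects = 17, seed = 3, beta_age_nds = 0.02,
                      beta_la_nds = 0, noise_sd_nds = 0)
  sim <- simulate_cohort(spec, include = character())
  fit <- lm(nds_true ~ age, data = sim$cohort)
  expect_equal(unname(coef(fit)["age"]), 0.02, tolerance = 1e-10)
})

test_that("lambda is independent of age under the null across a large cohort", {
  spec <- cohort_spec(n_subjects = 800, seed = 4, beta_age_la = 0,
                      outlier_rate = 0)
  sim <- simulate_cohort(spec, include = character())
  expect_lt(abs(cor(sim$cohort$age, log(sim$cohort$true_lambda))), 0.1)
})

test_that("the heavy-tail mixture produces roughly the expected outlier count", {
  flagged <- purrr::map_int(1:30, function(s) {
    sim <- simulate_cohort(cohort_spec(n_subjects = 17, seed = 1000 + s,
                                       outlier_rate = 5 / 17),
                           include = character())
    sum(flag_outliers(sim$cohort$true_lambda))
  })
  # tail-drawn lambdas drive the >2 SD flags. With the sample SD in the
  # denominator, at most floor((n-1)/4) = 4 of 17 values can ever exceed
  # 2 SD (sum of squared z-scores is n-1), so flags cluster at 1-3.
  expect_gt(mean(flagged), 0.5)
  expect_true(all(flagged <= 4))
})

test_that("cohort ground truth is identical whichever components are included", {
  spec <- cohort_spec(n_subjects = 6, seed = 9)
  t_only <- simulate_cohort(spec, include = character())
  full <- simulate_cohort(spec)
  expect_identical(t_only$cohort, full$cohort)
  expect_length(full$sessions, 6)
  expect_length(full$voxels, 6)
  again <- simulate_cohort(spec)
  expect_identical(full$sessions$sub03$trials, again$sessions$sub03$trials)
  expect_equal(full$voxels$sub05$t17, again$voxels$sub05$t17)
})

test_that("cohort spec validates its arguments", {
  expect_error(cohort_spec(n_subjects = 2), ">= 3")
  expect_error(cohort_spec(age_range = c(50, 20)), "age_range")
  expect_error(subject_spec("x", true_lambda = -1), "positive")
})
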