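test_that("the double-gamma HRF is causal, unit-peak, and peaks ~5-6 s", {
  t <- seq(-5, 32, by = 0.01)
  h <- hrf_double_gamma(t)
  expect_true(all(h[t < 0] == 0))
  expect_equal(max(h), 1, tolerance = 1e-3)
  expect_gt(t[which.max(h)], 4)
  expect_lt(t[which.max(h)], 6.5)
  expect_lt(min(h), 0) # undershoot
})

test_that("a single-block regressor is causal and peaks after onset", {
  tl <- make_block_timeline(c("happy", "fixation", "fixation"))
  X <- build_design_matrix(tl, tr = 2.5)
  expect_equal(colnames(X), c("happy", "intercept", "drift"))
  reg <- X[, "happy"]
  ft <- attr(X, "frame_times")
  expect_true(all(abs(reg[ft < 0.5]) < 1e-6))
  peak_t <- ft[which.max(reg)]
  expect_gt(peak_t, 5)   # block onset 0, 20 s block: plateau from ~5 s
  expect_lt(peak_t, 26)
})

test_that("regressors are additive over non-overlapping identical blocks", {
  both <- make_block_timeline(c("happy", "fixation", "fixation", "fixation",
                                "happy", "fixation", "fixation", "fixation"))
  only1 <- make_block_timeline(rep("fixation", 8)); only1$trial_type[1] <- "happy"
  only2 <- make_block_timeline(rep("fixation", 8)); only2$trial_type[5] <- "happy"
  n_vol <- 64
  x_both <- build_design_matrix(both, n_volumes = n_vol)[, "happy"]
  x1 <- build_design_matrix(only1, n_volumes = n_vol)[, "happy"]
  x2 <- build_design_matrix(only2, n_volumes = n_vol)[, "happy"]
  expect_equal(x_both, x1 + x2, tolerance = 1e-8)
})

test_that("empty or too-short timelines are rejected", {
  expect_error(build_design_matrix(tibble::tibble(onset = numeric(),
                                                  duration = numeric(),
                                                  trial_type = character())),
               "empty")
  tiny <- make_block_timeline("happy", block_duration = 3)
  expect_error(build_design_matrix(tiny, tr = 2.5), "two volumes")
})

test_that("noiseless voxels recover their betas to numerical precision", {
  tl <- build_timeline(generate_block_sequence(15, seed = 3), seed = 3)
  X <- build_design_matrix(tl)
  conds <- attr(X, "conditions")
  beta <- setNames(seq(0.5, by = 0.25, length.out = length(conds)), conds)
  y <- drop(unclass(X)[, conds] %*% beta) + 100
  vox <- tibble::as_tibble(as.list(setNames(y, paste0("t", seq_along(y)))))
  vox <- dplyr::bind_cols(tibble::tibble(voxel_id = "v1", roi_label = "none"), vox)
  fit <- fit_glm(vox, X)
  expect_equal(unname(fit$betas[1, conds]), unname(beta), tolerance = 1e-8)
  expect_equal(unname(fit$betas[1, "intercept"]), 100, tolerance = 1e-6)
})

test_that("a rank-deficient design is rejected by name", {
  tl <- make_block_timeline(c("happy", "fixation", "angry", "fixation"))
  X <- build_design_matrix(tl)
  Xdup <- cbind(unclass(X), dup = unclass(X)[, "happy"])
  class(Xdup) <- class(X)
  vox <- tibble::as_tibble(as.list(setNames(rnorm(nrow(X)), paste0("t", seq_len(nrow(X))))))
  vox <- dplyr::bind_cols(tibble::tibble(voxel_id = "v1", roi_label = "none"), vox)
  expect_error(fit_glm(vox, Xdup), class = "lapref_error_rank")
})

test_that("the contrast averages the negative betas against happy", {
  tl <- build_timeline(generate_block_sequence(15, seed = 8), seed = 8)
  X <- build_design_matrix(tl)
  conds <- attr(X, "conditions")
  make_vox <- function(beta_by_cond, id) {
    beta <- setNames(numeric(length(conds)), conds)
    beta[names(beta_by_cond)] <- beta_by_cond
    y <- drop(unclass(X)[, conds] %*% beta)
    out <- tibble::as_tibble(as.list(setNames(y, paste0("t", seq_along(y)))))
    dplyr::bind_cols(tibble::tibble(voxel_id = id, roi_label = "none"), out)
  }
  vox <- dplyr::bind_rows(
    make_vox(c(angry = 1, fearful = 1, sad = 1, happy = 1), "v1"),
    make_vox(c(angry = 2, fearful = 2, sad = 2, happy = 1), "v2"),
    make_vox(c(angry = 1, fearful = 2, sad = 3, happy = 2), "v3")
  )
  cc <- contrast_neg_minus_pos(fit_glm(vox, X))
  expect_equal(cc$contrast, c(0, 1, 0), tolerance = 1e-8)
  expect_equal(cc$beta_neg - cc$beta_pos, cc$contrast)
})

test_that("contrasts are invariant to a constant added to all amplitudes", {
  tl <- build_timeline(generate_block_sequence(15, seed = 4), seed = 4)
  X <- build_design_matrix(tl)
  conds <- attr(X, "conditions")
  base <- setNames(c(1, 1.5, 1, 0.5, 1, 0.7), conds)[conds]
  shift <- base + 2
  mk <- function(beta) {
    y <- drop(unclass(X)[, conds] %*% beta) + rnorm(nrow(X), sd = 0) # noiseless
    out <- tibble::as_tibble(as.list(setNames(y, paste0("t", seq_along(y)))))
    dplyr::bind_cols(tibble::tibble(voxel_id = "v", roi_label = "none"), out)
  }
  c1 <- contrast_neg_minus_pos(fit_glm(mk(base), X))$contrast
  c2 <- contrast_neg_minus_pos(fit_glm(mk(shift), X))$contrast
  expect_equal(c1, c2, tolerance = 1e-8)
})

test_that("missing condition betas raise an error", {
  tl <- make_block_timeline(c("happy", "fixation", "angry", "fixation"))
  X <- build_design_matrix(tl)
  vox <- tibble::as_tibble(as.list(setNames(rnorm(nrow(X)), paste0("t", seq_len(nrow(X))))))
  vox <- dplyr::bind_cols(tibble::tibble(voxel_id = "v1", roi_label = "none"), vox)
  expect_error(contrast_neg_minus_pos(fit_glm(vox, X)), "missing")
})

test_that("NDS extraction averages supra-threshold ROI voxels", {
  cc <- tibble::tibble(voxel_id = 1:4,
                       roi_label = c(rep("VS_NAc_left", 3), "none"),
                       contrast = c(0.5, 0.7, 0.9, 5),
                       z = c(3, 4, 5, 9))
  res <- extract_nds(cc, roi = "left")
  expect_equal(res$nds, 0.7)
  expect_equal(res$n_voxels_used, 3L)
  sub <- dplyr::mutate(cc, z = 1)
  res2 <- extract_nds(sub, roi = "left")
  expect_false(res2$valid)
  expect_equal(res2$n_voxels_used, 0L)
  expect_error(extract_nds(cc, roi = "right"), class = "lapref_error_roi")
})

test_that("null voxels exceed z = 1.96 at about the one-sided normal rate", {
  tl <- build_timeline(generate_block_sequence(25, seed = 5), seed = 5)
  vox <- simulate_voxel_table(subject_spec("s1", nds_true = 0.4), tl,
                              n_voxels = 2500, prop_roi = 0.2,
                              noise_sd = 1, seed = 77)
  cc <- contrast_neg_minus_pos(fit_glm(vox, build_design_matrix(tl)))
  null_z <- cc$z[cc$roi_label == "none"]
  rate <- mean(null_z > 1.96)
  # 2000 null voxels: binomial 3 SD band around 0.025 is +/- 0.0105
  expect_lt(abs(rate - 0.025), 0.0105)
})

test_that("voxel tables round-trip through TSV with their TR", {
  tl <- build_timeline(generate_block_sequence(10, seed = 6), seed = 6)
  vox <- simulate_voxel_table(subject_spec("s1"), tl, n_voxels = 6, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_voxel_tsv(vox, path)
  back <- read_voxel_tsv(path)
  expect_equal(attr(back, "tr"), 2.5)
  expect_equal(back$roi_label, vox$roi_label)
  expect_equal(back$t5, vox$t5, tolerance = 1e-9)
})
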