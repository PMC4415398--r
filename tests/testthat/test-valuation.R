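test_that("exact lines and power curves are recovered", {
  lin <- fit_value_curve(tibble::tibble(H = c(1, 2, 3), K = c(2, 4, 6)),
                         form = "linear")
  expect_equal(lin$params[["a"]], 2)
  expect_equal(lin$rms_residual, 0)

  h <- c(0.25, 0.5, 1, 1.5, 2)
  pow <- fit_value_curve(tibble::tibble(H = h, K = h^2), form = "power")
  expect_equal(pow$form, "power")
  expect_equal(pow$params[["a"]], 1, tolerance = 1e-6)
  expect_equal(pow$params[["b"]], 2, tolerance = 1e-6)

  quad <- fit_value_curve(tibble::tibble(H = h, K = 3 * h + 0.5 * h^2),
                          form = "quadratic")
  expect_equal(unname(quad$params), c(3, 0.5), tolerance = 1e-8)
})

test_that("avoidance fits carry negative fitted values", {
  fit <- fit_value_curve(tibble::tibble(H = 1:3, K = -2 * (1:3)))
  expect_equal(fit$limb, "avoidance")
  expect_true(all(predict(fit, seq(1, 3, by = 0.1)) <= 0))
})

test_that("under-determined forms fall back to linear and degenerate input errors", {
  two <- fit_value_curve(tibble::tibble(H = c(1, 2), K = c(2, 4)), form = "power")
  expect_equal(two$form, "linear")
  expect_equal(two$form_requested, "power")
  expect_error(
    fit_value_curve(tibble::tibble(H = c(1, 2), K = c(2, 4)), form = "power",
                    fallback = FALSE),
    class = "lapref_error_unfittable"
  )
  expect_error(
    fit_value_curve(tibble::tibble(H = c(2, 2, 2), K = c(1, 2, 3)),
                    form = "linear"),
    class = "lapref_error_unfittable"
  )
  expect_error(fit_value_curve(tibble::tibble(H = c(1, 2), K = c(-1, 2))),
               "mix limbs")
})

test_that("local slope matches closed forms", {
  lin <- fit_value_curve(tibble::tibble(H = 1:3, K = 2 * (1:3)), form = "linear")
  expect_equal(local_slope(lin, 0.1), 2)
  expect_equal(local_slope(lin, 1), 2) # fraction -> 1 equals the global slope

  h <- seq(0, 1, by = 0.1)
  pow <- fit_value_curve(tibble::tibble(H = h, K = h^2), form = "power")
  expect_equal(local_slope(pow, 0.1), 0.1, tolerance = 1e-6)

  mirror <- fit_value_curve(tibble::tibble(H = 1:3, K = -2 * (1:3)),
                            form = "linear")
  expect_equal(local_slope(mirror, 0.1), -2)
  expect_error(local_slope(lin, 0), "fraction")
})

test_that("loss aversion is the absolute slope ratio", {
  pts <- mirrored_line_points(4.5, 2.0)
  la <- loss_aversion(fit_value_curve(pts$neg, form = "linear"),
                      fit_value_curve(pts$pos, form = "linear"))
  expect_equal(la$lambda, 2.25)
  expect_equal(la$s_minus, -4.5)
  expect_equal(la$s_plus, 2.0)

  la2 <- loss_aversion(
    fit_value_curve(tibble::tibble(H = 1:3, K = -2.06 * (1:3)), form = "linear"),
    fit_value_curve(tibble::tibble(H = 1:3, K = 1.0 * (1:3)), form = "linear")
  )
  expect_equal(la2$lambda, 2.06)

  sym <- mirrored_line_points(3, 3)
  expect_equal(loss_aversion(fit_value_curve(sym$neg), fit_value_curve(sym$pos))$lambda, 1.0)
  expect_error(loss_aversion(fit_value_curve(sym$pos), fit_value_curve(sym$neg)),
               "avoidance fit")
})

test_that("a flat approach limb yields an infinite lambda that gets flagged", {
  neg <- fit_value_curve(tibble::tibble(H = 1:3, K = -2 * (1:3)), form = "linear")
  pos <- fit_value_curve(tibble::tibble(H = 1:3, K = c(0, 0, 0)),
                         form = "linear", limb = "approach")
  expect_warning(la <- loss_aversion(neg, pos), "infinite")
  expect_equal(la$lambda, Inf)
  expect_true(flag_outliers(c(2, 2.1, 1.9, la$lambda))[4])
})

test_that("lambda is invariant to rescaling K and inverts under limb swap", {
  set.seed(31)
  for (form in c("linear", "power", "quadratic")) {
    h <- c(0.5, 1, 1.5, 2, 2.5)
    kneg <- -(2.2 * h^1.3 + abs(rnorm(5, 0, 0.05)))
    kpos <- 1.4 * h^0.9 + abs(rnorm(5, 0, 0.05))
    lam <- function(kn, kp) {
      loss_aversion(
        fit_value_curve(tibble::tibble(H = h, K = kn), form = form, limb = "avoidance"),
        fit_value_curve(tibble::tibble(H = h, K = kp), form = form, limb = "approach")
      )$lambda
    }
    l0 <- lam(kneg, kpos)
    for (c_scale in c(0.5, 3, 10)) {
      expect_equal(lam(c_scale * kneg, c_scale * kpos), l0, tolerance = 1e-6)
    }
    l_swapped <- lam(-kpos, -kneg)
    expect_equal(l_swapped, 1 / l0, tolerance = 1e-6)
  }
})

test_that("the 2-SD outlier rule flags by cohort mean and sample SD", {
  x <- c(rep(2, 9), 12) # mean 3, sd sqrt(10): only the 12 exceeds 2 SD
  expect_equal(which(flag_outliers(x)), 10L)
  expect_false(any(flag_outliers(rep(5, 6))))
  expect_false(any(flag_outliers(c(1, 1, 1, 1, 10)))) # 1.79 SD deviation
  expect_true(flag_outliers(c(1, 2, 3, NA))[4])
  expect_error(flag_outliers(c(1, 2)), "at least 3")
})

test_that("estimate_loss_aversion fits per subject and skips neutral categories", {
  trials <- dplyr::bind_rows(
    make_trials(c(18L, 20L, 22L), "happy"),
    make_trials(c(-38L, -40L, -42L), "angry", offset = 3L),
    make_trials(c(-39L, -41L, -40L), "sad", offset = 6L),
    make_trials(c(1L, -1L, 0L), "neutral", offset = 9L)
  )
  la <- estimate_loss_aversion(category_valuation(trials))
  expect_equal(nrow(la), 1)
  expect_equal(la$lambda, 2, tolerance = 0.05)
  expect_equal(la$n_minus, 2) # angry + sad; neutral never enters
})

test_that("value-curve tidiers expose parameters and fit summaries", {
  fit <- fit_value_curve(tibble::tibble(H = c(0.5, 1, 2), K = c(1, 2, 4)),
                         form = "linear")
  td <- tidy(fit)
  expect_equal(td$term, "a")
  expect_equal(td$estimate, 2)
  gl <- glance(fit)
  expect_equal(gl$n_points, 3)
  expect_equal(gl$form, "linear")
})
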