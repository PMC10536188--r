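printed_descriptors <- function() {
  tibble::tibble(
    system = c("ISRP", "IAM", "CHOL"),
    logkw = c(0.637, 1.656, 2.361),
    logpcw = 8.995,
    E = 1.46
  )
}

test_that("hydrogen-binding potential reproduces the printed table rows", {
  expect_equal(delta_logp(0.637, 8.995), 8.358)
  expect_equal(delta_logp(1.656, 8.995), 7.339)
  expect_equal(delta_logp(2.361, 8.995), 6.634)
  expect_equal(delta_logp(3.2, 3.2), 0)
  expect_error(delta_logp(NA_real_, 1), "finite")
})

test_that("the built-in model evaluates to the hand-computed logBB values", {
  pred <- predict_logbb(logbb_model(), printed_descriptors())
  expect_equal(pred$logbb_pred, c(-0.4377, -0.0546, 0.2105),
               tolerance = 1e-3)
  # exact hand arithmetic
  expect_equal(pred$logbb_pred[1],
               -0.114 - 0.098 * 8.358 + 0.278 * 0.637 + 0.218 * 1.46,
               tolerance = 1e-12)
  # all-zero descriptors: intercept only
  zero <- tibble::tibble(delta_logp = 0, logkw = 0, E = 0)
  expect_equal(predict_logbb(logbb_model(), zero)$logbb_pred, -0.114)
})

test_that("prediction is exactly linear in the descriptors", {
  d <- gen_qsar_dataset(n = 12, seed = 4)
  pred <- predict_logbb(logbb_model(), d)$logbb_pred
  avg_row <- tibble::tibble(
    delta_logp = mean(d$delta_logp), logkw = mean(d$logkw), E = mean(d$E))
  expect_equal(predict_logbb(logbb_model(), avg_row)$logbb_pred,
               mean(pred), tolerance = 1e-12)
})

test_that("missing descriptors are reported by name", {
  expect_error(predict_logbb(logbb_model(), tibble::tibble(logkw = 1)),
               "delta_logp")
  expect_error(
    predict_logbb(logbb_model(),
                  tibble::tibble(logkw = 1, logpcw = 5)),
    "E")
})

test_that("delta_logp is recomputed from its parents, never free-set", {
  d <- tibble::tibble(logkw = 1, logpcw = 5, delta_logp = 99, E = 1)
  expect_warning(pred <- predict_logbb(logbb_model(), d), "recomputed")
  expect_equal(pred$delta_logp, 4)
})

test_that("noiseless data yield exact coefficient recovery and R^2 = 1", {
  d <- gen_qsar_dataset(n = 20, sigma = 0, seed = 7)
  fit <- suppressWarnings(
    fit_mlr_backward(d, descriptors = c("delta_logp", "logkw", "E")))
  expect_equal(unname(fit$coefficients),
               c(-0.114, -0.098, 0.278, 0.218), tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("degenerate designs are rejected", {
  d <- gen_qsar_dataset(n = 20, seed = 1)
  d$dup <- d$logkw * 2
  expect_error(
    fit_mlr_backward(d, descriptors = c("logkw", "dup", "E")),
    "rank-deficient")
  d$flat <- 1
  expect_error(fit_mlr_backward(d, descriptors = c("logkw", "flat")),
               "constant")
})

test_that("pure-noise responses collapse to an intercept-only model", {
  set.seed(9)
  d <- tibble::tibble(x1 = runif(30), x2 = runif(30), logbb = rnorm(30))
  expect_warning(
    fit <- fit_mlr_backward(d, descriptors = c("x1", "x2")),
    "intercept-only")
  expect_named(fit$coefficients, "(Intercept)")
})

test_that("leave-ten-out CV is exact on noiseless data and matches the oracle", {
  d <- gen_qsar_dataset(n = 40, sigma = 0, seed = 3)
  cv <- cross_validate_lto(d, descriptors = c("delta_logp", "logkw", "E"),
                           seed = 11)
  expect_equal(cv$press, 0, tolerance = 1e-18)
  expect_equal(cv$r2_cv, 1, tolerance = 1e-12)

  noisy <- gen_qsar_dataset(n = 40, seed = 5)
  fold_id <- rep(1:4, each = 10)
  cv2 <- cross_validate_lto(noisy, descriptors = c("delta_logp", "logkw", "E"),
                            fold_id = fold_id)
  expect_equal(cv2$press,
               press_oracle(noisy, "logbb",
                            c("delta_logp", "logkw", "E"), fold_id),
               tolerance = 1e-10)
  expect_equal(cv2$rmsecv, sqrt(cv2$press / 40), tolerance = 1e-12)
})

test_that("cross-validation refuses single-fold problems and warns on ragged folds", {
  d <- gen_qsar_dataset(n = 10, seed = 2)
  expect_error(cross_validate_lto(d), "fold_size")
  d2 <- gen_qsar_dataset(n = 25, seed = 2)
  expect_warning(cross_validate_lto(d2, descriptors = c("logkw", "E")),
                 "smaller")
})

test_that("leverage has the centroid and trace properties and flags outliers", {
  d <- gen_qsar_dataset(n = 40, seed = 13)
  fit <- fit_mlr_backward(d, descriptors = c("delta_logp", "logkw", "E"),
                          alpha_remove = 1)
  centroid <- tibble::tibble(delta_logp = mean(d$delta_logp),
                             logkw = mean(d$logkw), E = mean(d$E))
  expect_equal(applicability_domain(fit, centroid)$leverage, 1 / 40,
               tolerance = 1e-12)
  train_h <- applicability_domain(fit, d)$leverage
  expect_equal(sum(train_h), 4, tolerance = 1e-10)  # p + 1
  far <- tibble::tibble(
    delta_logp = mean(d$delta_logp) + 10 * sd(d$delta_logp),
    logkw = mean(d$logkw) + 10 * sd(d$logkw),
    E = mean(d$E) + 10 * sd(d$E))
  ad <- applicability_domain(fit, far)
  expect_gt(ad$leverage, ad$threshold)
  expect_false(ad$in_domain)
  expect_error(applicability_domain(logbb_model(), centroid),
               "training design")
})

test_that("models serialise to JSON and back without loss", {
  d <- gen_qsar_dataset(n = 40, seed = 17)
  fit <- fit_mlr_backward(d, descriptors = c("delta_logp", "logkw", "E"),
                          alpha_remove = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_qsar_model(fit, path)
  back <- read_qsar_model(path)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$s, fit$s)
  q <- printed_descriptors()
  expect_equal(predict_logbb(back, q)$logbb_pred,
               predict_logbb(fit, q)$logbb_pred, tolerance = 1e-12)
  expect_equal(applicability_domain(back, q)$leverage,
               applicability_domain(fit, q)$leverage, tolerance = 1e-12)
})
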