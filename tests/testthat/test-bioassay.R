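test_that("exact calibration points recover the printed curve parameters", {
  amounts <- c(2, 4, 6, 8, 10)
  pts <- tibble::tibble(amount = amounts,
                        response = 12491 * amounts - 12671)
  cal <- suppressWarnings(fit_linear_calibration(pts))
  expect_equal(cal$slope, 12491)
  expect_equal(cal$intercept, -12671)
  expect_equal(cal$r_squared, 1)
})

test_that("two calibration points always give R^2 = 1", {
  cal <- suppressWarnings(fit_linear_calibration(
    tibble::tibble(amount = c(1, 2), response = c(5, 9))))
  expect_equal(cal$r_squared, 1)
})

test_that("noisy calibration matches the normal-equations oracle", {
  set.seed(8)
  amounts <- 1:6
  resp <- 120 * amounts - 30 + rnorm(6, sd = 4)
  cal <- fit_linear_calibration(tibble::tibble(amount = amounts,
                                               response = resp))
  beta <- ols_oracle(matrix(amounts), resp)
  expect_equal(cal$intercept, beta[1], tolerance = 1e-10)
  expect_equal(cal$slope, beta[2], tolerance = 1e-10)
})

test_that("degenerate calibration input errors", {
  expect_error(fit_linear_calibration(
    tibble::tibble(amount = c(2, 2, 2), response = c(1, 2, 3))),
    "identical")
  expect_error(fit_linear_calibration(
    tibble::tibble(amount = 1, response = 1)), "2 calibration points")
})

test_that("viability percentages follow the blank-corrected form", {
  expect_equal(viability_percent(0.9, 0.9, 0.1), 100)
  expect_equal(viability_percent(0.1, 0.9, 0.1), 0)
  expect_equal(viability_percent(0.55, 0.90, 0.10), 56.25)
  expect_error(viability_percent(0.5, 0.1, 0.2), "exceed")
})

test_that("viability and inhibition sum to exactly 100", {
  set.seed(2)
  od <- runif(20, 0.15, 0.85)
  expect_equal(viability_percent(od, 0.9, 0.1) +
                 inhibition_percent(od, 0.9, 0.1),
               rep(100, 20))
})

test_that("noiseless logistic data recover all four parameters and the midpoint", {
  doses <- c(25, 50, 100, 200, 400, 715, 1200, 2500, 5000, 10000)
  truth <- c(bottom = 10, top = 104, mid = 715, hill = 1.3)
  resp <- truth["bottom"] + (truth["top"] - truth["bottom"]) /
    (1 + (doses / truth["mid"])^truth["hill"])
  fit <- ic50_dose_response(tibble::tibble(dose = doses, viability = resp))
  expect_equal(fit$method, "logistic-4p")
  expect_equal(unname(fit$parameters[names(truth)]), unname(truth),
               tolerance = 1e-6)
  ic50_true <- 715 * ((104 - 50) / (50 - 10))^(1 / 1.3)
  expect_equal(fit$ic50, ic50_true, tolerance = 1e-3)
})

test_that("generator/fit round-trip recovers the midpoint within 0.1%", {
  plate <- gen_mtt_plate(ic50 = 715, hill = 1.2, noise_sd = 0,
                         doses = c(50, 150, 300, 500, 715, 1000, 2000),
                         seed = 1)
  fit <- ic50_dose_response(plate_viability(plate))
  expect_equal(fit$ic50, 715, tolerance = 1e-3)
})

test_that("interpolation between the printed bracketing points gives 727.8", {
  tri <- tibble::tibble(dose = c(100, 300, 1000),
                        viability = c(71.5, 61, 43))
  fit <- ic50_dose_response(tri, method = "interpolation")
  expect_equal(fit$ic50, 300 + (61 - 50) / (61 - 43) * 700,
               tolerance = 1e-12)
  expect_equal(fit$method, "interpolation")
})

test_that("non-bracketing responses are not identifiable", {
  high <- tibble::tibble(dose = c(1, 10, 100), viability = c(95, 88, 72))
  expect_error(ic50_dose_response(high), "not identifiable")
})

test_that("the IC50 rescales with a uniform dose rescaling", {
  plate <- gen_mtt_plate(ic50 = 600, hill = 1.1, noise_sd = 0.004, seed = 6)
  v <- plate_viability(plate)
  fit1 <- ic50_dose_response(v, seed = 2)
  v$dose <- v$dose * 7
  fit2 <- ic50_dose_response(v, seed = 2)
  expect_equal(fit2$ic50 / fit1$ic50, 7, tolerance = 1e-4)
})

test_that("TLC IC50 solves the calibration line and converts units", {
  # y = 2x, reference 100 -> half-reference 50 -> x = 25
  cal <- suppressWarnings(fit_linear_calibration(
    tibble::tibble(amount = c(1, 50), response = c(2, 100))))
  expect_equal(ic50_tlc(cal, reference_response = 100)$amount, 25)

  # algebraic identity: reference = 2 * (slope x0 + intercept) -> x0
  cal2 <- suppressWarnings(fit_linear_calibration(
    tibble::tibble(amount = c(1, 9), response = 12491 * c(1, 9) - 12671)))
  x0 <- 5.3
  ref <- 2 * (cal2$slope * x0 + cal2$intercept)
  expect_equal(ic50_tlc(cal2, ref)$amount, x0, tolerance = 1e-10)

  # constructed conversion record whose answer is 9.22 uM, recovered by
  # the same unit path (round-trip, not a reproduction of the assay)
  target_um <- 9.22
  mw <- 456.7
  zone_ul <- 50
  amount_mg <- target_um * mw * zone_ul / 1e9
  cal3 <- suppressWarnings(fit_linear_calibration(
    tibble::tibble(amount = c(amount_mg / 2, amount_mg * 2),
                   response = c(40, 160))))
  ref3 <- 2 * (cal3$slope * amount_mg + cal3$intercept)
  out <- ic50_tlc(cal3, ref3,
                  conversion = list(molar_mass = mw, zone_volume_ul = zone_ul))
  expect_equal(out$micromolar, target_um, tolerance = 1e-3)
})

test_that("TLC conversion validates its constants and the solved amount", {
  cal <- suppressWarnings(fit_linear_calibration(
    tibble::tibble(amount = c(1, 50), response = c(2, 100))))
  expect_error(ic50_tlc(cal, 100, conversion = list(molar_mass = 456.7)),
               "zone_volume_ul")
  expect_error(
    ic50_tlc(cal, 100,
             conversion = list(molar_mass = 456.7, zone_volume_ul = 50,
                               amount_unit = "uL")),
    "stock_conc_mg_ml")
  # half-reference below the line's positive range
  cal_neg <- suppressWarnings(fit_linear_calibration(
    tibble::tibble(amount = c(1, 2), response = c(1000, 1100))))
  expect_error(ic50_tlc(cal_neg, 100), "non-positive")
})

test_that("plate CSV round-trips through the reader", {
  plate <- gen_mtt_plate(seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(plate, path)
  back <- read_plate_csv(path)
  expect_equal(back$od, plate$od)
  expect_equal(plate_viability(back), plate_viability(plate))
})
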