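# IC50 machinery: linear densitometry calibration for TLC-bioautography
# enzyme-inhibition assays, blank-corrected MTT viability, and dose-response
# IC50 estimation (four-parameter logistic with an interpolation fallback).

#' Fit a linear densitometry calibration curve
#'
#' Ordinary least squares of a densitometric response (peak area) on the
#' applied amount: `response = slope * amount + intercept`. Two points give
#' an exact line (R^2 = 1); an R^2 worth reporting needs at least three.
#'
#' @param data Tibble with the amount and response columns.
#' @param amount_col,response_col Column names (defaults `"amount"`,
#'   `"response"`).
#' @return An object of class `calibration_curve` with `slope`,
#'   `intercept`, `r_squared` and the points.
#' @export
#' @examples
#' pts <- tibble::tibble(amount = 1:4, response = 12491 * (1:4) - 12671)
#' fit_linear_calibration(pts)
fit_linear_calibration <- function(data, amount_col = "amount",
                                   response_col = "response") {
  amount <- pull_col(data, amount_col)
  response <- pull_col(data, response_col)
  if (length(amount) < 2) stop_bbb("need at least 2 calibration points")
  if (length(unique(amount)) == 1) {
    stop_bbb("all calibration amounts are identical; cannot fit a line")
  }
  if (any(amount <= 0)) stop_bbb("calibration amounts must be positive")
  fit <- stats::lm(response ~ amount)
  sm <- summary(fit)
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = sm$r.squared,
      n = length(amount),
      lm_fit = fit,
      points = tibble::tibble(amount = amount, response = response)
    ),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, digits = 6, ...) {
  cat("<calibration_curve>\n")
  cat(sprintf("  y = %.*g x %s %.*g   (n = %d, R^2 = %.4f)\n",
              digits, x$slope, ifelse(x$intercept < 0, "-", "+"),
              digits, abs(x$intercept), x$n, x$r_squared))
  invisible(x)
}

#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n = x$n)
}

#' @export
tidy.calibration_curve <- function(x, ...) {
  sm <- summary(x$lm_fit)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = unname(sm[, "Std. Error"])
  )
}

#' @export
autoplot.calibration_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$amount, .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         linetype = 2) +
    ggplot2::labs(x = "applied amount", y = "peak area") +
    ggplot2::theme_minimal()
}

#' Blank-corrected viability and inhibition percentages
#'
#' `viability = 100 * (OD_treated - OD_blank) / (OD_control - OD_blank)`,
#' the standard blank-corrected form; inhibition is its complement, so the
#' two always sum to exactly 100.
#'
#' @param od_treated,od_control,od_blank Optical densities. `od_control`
#'   must exceed `od_blank`.
#' @return Percentage, vectorised.
#' @export
#' @examples
#' viability_percent(0.55, 0.90, 0.10)  # 56.25
viability_percent <- function(od_treated, od_control, od_blank) {
  check_number(od_treated, "od_treated")
  check_number(od_control, "od_control")
  check_number(od_blank, "od_blank")
  if (any(od_control <= od_blank)) {
    stop_bbb("od_control must exceed od_blank")
  }
  100 * (od_treated - od_blank) / (od_control - od_blank)
}

#' @rdname viability_percent
#' @export
inhibition_percent <- function(od_treated, od_control, od_blank) {
  100 - viability_percent(od_treated, od_control, od_blank)
}

# four-parameter logistic in its decreasing form for viability data:
# r(d) = bottom + (top - bottom) / (1 + (d / mid)^hill)
fpl <- function(dose, bottom, top, mid, hill) {
  bottom + (top - bottom) / (1 + (dose / mid)^hill)
}

#' Estimate an IC50 from a dose-response curve
#'
#' Primary path: least-squares fit of a four-parameter logistic
#' `r(d) = bottom + (top - bottom) / (1 + (d/mid)^hill)` (decreasing in
#' dose for viability responses) by seeded multi-start Levenberg-Marquardt
#' with bounds `bottom` in \[0, 50\] and `top` in \[50, 120\], then the
#' dose at which the fitted curve crosses a response of 50 is solved
#' analytically. Fallback path (used when the logistic fit fails or when
#' `method = "interpolation"`): linear interpolation in concentration
#' between the two adjacent doses bracketing 50%. The method actually used
#' is recorded in the result. Responses must bracket 50% (some above, some
#' below), otherwise the IC50 is not identifiable in the tested range.
#'
#' @param data Tibble of dose-response points.
#' @param dose_col,response_col Column names (defaults `"dose"`,
#'   `"viability"`); the response is a percentage with 100 = untreated.
#' @param method `"logistic"` (4PL with interpolation fallback) or
#'   `"interpolation"`.
#' @param seed Seed for the multi-start jitter.
#' @return An object of class `ic50_fit` with `ic50`, `se`, `method`,
#'   fitted `parameters` and the data.
#' @export
ic50_dose_response <- function(data, dose_col = "dose",
                               response_col = "viability",
                               method = c("logistic", "interpolation"),
                               seed = 1) {
  method <- match.arg(method)
  dose <- pull_col(data, dose_col)
  response <- pull_col(data, response_col)
  if (any(dose <= 0)) stop_bbb("doses must be strictly positive")
  if (any(!is.finite(response))) stop_bbb("responses must be finite")
  ord <- order(dose)
  dose <- dose[ord]; response <- response[ord]
  if (!(any(response > 50) && any(response < 50))) {
    stop_bbb("IC50 not identifiable in tested range: responses do not ",
             "bracket 50%")
  }
  points <- tibble::tibble(dose = dose, response = response)

  interp <- function() {
    above <- which(response[-length(response)] > 50 & response[-1] < 50)
    if (length(above) == 0) {
      # non-monotone ordering; take the closest straddling pair
      above <- which(response > 50)
      below <- which(response < 50)
      i <- max(above[above < max(below)])
      j <- min(below[below > i])
    } else {
      i <- above[1]; j <- i + 1
    }
    d1 <- dose[i]; d2 <- dose[j]; r1 <- response[i]; r2 <- response[j]
    d1 + (r1 - 50) / (r1 - r2) * (d2 - d1)
  }

  if (method == "interpolation") {
    return(structure(
      list(ic50 = interp(), se = NA_real_, method = "interpolation",
           parameters = NULL, data = points),
      class = "ic50_fit"
    ))
  }

  fit <- fit_fpl(dose, response, seed = seed)
  if (is.null(fit)) {
    return(structure(
      list(ic50 = interp(), se = NA_real_, method = "interpolation",
           parameters = NULL, data = points),
      class = "ic50_fit"
    ))
  }
  p <- coef(fit)
  # dose at which the fitted curve equals a response of 50
  ic50 <- unname(p["mid"] * ((p["top"] - 50) / (50 - p["bottom"]))^(1 / p["hill"]))
  se <- tryCatch(fpl_ic50_se(fit), error = function(e) NA_real_)
  structure(
    list(ic50 = ic50, se = se, method = "logistic-4p",
         parameters = p, data = points, nls_fit = fit),
    class = "ic50_fit"
  )
}

# seeded multi-start bounded Levenberg-Marquardt 4PL fit; NULL on failure
fit_fpl <- function(dose, response, seed = 1, n_starts = 8) {
  lower <- c(bottom = 0, top = 50, mid = min(dose) / 100, hill = 0.05)
  upper <- c(bottom = 50, top = 120, mid = max(dose) * 100, hill = 10)
  mid0 <- exp(mean(log(range(dose))))
  starts <- list(c(bottom = 0, top = 100, mid = mid0, hill = 1))
  jitter <- withr::with_seed(seed, {
    purrr::map(seq_len(n_starts - 1), \(i) c(
      bottom = runif(1, 0, 30),
      top = runif(1, 80, 115),
      mid = exp(runif(1, log(min(dose)), log(max(dose)))),
      hill = exp(runif(1, log(0.3), log(4)))
    ))
  })
  best <- NULL
  for (st in c(starts, jitter)) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        response ~ fpl(dose, bottom, top, mid, hill),
        data = data.frame(dose = dose, response = response),
        start = as.list(st), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) return(NULL)
  p <- coef(best$fit)
  if (p["top"] - 50 <= 0 || 50 - p["bottom"] <= 0) return(NULL)
  best$fit
}

# delta-method standard error of the 50%-crossing dose
fpl_ic50_se <- function(fit) {
  p <- coef(fit)
  V <- vcov(fit)
  f <- function(q) {
    unname(q["mid"] * ((q["top"] - 50) / (50 - q["bottom"]))^(1 / q["hill"]))
  }
  eps <- pmax(abs(p), 1e-3) * 1e-6
  grad <- vapply(seq_along(p), function(i) {
    q1 <- p; q2 <- p
    q1[i] <- q1[i] + eps[i]; q2[i] <- q2[i] - eps[i]
    (f(q1) - f(q2)) / (2 * eps[i])
  }, numeric(1))
  sqrt(drop(t(grad) %*% V %*% grad))
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat("<ic50_fit> method:", x$method, "\n")
  if (is.finite(x$se)) {
    cat(sprintf("  IC50 = %.4g +/- %.3g\n", x$ic50, x$se))
  } else {
    cat(sprintf("  IC50 = %.4g\n", x$ic50))
  }
  invisible(x)
}

#' @export
glance.ic50_fit <- function(x, ...) {
  p <- x$parameters
  tibble::tibble(
    ic50 = x$ic50, se = x$se, method = x$method,
    bottom = if (is.null(p)) NA_real_ else unname(p["bottom"]),
    top = if (is.null(p)) NA_real_ else unname(p["top"]),
    mid = if (is.null(p)) NA_real_ else unname(p["mid"]),
    hill = if (is.null(p)) NA_real_ else unname(p["hill"]),
    n = nrow(x$data)
  )
}

#' @export
autoplot.ic50_fit <- function(object, ...) {
  g <- ggplot2::ggplot(object$data, ggplot2::aes(.data$dose, .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 50, linetype = 3) +
    ggplot2::geom_vline(xintercept = object$ic50, linetype = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose", y = "response (%)",
                  title = sprintf("IC50 = %.4g (%s)", object$ic50,
                                  object$method)) +
    ggplot2::theme_minimal()
  if (!is.null(object$parameters)) {
    p <- object$parameters
    grid <- tibble::tibble(
      dose = exp(seq(log(min(object$data$dose)),
                     log(max(object$data$dose)), length.out = 200)))
    grid$response <- fpl(grid$dose, p["bottom"], p["top"], p["mid"], p["hill"])
    g <- g + ggplot2::geom_line(data = grid)
  }
  g
}

#' IC50 from a TLC-bioautography calibration line
#'
#' Solves the applied amount `x` at which the calibration line predicts
#' half of a user-supplied maximal-inhibition reference response
#' (`response = 0.5 * reference_response`), then optionally converts the
#' amount to a molar concentration. The assay itself never defines an
#' absolute 100% point, so the reference response is an explicit input,
#' and every conversion constant (molar mass, stock concentration, zone
#' volume) is an explicit parameter so any unit convention can be
#' reproduced.
#'
#' @param calibration A [fit_linear_calibration()] result.
#' @param reference_response Response corresponding to maximal inhibition;
#'   the IC50 is read at half this value.
#' @param conversion Optional named list with the constants needed to
#'   convert the solved amount to micromolar: `molar_mass` (g/mol) and
#'   `zone_volume_ul` (the volume the applied amount is dissolved in when
#'   expressing molarity, in microlitres); plus, when the calibration
#'   amounts are applied volumes rather than masses,
#'   `stock_conc_mg_ml` and `amount_unit = "uL"`. With `conversion =
#'   NULL` only the amount is returned.
#' @return An object of class `tlc_ic50`: list with `amount` (calibration
#'   amount units), `micromolar` (or `NA` without conversion) and the
#'   inputs.
#' @export
ic50_tlc <- function(calibration, reference_response, conversion = NULL) {
  stopifnot(inherits(calibration, "calibration_curve"))
  check_number(reference_response, "reference_response", positive = TRUE)
  x <- (0.5 * reference_response - calibration$intercept) / calibration$slope
  if (!is.finite(x) || x <= 0) {
    stop_bbb("solved amount is non-positive; the half-reference response ",
             "lies outside the calibrated range")
  }
  micromolar <- NA_real_
  if (!is.null(conversion)) {
    needed <- c("molar_mass", "zone_volume_ul")
    unit <- conversion$amount_unit %||% "mg"
    if (identical(unit, "uL")) needed <- c(needed, "stock_conc_mg_ml")
    missing <- setdiff(needed, names(conversion))
    if (length(missing) > 0) {
      stop_bbb("missing conversion constant(s): ",
               paste(missing, collapse = ", "))
    }
    amount_mg <- if (identical(unit, "uL")) {
      x * conversion$stock_conc_mg_ml / 1000
    } else {
      x
    }
    # mg -> mol -> mol/L in the zone volume -> micromolar
    micromolar <- amount_mg * 1e9 /
      (conversion$molar_mass * conversion$zone_volume_ul)
  }
  structure(
    list(amount = x, micromolar = micromolar,
         reference_response = reference_response,
         conversion = conversion, calibration = calibration),
    class = "tlc_ic50"
  )
}

#' @export
print.tlc_ic50 <- function(x, ...) {
  cat("<tlc_ic50>\n")
  cat(sprintf("  amount at half reference response: %.4g\n", x$amount))
  if (is.finite(x$micromolar)) {
    cat(sprintf("  IC50 = %.4g uM\n", x$micromolar))
  }
  invisible(x)
}

#' Read assay CSV tables
#'
#' `read_plate_csv()` expects microplate columns `well`, `dose`, `od`
#' (control wells: `dose = 0`; blank wells: `dose = NA`).
#' `read_densitometry_csv()` expects `lane`, `amount`, `peak_area`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_plate_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  for (col in c("well", "dose", "od")) pull_col(data, col)
  tibble::as_tibble(data)
}

#' @rdname read_plate_csv
#' @export
read_densitometry_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  for (col in c("lane", "amount", "peak_area")) pull_col(data, col)
  tibble::as_tibble(data)
}

#' Summarise a microplate into per-dose viability
#'
#' Averages the optical density of control (`dose = 0`) and blank
#' (`dose = NA`) wells and converts every treated dose to a mean
#' blank-corrected viability percentage.
#'
#' @param plate Tibble with columns `dose`, `od` (layout of
#'   [read_plate_csv()] / [gen_mtt_plate()]).
#' @return Tibble with columns `dose`, `viability`, `n_wells`.
#' @export
plate_viability <- function(plate) {
  od <- pull_col(plate, "od")
  dose <- pull_col(plate, "dose")
  blank <- mean(od[is.na(dose)])
  control <- mean(od[!is.na(dose) & dose == 0])
  if (!is.finite(blank)) blank <- 0
  if (!is.finite(control)) stop_bbb("plate has no control wells (dose = 0)")
  plate |>
    dplyr::filter(!is.na(.data$dose), .data$dose > 0) |>
    dplyr::group_by(.data$dose) |>
    dplyr::summarise(
      viability = mean(viability_percent(.data$od, control, blank)),
      n_wells = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$dose)
}
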