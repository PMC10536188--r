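# Biomimetic (membrane-like) HPLC lipophilicity: retention factors and the
# Soczewinski-Wachtmeister extrapolation logk = logkw - s * phi, whose
# intercept logkw (retention extrapolated to pure water) is the
# chromatographic lipophilicity descriptor used downstream.

#' Chromatographic retention factor
#'
#' `k = (t_retention - t_dead) / t_dead`, the standard dimensionless
#' retention factor. `log_retention_factor()` returns `log10(k)` and
#' errors when the analyte elutes at the dead time (`k = 0`), where the
#' logarithm is undefined.
#'
#' @param t_retention Retention time, minutes.
#' @param t_dead Column dead time, minutes (from an unretained marker such
#'   as citric acid). Must be positive.
#' @return `retention_factor()`: the retention factor (vectorised);
#'   `log_retention_factor()`: its base-10 logarithm.
#' @export
#' @examples
#' retention_factor(2.0, 1.0)      # 1
#' log_retention_factor(2.0, 1.0)  # 0
retention_factor <- function(t_retention, t_dead) {
  check_number(t_retention, "t_retention")
  check_number(t_dead, "t_dead", positive = TRUE)
  if (any(t_retention < t_dead)) {
    stop_bbb("t_retention < t_dead: analyte elutes before the dead time ",
             "(non-retained); retention factor undefined")
  }
  (t_retention - t_dead) / t_dead
}

#' @rdname retention_factor
#' @export
log_retention_factor <- function(t_retention, t_dead) {
  k <- retention_factor(t_retention, t_dead)
  if (any(k == 0)) {
    stop_bbb("retention factor is 0 (retention time equals dead time); ",
             "log k is undefined")
  }
  log10(k)
}

#' Read a retention table from CSV
#'
#' Expects columns `system`, `phi`, `t_retention`, `t_dead` and optionally
#' `replicate`. The organic-modifier fraction `phi` may be given either as
#' a fraction (0.75) or as a percentage (75); percentages are detected by
#' values above 1 and normalised, with a message recording the
#' interpretation.
#'
#' @param path Path to a CSV file.
#' @param phi_scale `"auto"` (default), `"fraction"` or `"percent"`.
#' @return A tibble.
#' @export
read_retention_csv <- function(path, phi_scale = c("auto", "fraction", "percent")) {
  phi_scale <- match.arg(phi_scale)
  data <- readr::read_csv(path, show_col_types = FALSE)
  for (col in c("system", "phi", "t_retention", "t_dead")) pull_col(data, col)
  if (!"replicate" %in% names(data)) data$replicate <- 1L
  if (phi_scale == "percent" ||
      (phi_scale == "auto" && any(data$phi > 1))) {
    message("interpreting `phi` as percent; dividing by 100")
    data$phi <- data$phi / 100
  }
  if (any(data$phi < 0 | data$phi >= 1)) {
    stop_bbb("phi must lie in [0, 1) after normalisation")
  }
  tibble::as_tibble(data)
}

#' Average replicate injections and compute log retention factors
#'
#' Replicates are aggregated as the arithmetic mean of retention times per
#' (system, phi) before the retention factor is computed, matching the
#' convention of averaging measured times rather than averaging log k.
#' (The two differ only when replicates are unequal.)
#'
#' @param data Tibble with columns `system`, `phi`, `t_retention`,
#'   `t_dead` and optionally `replicate`.
#' @return A tibble with one row per (system, phi) and columns `k`,
#'   `logk`.
#' @export
prepare_retention_series <- function(data) {
  for (col in c("system", "phi", "t_retention", "t_dead")) pull_col(data, col)
  data |>
    dplyr::group_by(.data$system, .data$phi) |>
    dplyr::summarise(
      t_retention = mean(.data$t_retention),
      t_dead = mean(.data$t_dead),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      k = retention_factor(.data$t_retention, .data$t_dead),
      logk = log_retention_factor(.data$t_retention, .data$t_dead)
    ) |>
    dplyr::arrange(.data$system, .data$phi)
}

#' Fit the Soczewinski-Wachtmeister retention relation
#'
#' Ordinary least squares of `logk` on `phi` for one retention series:
#' `logk = logkw - s * phi`. The intercept `logkw` is the lipophilicity
#' descriptor (retention extrapolated to a purely aqueous mobile phase);
#' `s` is reported as the positive slope magnitude of the decreasing line.
#' If retention does not decrease with `phi` the fit is flagged with a
#' warning (retention theory violated) but still returned, with `s`
#' negative.
#'
#' @param data A tibble with columns `phi` and `logk`, or raw columns
#'   `phi`, `t_retention`, `t_dead` (and optionally `replicate`,
#'   `system`), in which case replicates are averaged via
#'   [prepare_retention_series()] first.
#' @param system Optional system label; taken from the data when present.
#' @return An object of class `sw_fit` with components `logkw`, `s`,
#'   `r_squared`, `residual_se`, `n`, `retention_decreasing`, `data`.
#' @export
#' @examples
#' pts <- tibble::tibble(phi = c(0, 1), logk = c(2, 0))
#' fit_sw(pts)  # logkw = 2, s = 2
fit_sw <- function(data, system = NULL) {
  if (!"logk" %in% names(data)) {
    data <- prepare_retention_series(data)
  }
  if (is.null(system)) {
    system <- if ("system" %in% names(data)) {
      sys <- unique(data$system)
      if (length(sys) > 1) {
        stop_bbb("multiple systems in input; fit one at a time or use ",
                 "sw_fit_table()")
      }
      sys
    } else {
      "unknown"
    }
  }
  phi <- pull_col(data, "phi")
  logk <- pull_col(data, "logk")
  if (any(phi < 0 | phi >= 1)) stop_bbb("phi must lie in [0, 1)")
  if (length(unique(phi)) < 2) {
    stop_bbb("need at least 2 distinct phi values to fit the retention line")
  }
  fit <- stats::lm(logk ~ phi)
  slope <- unname(coef(fit)[2])
  logkw <- unname(coef(fit)[1])
  sm <- summary(fit)
  r2 <- sm$r.squared
  resid_se <- if (fit$df.residual > 0) sm$sigma else 0
  decreasing <- slope < 0
  if (!decreasing) {
    warning("retention does not decrease with phi; check the series ",
            "(s reported negative)", call. = FALSE)
  }
  structure(
    list(
      system = system,
      logkw = logkw,
      s = -slope,
      r_squared = r2,
      residual_se = resid_se,
      n = length(phi),
      retention_decreasing = decreasing,
      lm_fit = fit,
      data = tibble::tibble(phi = phi, logk = logk)
    ),
    class = "sw_fit"
  )
}

#' @export
print.sw_fit <- function(x, digits = 3, ...) {
  cat("<sw_fit> system:", x$system, "\n")
  cat(sprintf("  logk = %.*f - %.*f * phi   (n = %d, R^2 = %.*f)\n",
              digits, x$logkw, digits, x$s, x$n, digits, x$r_squared))
  if (!x$retention_decreasing) cat("  ! retention not decreasing with phi\n")
  invisible(x)
}

#' @export
tidy.sw_fit <- function(x, ...) {
  sm <- summary(x$lm_fit)$coefficients
  tibble::tibble(
    term = c("logkw", "s"),
    estimate = c(x$logkw, x$s),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]) * c(1, -1),
    p.value = unname(sm[, "Pr(>|t|)"])
  )
}

#' @export
glance.sw_fit <- function(x, ...) {
  tibble::tibble(
    system = x$system,
    logkw = x$logkw,
    s = x$s,
    r_squared = x$r_squared,
    residual_se = x$residual_se,
    n = x$n,
    retention_decreasing = x$retention_decreasing
  )
}

#' @export
autoplot.sw_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$phi, .data$logk)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$logkw, slope = -object$s,
                         linetype = 2) +
    ggplot2::labs(
      x = expression(phi ~ "(organic-modifier fraction)"),
      y = expression(log ~ italic(k)),
      title = paste0(object$system, ": logkw = ",
                     signif(object$logkw, 4),
                     ", s = ", signif(object$s, 4))
    ) +
    ggplot2::theme_minimal()
}

#' Fit the retention relation for every system in a table
#'
#' Groups the input by `system`, fits [fit_sw()] per group and binds the
#' one-row summaries, giving a table in the conventional (logkw, s, R^2)
#' layout.
#'
#' @inheritParams prepare_retention_series
#' @return A tibble with one row per system.
#' @export
sw_fit_table <- function(data) {
  if (!"logk" %in% names(data)) data <- prepare_retention_series(data)
  pull_col(data, "system")
  data |>
    dplyr::group_by(.data$system) |>
    dplyr::group_split() |>
    purrr::map(\(d) glance(fit_sw(d))) |>
    purrr::list_rbind()
}

#' Write a fitted retention-parameter table to TSV
#'
#' @param table Output of [sw_fit_table()].
#' @param path Output path.
#' @export
write_sw_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}
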