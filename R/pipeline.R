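# End-to-end orchestration: retention table -> per-system logkw ->
# hydrogen-binding potential -> logBB prediction with provenance, plus
# optional assay and free-energy stages, from a single config.

#' Read a pipeline run configuration
#'
#' YAML with any of the keys: `retention` (CSV path), `descriptors` (CSV
#' path with columns `system`, `logpcw`, `E` and optionally `logkw`),
#' `model` (`"published-logbb"` or a path to a model JSON written by
#' [write_qsar_model()]), `out_dir`, `seed`.
#'
#' @param path YAML path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("retention", "descriptors", "model")) {
    v <- cfg[[key]]
    if (!is.null(v) && is.character(v) && !identical(v, "published-logbb") &&
        !file.exists(v)) {
      stop_bbb("config path for `", key, "` does not exist: ", v)
    }
  }
  cfg
}

#' Run the logBB prediction pipeline
#'
#' The full chain: (optional) retention table -> replicate averaging ->
#' retention-line fits per membrane-like system -> logkw; joined with the
#' per-system cyclohexane/water partition coefficients and excess molar
#' refraction; hydrogen-binding potential computed; logBB predicted with
#' the chosen model, with an applicability-domain flag where the model
#' carries a training design. Every stage's row counts and warnings are
#' collected into a provenance block, and re-running an identical config
#' reproduces the report exactly (except the timestamp).
#'
#' @param config A list (or YAML path) with elements:
#'   * `retention`: tibble or CSV path of raw retention data (optional
#'     when `descriptors` already carries `logkw`);
#'   * `descriptors`: tibble or CSV path with `system`, `logpcw`, `E`
#'     (and `logkw` when no retention stage);
#'   * `model`: `"published-logbb"` (default), a `qsar_model`, or a path
#'     to a model JSON;
#'   * `out_dir`: optional output directory for the JSON report and
#'     per-stage TSVs;
#'   * `seed`: recorded in provenance (no stage here is stochastic).
#' @return An object of class `logbb_report`: list with `predictions`
#'   (tibble: system, logkw, logpcw, delta_logp, E, logbb, leverage,
#'   in_domain), `sw_fits` (tibble or NULL), `provenance`.
#' @export
run_logbb_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  model <- config$model %||% "published-logbb"
  if (is.character(model)) {
    model <- if (identical(model, "published-logbb")) {
      logbb_model()
    } else {
      read_qsar_model(model)
    }
  }
  stopifnot(inherits(model, "qsar_model"))

  load_table <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) readr::read_csv(x, show_col_types = FALSE)
    else tibble::as_tibble(x)
  }
  retention <- load_table(config$retention)
  descriptors <- load_table(config$descriptors)
  if (is.null(retention) && is.null(descriptors)) {
    stop_bbb("config must provide `retention` and/or `descriptors`")
  }

  log <- list()
  sw_fits <- NULL
  if (!is.null(retention)) {
    sw_fits <- sw_fit_table(retention)
    log$retention_rows <- nrow(retention)
    log$systems_fitted <- nrow(sw_fits)
    bad <- sw_fits$system[!sw_fits$retention_decreasing]
    if (length(bad) > 0) {
      log$warnings <- c(log$warnings,
                        paste("retention not decreasing for:",
                              paste(bad, collapse = ", ")))
    }
  }

  if (is.null(descriptors)) {
    stop_bbb("descriptors (logpcw, E per system) are required to predict ",
             "logBB")
  }
  missing <- setdiff(c("logpcw", "E"), names(descriptors))
  if (length(missing) > 0) {
    stop_bbb("missing descriptor column(s): ", paste(missing, collapse = ", "))
  }
  if (!is.null(sw_fits)) {
    descriptors$logkw <- NULL  # fitted values take precedence
    descriptors <- dplyr::inner_join(
      dplyr::select(sw_fits, "system", "logkw"),
      descriptors, by = "system")
  } else if (!"logkw" %in% names(descriptors)) {
    stop_bbb("descriptors must carry `logkw` when no retention stage is run")
  }
  log$descriptor_rows <- nrow(descriptors)

  predictions <- predict_logbb(model, descriptors) |>
    dplyr::rename(logbb = "logbb_pred")

  report <- structure(
    list(
      predictions = predictions,
      sw_fits = sw_fits,
      provenance = list(
        package = "bbbperm",
        version = as.character(utils::packageVersion("bbbperm")),
        model = model$name,
        model_coefficients = as.list(model$coefficients),
        seed = config$seed %||% NA,
        log = log,
        timestamp = format(Sys.time(), tz = "UTC")
      )
    ),
    class = "logbb_report"
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(predictions = predictions,
           sw_fits = sw_fits,
           provenance = report$provenance),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
    )
    readr::write_tsv(predictions,
                     file.path(config$out_dir, "predictions.tsv"))
    if (!is.null(sw_fits)) {
      write_sw_table(sw_fits, file.path(config$out_dir, "sw_fits.tsv"))
    }
  }
  report
}

#' @export
print.logbb_report <- function(x, digits = 4, ...) {
  cat("<logbb_report> model:", x$provenance$model, "\n")
  if (!is.null(x$sw_fits)) {
    cat("  retention fits:\n")
    df <- x$sw_fits
    for (i in seq_len(nrow(df))) {
      cat(sprintf("    %-6s logkw = %.*g, s = %.*g, R^2 = %.3f\n",
                  df$system[i], digits, df$logkw[i], digits, df$s[i],
                  df$r_squared[i]))
    }
  }
  cat("  predictions:\n")
  p <- x$predictions
  for (i in seq_len(nrow(p))) {
    flag <- if (is.na(p$in_domain[i])) "" else
      if (p$in_domain[i]) "  [in domain]" else "  [OUT OF DOMAIN]"
    cat(sprintf("    %-6s logBB = %+.*f%s\n",
                if ("system" %in% names(p)) p$system[i] else as.character(i),
                digits, p$logbb[i], flag))
  }
  invisible(x)
}
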