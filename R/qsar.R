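# Blood-brain distribution (logBB) QSAR: descriptor assembly (the
# hydrogen-binding potential delta_logp), prediction with a built-in
# published model, and the full model-building/validation machinery
# (backward-elimination MLR, leave-ten-out cross-validation, leverage-based
# applicability domain).

#' Hydrogen-binding potential
#'
#' `delta_logp = logpcw - logkw`: the difference between the
#' cyclohexane/water partition coefficient and the chromatographic
#' lipophilicity descriptor. Because cyclohexane cannot donate or accept
#' hydrogen bonds while a membrane-like phase can, the difference probes a
#' solute's hydrogen-binding capacity. The published descriptor table
#' prints positive values equal to `logpcw - logkw`, and that arithmetic
#' is what this function implements.
#'
#' @param logkw Chromatographic lipophilicity descriptor (log10 retention
#'   factor extrapolated to water).
#' @param logpcw Cyclohexane/water partition coefficient (log10).
#' @return `logpcw - logkw`, vectorised.
#' @export
#' @examples
#' delta_logp(0.637, 8.995)  # 8.358
delta_logp <- function(logkw, logpcw) {
  check_number(logkw, "logkw")
  check_number(logpcw, "logpcw")
  logpcw - logkw
}

new_qsar_model <- function(coefficients, n_train, r2 = NA_real_,
                           rmse = NA_real_, s = NA_real_, r2_cv = NA_real_,
                           r2_pred = NA_real_, press = NA_real_,
                           rmsecv = NA_real_, training_design = NULL,
                           coef_table = NULL, name = "qsar_model") {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  structure(
    list(
      name = name,
      coefficients = coefficients,
      n_train = n_train,
      r2 = r2, rmse = rmse, s = s,
      r2_cv = r2_cv, r2_pred = r2_pred,
      press = press, rmsecv = rmsecv,
      training_design = training_design,
      coef_table = coef_table
    ),
    class = "qsar_model"
  )
}

#' The built-in published logBB model
#'
#' The multiple-linear-regression model relating blood-brain distribution
#' to the hydrogen-binding potential, the membrane-like lipophilicity
#' descriptor and Abraham's excess molar refraction:
#'
#' `logBB = -0.114 - 0.098 delta_logp + 0.278 logkw + 0.218 E`
#'
#' fitted on 40 chemically diverse compounds with cross-validated
#' R^2 of 78.25%, external-prediction R^2 of 74.02% and residual standard
#' error S = 0.436 log units. The 40-compound literature training set is
#' not redistributed, so this model carries no training design: leverage
#' and applicability-domain flags are unavailable for it (reported `NA`).
#'
#' @return A `qsar_model`.
#' @export
#' @examples
#' predict_logbb(logbb_model(),
#'               tibble::tibble(logkw = 0.637, logpcw = 8.995, E = 1.46))
logbb_model <- function() {
  new_qsar_model(
    coefficients = c(`(Intercept)` = -0.114, delta_logp = -0.098,
                     logkw = 0.278, E = 0.218),
    n_train = 40,
    s = 0.436,
    r2_cv = 0.7825,
    r2_pred = 0.7402,
    name = "published-logbb"
  )
}

#' @export
print.qsar_model <- function(x, digits = 3, ...) {
  cat("<qsar_model>", x$name, "\n")
  co <- x$coefficients
  terms <- setdiff(names(co), "(Intercept)")
  rhs <- paste0(
    signif(co["(Intercept)"], digits),
    paste0(ifelse(co[terms] >= 0, " + ", " - "),
           signif(abs(co[terms]), digits), " ", terms, collapse = "")
  )
  cat("  logBB =", rhs, "\n")
  cat(sprintf("  n = %s", x$n_train))
  for (f in c("r2", "s", "r2_cv", "r2_pred")) {
    if (is.finite(x[[f]])) cat(sprintf(", %s = %.4g", f, x[[f]]))
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.qsar_model <- function(x, ...) {
  if (!is.null(x$coef_table)) return(x$coef_table)
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.qsar_model <- function(x, ...) {
  tibble::tibble(
    name = x$name, n_train = x$n_train, r2 = x$r2, rmse = x$rmse,
    s = x$s, r2_cv = x$r2_cv, r2_pred = x$r2_pred,
    press = x$press, rmsecv = x$rmsecv,
    n_terms = length(x$coefficients)
  )
}

# assemble the descriptor columns a model needs, recomputing delta_logp
# from (logkw, logpcw) whenever possible -- it is a derived quantity and is
# never accepted at face value when its parents are present
assemble_descriptors <- function(model, data) {
  terms <- setdiff(names(model$coefficients), "(Intercept)")
  data <- tibble::as_tibble(data)
  if ("delta_logp" %in% terms) {
    if (all(c("logkw", "logpcw") %in% names(data))) {
      recomputed <- delta_logp(data$logkw, data$logpcw)
      if ("delta_logp" %in% names(data) &&
          any(abs(data$delta_logp - recomputed) > 1e-8)) {
        warn("supplied delta_logp disagrees with logpcw - logkw; using the recomputed value")
      }
      data$delta_logp <- recomputed
    } else if (!"delta_logp" %in% names(data)) {
      stop_bbb("missing descriptor `delta_logp` (supply it, or supply ",
               "`logkw` and `logpcw` so it can be computed)")
    }
  }
  missing <- setdiff(terms, names(data))
  if (length(missing) > 0) {
    stop_bbb("missing descriptor(s): ", paste(missing, collapse = ", "))
  }
  bad <- terms[vapply(terms, \(t) any(!is.finite(data[[t]])), logical(1))]
  if (length(bad) > 0) {
    stop_bbb("non-finite descriptor value(s) in: ", paste(bad, collapse = ", "))
  }
  data
}

#' Predict blood-brain distribution from descriptors
#'
#' Evaluates a linear logBB model on a descriptor table. The
#' hydrogen-binding potential is always recomputed from `logkw` and
#' `logpcw` when both are present. If the model carries its training
#' design, each query also receives a leverage value and an
#' applicability-domain flag (see [applicability_domain()]); the built-in
#' published model carries none, so those columns are `NA` for it.
#'
#' @param model A `qsar_model`, e.g. [logbb_model()] or a fit from
#'   [fit_mlr_backward()].
#' @param data Descriptor table (one row per compound/system) containing
#'   the model's descriptor columns.
#' @return The input tibble with columns `logbb_pred`, `leverage` and
#'   `in_domain` appended.
#' @export
predict_logbb <- function(model, data) {
  stopifnot(inherits(model, "qsar_model"))
  data <- assemble_descriptors(model, data)
  terms <- setdiff(names(model$coefficients), "(Intercept)")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, terms, drop = FALSE]))
  pred <- drop(X %*% model$coefficients[colnames(X)])
  out <- data
  out$logbb_pred <- unname(pred)
  if (!is.null(model$training_design)) {
    ad <- applicability_domain(model, data)
    out$leverage <- ad$leverage
    out$in_domain <- ad$in_domain
  } else {
    out$leverage <- NA_real_
    out$in_domain <- NA
  }
  out
}

#' Fit a logBB model by backward-elimination multiple linear regression
#'
#' Starts from all candidate descriptors and iteratively removes the least
#' significant one (largest partial-t p-value) while that p-value exceeds
#' `alpha_remove`, one variable per iteration, until every retained
#' descriptor is significant. Reports the usual goodness-of-fit measures:
#' R^2, RMSE (root-mean-square residual) and S (residual standard error).
#'
#' @param data Training table containing the response and descriptor
#'   columns.
#' @param response Name of the response column (default `"logbb"`).
#' @param descriptors Character vector of candidate descriptor columns;
#'   defaults to every numeric column except the response.
#' @param alpha_remove Significance level above which a descriptor is
#'   removed (default 0.05).
#' @return A `qsar_model` carrying the retained coefficients, fit
#'   statistics and the retained training design (for leverage).
#' @export
fit_mlr_backward <- function(data, response = "logbb", descriptors = NULL,
                             alpha_remove = 0.05) {
  data <- tibble::as_tibble(data)
  y <- pull_col(data, response, "response column")
  if (is.null(descriptors)) {
    descriptors <- setdiff(
      names(data)[vapply(data, is.numeric, logical(1))], response)
  }
  if (length(descriptors) == 0) stop_bbb("no candidate descriptors")
  n <- nrow(data)
  if (n <= length(descriptors) + 1) {
    stop_bbb("need n > number of candidate descriptors + 1")
  }
  const <- descriptors[vapply(descriptors,
                              \(d) var(data[[d]]) == 0, logical(1))]
  if (length(const) > 0) {
    stop_bbb("constant descriptor column(s): ", paste(const, collapse = ", "))
  }
  X_all <- as.matrix(data[descriptors])
  if (qr(cbind(1, X_all))$rank < ncol(X_all) + 1) {
    stop_bbb("rank-deficient design: descriptors are collinear")
  }

  retained <- descriptors
  repeat {
    fml <- stats::reformulate(if (length(retained)) retained else "1",
                              response = response)
    fit <- stats::lm(fml, data = data)
    if (length(retained) == 0) break
    cm <- summary(fit)$coefficients
    p <- setNames(cm[-1, "Pr(>|t|)"], rownames(cm)[-1])
    worst <- which.max(p)
    if (p[worst] <= alpha_remove) break
    retained <- setdiff(retained, names(p)[worst])
  }
  if (length(retained) == 0) {
    warning("all descriptors eliminated; returning an intercept-only model",
            call. = FALSE)
  }
  sm <- summary(fit)
  res <- stats::residuals(fit)
  ct <- tibble::tibble(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, "Estimate"],
    std.error = sm$coefficients[, "Std. Error"],
    statistic = sm$coefficients[, "t value"],
    p.value = sm$coefficients[, "Pr(>|t|)"]
  )
  new_qsar_model(
    coefficients = coef(fit),
    n_train = n,
    r2 = sm$r.squared,
    rmse = sqrt(mean(res^2)),
    s = sm$sigma,
    training_design = as.matrix(data[retained]),
    coef_table = ct,
    name = "fitted-logbb"
  )
}

#' Leave-ten-out cross-validation
#'
#' Partitions the samples into disjoint folds (default size 10) by seeded
#' random assignment, refits the model specification on each fold's
#' complement and predicts the held-out rows. Reports `PRESS` (the sum of
#' squared cross-validated residuals), `R^2_CV = 1 - PRESS/TSS` and
#' `RMSECV = sqrt(PRESS/n)`. When `n` is not divisible by the fold size
#' the last fold is smaller and a warning is raised. The partition is
#' repeated `n_repeats` times (fresh seeded partitions) and per-repeat
#' statistics are returned alongside their means.
#'
#' @inheritParams fit_mlr_backward
#' @param descriptors Descriptor columns of the model specification to
#'   cross-validate (no re-selection inside folds).
#' @param fold_size Number of samples per fold (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param n_repeats Number of repeated random partitions.
#' @param fold_id Optional explicit fold assignment (integer vector of
#'   length `nrow(data)`); overrides the seeded partition and forces
#'   `n_repeats = 1`.
#' @return An object of class `lto_cv`: a list with elements `press`,
#'   `r2_cv`, `rmsecv` (means over repeats), `repeats` (per-repeat
#'   tibble), `fold_size`, `n`.
#' @export
cross_validate_lto <- function(data, response = "logbb", descriptors = NULL,
                               fold_size = 10, seed = 1, n_repeats = 1,
                               fold_id = NULL) {
  data <- tibble::as_tibble(data)
  y <- pull_col(data, response, "response column")
  n <- nrow(data)
  if (n <= fold_size) {
    stop_bbb("need n > fold_size (", fold_size, ") for cross-validation")
  }
  if (is.null(descriptors)) {
    descriptors <- setdiff(
      names(data)[vapply(data, is.numeric, logical(1))], response)
  }
  if (n %% fold_size != 0) {
    warning("n is not divisible by the fold size; the last fold is smaller",
            call. = FALSE)
  }
  fml <- stats::reformulate(descriptors, response = response)
  tss <- sum((y - mean(y))^2)
  n_folds <- ceiling(n / fold_size)

  one_repeat <- function(assignment) {
    y_hat <- numeric(n)
    for (f in unique(assignment)) {
      hold <- assignment == f
      fit_f <- stats::lm(fml, data = data[!hold, , drop = FALSE])
      y_hat[hold] <- predict(fit_f, newdata = data[hold, , drop = FALSE])
    }
    press <- sum((y - y_hat)^2)
    tibble::tibble(press = press,
                   r2_cv = 1 - press / tss,
                   rmsecv = sqrt(press / n))
  }

  assignments <- if (!is.null(fold_id)) {
    stopifnot(length(fold_id) == n)
    list(fold_id)
  } else {
    purrr::map(seq_len(n_repeats), function(r) {
      withr::with_seed(child_seed(seed, r), {
        sample(rep(seq_len(n_folds), each = fold_size, length.out = n))
      })
    })
  }
  repeats <- purrr::map(assignments, one_repeat) |>
    purrr::list_rbind() |>
    dplyr::mutate(repeat_id = dplyr::row_number(), .before = 1)

  structure(
    list(
      press = mean(repeats$press),
      r2_cv = mean(repeats$r2_cv),
      rmsecv = mean(repeats$rmsecv),
      r2_cv_sd = if (n_repeats > 1) sd(repeats$r2_cv) else NA_real_,
      repeats = repeats,
      fold_size = fold_size,
      n = n
    ),
    class = "lto_cv"
  )
}

#' @export
print.lto_cv <- function(x, ...) {
  cat("<lto_cv> n =", x$n, ", fold size =", x$fold_size,
      ", repeats =", nrow(x$repeats), "\n")
  cat(sprintf("  PRESS = %.4g, R^2_CV = %.4f, RMSECV = %.4g\n",
              x$press, x$r2_cv, x$rmsecv))
  if (is.finite(x$r2_cv_sd)) {
    cat(sprintf("  R^2_CV sd over repeats = %.4g\n", x$r2_cv_sd))
  }
  invisible(x)
}

#' @export
glance.lto_cv <- function(x, ...) {
  tibble::tibble(press = x$press, r2_cv = x$r2_cv, rmsecv = x$rmsecv,
                 r2_cv_sd = x$r2_cv_sd, n = x$n, fold_size = x$fold_size,
                 n_repeats = nrow(x$repeats))
}

#' Leverage-based applicability domain
#'
#' Computes the leverage `h = x (X'X)^-1 x'` of each query against the
#' model's training design (with intercept column) and flags a query as
#' inside the domain when `h <= h* = 3 (p + 1) / n`, the conventional
#' Williams-plot warning threshold. At the training centroid the leverage
#' equals `1/n`, and the training leverages sum to `p + 1` (hat-matrix
#' trace).
#'
#' @param model A `qsar_model` carrying a training design.
#' @param data Query descriptor table.
#' @return A tibble with columns `leverage`, `threshold`, `in_domain`.
#' @export
applicability_domain <- function(model, data) {
  stopifnot(inherits(model, "qsar_model"))
  if (is.null(model$training_design)) {
    stop_bbb("model carries no training design; applicability domain ",
             "cannot be evaluated")
  }
  data <- assemble_descriptors(model, data)
  terms <- colnames(model$training_design)
  X_train <- cbind(1, model$training_design)
  XtX <- crossprod(X_train)
  inv <- tryCatch(solve(XtX), error = function(e) {
    stop_bbb("singular training cross-product; leverage undefined")
  })
  X_q <- cbind(1, as.matrix(data[, terms, drop = FALSE]))
  h <- rowSums((X_q %*% inv) * X_q)
  p1 <- ncol(X_train)
  n <- nrow(X_train)
  h_star <- 3 * p1 / n
  tibble::tibble(leverage = unname(h), threshold = h_star,
                 in_domain = unname(h) <= h_star)
}

#' Serialise a fitted model to JSON / read it back
#'
#' Coefficients, validation statistics and the training design are stored
#' at full precision in a plain-text JSON file.
#'
#' @param model A `qsar_model`.
#' @param path File path.
#' @return `read_qsar_model()` returns a `qsar_model`.
#' @export
write_qsar_model <- function(model, path) {
  stopifnot(inherits(model, "qsar_model"))
  payload <- list(
    name = model$name,
    coefficients = as.list(model$coefficients),
    n_train = model$n_train,
    stats = list(r2 = model$r2, rmse = model$rmse, s = model$s,
                 r2_cv = model$r2_cv, r2_pred = model$r2_pred,
                 press = model$press, rmsecv = model$rmsecv),
    training_design = if (!is.null(model$training_design)) {
      list(columns = colnames(model$training_design),
           rows = unname(apply(model$training_design, 1, as.list,
                               simplify = FALSE)))
    }
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_qsar_model
#' @export
read_qsar_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  td <- NULL
  if (!is.null(p$training_design) && length(p$training_design) > 0) {
    rows <- p$training_design$rows
    td <- if (is.data.frame(rows)) {
      as.matrix(rows)
    } else {
      do.call(rbind, lapply(rows, unlist))
    }
    colnames(td) <- p$training_design$columns
  }
  new_qsar_model(
    coefficients = unlist(p$coefficients),
    n_train = p$n_train,
    r2 = p$stats$r2 %||% NA_real_, rmse = p$stats$rmse %||% NA_real_,
    s = p$stats$s %||% NA_real_, r2_cv = p$stats$r2_cv %||% NA_real_,
    r2_pred = p$stats$r2_pred %||% NA_real_,
    press = p$stats$press %||% NA_real_,
    rmsecv = p$stats$rmsecv %||% NA_real_,
    training_design = td,
    name = p$name %||% "qsar_model"
  )
}
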