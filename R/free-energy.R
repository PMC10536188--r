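# 1D umbrella-sampling free-energy estimation: the weighted histogram
# analysis method (WHAM) over harmonic-bias windows, Bayesian bootstrap of
# whole histograms for per-bin errors, and profile summaries (entry
# barrier, central barrier, immersion free energy) for membrane-permeation
# arguments.

#' Boltzmann constant times temperature
#'
#' kT in kJ/mol at a given temperature; the package default corresponds to
#' 310 K (2.5775 kJ/mol).
#'
#' @param temperature Kelvin.
#' @return kJ/mol.
#' @export
kT_kj_mol <- function(temperature = 310) {
  0.00831446261815324 * temperature
}

#' Construct an umbrella window
#'
#' One biased-sampling window: a harmonic restraint
#' `w(xi) = kappa/2 * (xi - center)^2` and the reaction-coordinate samples
#' collected under it.
#'
#' @param center Restraint centre, nm.
#' @param force_constant Restraint force constant `kappa`,
#'   kJ mol^-1 nm^-2 (>= 0; 0 means unbiased sampling).
#' @param samples Numeric vector of sampled coordinate values, nm.
#' @return An object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, force_constant, samples) {
  check_number(center, "center")
  check_number(force_constant, "force_constant")
  if (force_constant < 0) stop_bbb("force_constant must be >= 0")
  if (length(samples) == 0) stop_bbb("samples must be non-empty")
  check_number(samples, "samples")
  structure(
    list(center = center, force_constant = force_constant,
         samples = as.numeric(samples)),
    class = "umbrella_window"
  )
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("<umbrella_window> center %.3g nm, kappa %.4g kJ/mol/nm^2, %d samples\n",
              x$center, x$force_constant, length(x$samples)))
  invisible(x)
}

#' Read umbrella windows from pull-style text files
#'
#' The metadata file lists one window per line in the conventional WHAM
#' layout: `filename center force_constant` (whitespace separated; lines
#' beginning with `#` skipped). Each sample file is two-column whitespace
#' text (time, coordinate) in the xvg-like dialect, with comment lines
#' beginning with `#` or `@` skipped; the second column is used.
#'
#' @param meta_path Path to the metadata file; sample filenames are
#'   resolved relative to its directory.
#' @return A list of [umbrella_window()] objects.
#' @export
read_umbrella_windows <- function(meta_path) {
  meta_lines <- readLines(meta_path)
  meta_lines <- meta_lines[!grepl("^\\s*(#|$)", meta_lines)]
  if (length(meta_lines) == 0) stop_bbb("empty metadata file")
  base <- dirname(meta_path)
  purrr::map(meta_lines, function(line) {
    fields <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(fields) < 3) {
      stop_bbb("metadata line needs `filename center force_constant`: ", line)
    }
    f <- fields[1]
    path <- if (file.exists(f)) f else file.path(base, f)
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*(#|@|$)", lines)]
    vals <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
    xi <- as.numeric(vals[, 2])
    if (anyNA(xi)) stop_bbb("non-numeric coordinate values in ", path)
    umbrella_window(center = as.numeric(fields[2]),
                    force_constant = as.numeric(fields[3]),
                    samples = xi)
  })
}

#' Write umbrella windows to pull-style text files
#'
#' Inverse of [read_umbrella_windows()]: writes per-window two-column
#' sample files plus a metadata file, so synthetic windows can be fed to
#' any conventional WHAM reader.
#'
#' @param windows List of `umbrella_window` objects.
#' @param dir Output directory (created if needed).
#' @return The metadata file path, invisibly.
#' @export
write_umbrella_windows <- function(windows, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- character(length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    f <- sprintf("window_%03d.dat", i)
    lines <- sprintf("%.6f %.8f",
                     seq_along(w$samples) * 2e-3, w$samples)
    writeLines(c("# time(ns) xi(nm)", lines), file.path(dir, f))
    meta[i] <- sprintf("%s %.8f %.8f", f, w$center, w$force_constant)
  }
  meta_path <- file.path(dir, "metadata.txt")
  writeLines(c("# file center force_constant", meta), meta_path)
  invisible(meta_path)
}

# discard the leading equilibration fraction of each window's samples
discard_equilibration <- function(windows, fraction) {
  purrr::map(windows, function(w) {
    n <- length(w$samples)
    drop <- floor(n * fraction)
    if (drop >= n) stop_bbb("equilibration fraction leaves no samples")
    w$samples <- w$samples[(drop + 1):n]
    w
  })
}

#' Weighted histogram analysis of 1D umbrella windows
#'
#' Combines biased histograms into one unbiased free-energy profile by
#' self-consistent iteration of the WHAM equations: with `n_ij` the count
#' of window `i` in bin `j`, `N_i` the window totals and
#' `w_i(xi_j)` the bias energy at the bin centre,
#'
#' `p_j = sum_i n_ij / sum_i N_i exp((f_i - w_i(xi_j)) / kT)`,
#' `f_i = -kT log sum_j p_j exp(-w_i(xi_j) / kT)`,
#'
#' iterated from `f_i = 0` until the largest window free-energy change
#' falls below the tolerance. The profile is `G = -kT log p`, shifted so
#' its minimum is zero (`min-zero` convention). The first
#' `equilibration_fraction` of each window's samples is discarded as
#' equilibration before binning. Adjacent windows (by centre) must share
#' at least one occupied bin, otherwise the combined profile is anchored
#' on nothing and an error is raised.
#'
#' @param windows List of [umbrella_window()] objects (a single
#'   `umbrella_window` is accepted).
#' @param n_bins Number of uniform bins over the union of sampled ranges
#'   (default 200).
#' @param kT Thermal energy in kJ/mol (default 2.5775, i.e. 310 K).
#' @param tol Convergence tolerance on the window free energies, kJ/mol;
#'   default `1e-6 * kT`.
#' @param max_iter Maximum self-consistency iterations; hitting it flags
#'   the result as unconverged (with a warning) rather than erroring.
#' @param equilibration_fraction Leading fraction of each window's samples
#'   discarded before binning (default 1/8).
#' @param range Optional c(min, max) binning range; defaults to the
#'   sampled range.
#' @return A `free_energy_profile`: tibble with columns `xi` (bin centre,
#'   nm), `g` (kJ/mol, `NA` for unsampled bins) and `n_samples`;
#'   attributes `kT`, `converged`, `iterations`, `reference`,
#'   `bin_width`, `windows_meta`.
#' @export
wham <- function(windows, n_bins = 200, kT = kT_kj_mol(310), tol = NULL,
                 max_iter = 10000, equilibration_fraction = 1/8,
                 range = NULL) {
  if (inherits(windows, "umbrella_window")) windows <- list(windows)
  if (length(windows) == 0) stop_bbb("need at least one window")
  stopifnot(all(vapply(windows, inherits, logical(1), "umbrella_window")))
  check_number(kT, "kT", positive = TRUE)
  tol <- tol %||% (1e-6 * kT)
  windows <- discard_equilibration(windows, equilibration_fraction)

  all_samples <- unlist(purrr::map(windows, "samples"))
  lo <- range[1] %||% min(all_samples)
  hi <- range[2] %||% max(all_samples)
  if (hi <= lo) stop_bbb("degenerate sampling range")
  edges <- seq(lo, hi, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2

  W <- length(windows)
  counts <- matrix(0, nrow = W, ncol = n_bins)
  for (i in seq_len(W)) {
    s <- windows[[i]]$samples
    s <- s[s >= lo & s <= hi]
    idx <- pmin(pmax(findInterval(s, edges, all.inside = TRUE), 1), n_bins)
    counts[i, ] <- tabulate(idx, nbins = n_bins)
  }
  N <- rowSums(counts)

  if (W > 1) {
    ord <- order(vapply(windows, `[[`, numeric(1), "center"))
    occ <- counts > 0
    for (k in seq_len(W - 1)) {
      if (!any(occ[ord[k], ] & occ[ord[k + 1], ])) {
        stop_bbb("insufficient window overlap between windows centred at ",
                 signif(windows[[ord[k]]]$center, 4), " and ",
                 signif(windows[[ord[k + 1]]]$center, 4),
                 " nm (no shared occupied bin)")
      }
    }
  }

  # bias energies at bin centres, in kT units for the exponentials
  bias <- do.call(rbind, purrr::map(windows, function(w) {
    0.5 * w$force_constant * (centers - w$center)^2
  })) / kT
  log_num <- log(colSums(counts))       # -Inf for empty bins
  logN <- log(N)

  f <- rep(0, W)  # window free energies in kT units
  converged <- FALSE
  iterations <- 0L
  for (iter in seq_len(max_iter)) {
    iterations <- iter
    # log p_j = log(sum_i n_ij) - logsumexp_i(log N_i + f_i - bias_ij)
    A <- (logN + f) - bias              # W x n_bins
    m <- apply(A, 2, max)
    log_den <- m + log(colSums(exp(sweep(A, 2, m, "-"))))
    log_p <- log_num - log_den
    # f_i = -log sum_j exp(log p_j - bias_ij)
    B <- sweep(-bias, 2, log_p, "+")
    B[, !is.finite(log_p)] <- -Inf
    mB <- apply(B, 1, max)
    f_new <- -(mB + log(rowSums(exp(B - mB))))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta * kT < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("WHAM did not converge within ", max_iter,
            " iterations (max window shift ", signif(delta * kT, 3),
            " kJ/mol)", call. = FALSE)
  }

  g <- -kT * log_p
  g[!is.finite(log_p)] <- NA_real_
  g <- g - min(g, na.rm = TRUE)

  profile <- tibble::tibble(xi = centers, g = g, n_samples = colSums(counts))
  attr(profile, "kT") <- kT
  attr(profile, "converged") <- converged
  attr(profile, "iterations") <- iterations
  attr(profile, "reference") <- "min-zero"
  attr(profile, "bin_width") <- diff(edges[1:2])
  attr(profile, "windows_meta") <- tibble::tibble(
    center = vapply(windows, `[[`, numeric(1), "center"),
    force_constant = vapply(windows, `[[`, numeric(1), "force_constant"),
    n_samples = N,
    f_kj_mol = f * kT
  )
  class(profile) <- c("free_energy_profile", class(profile))
  profile
}

#' Bayesian bootstrap errors for a WHAM profile
#'
#' Repeats the WHAM solution `n_boot` times with whole-histogram window
#' weights drawn from a flat Dirichlet distribution (complete histograms
#' are reweighted, never individual samples), aligns every replica to the
#' min-zero convention, and reports the per-bin standard deviation.
#'
#' @inheritParams wham
#' @param n_boot Number of bootstrap replicas (>= 2).
#' @param seed Integer seed.
#' @param replicate_seeds Optional vector of per-replica seeds (length
#'   `n_boot`), overriding `seed`-derived ones; identical seeds give
#'   identical replicas.
#' @param ... Passed to [wham()] (`n_bins`, `kT`, `tol`, ...).
#' @return A `free_energy_profile` as from [wham()] on the full data, with
#'   a `g_error` column (kJ/mol) appended.
#' @export
wham_bayesian_bootstrap <- function(windows, n_boot = 20, seed = 1,
                                    replicate_seeds = NULL, ...) {
  if (inherits(windows, "umbrella_window")) windows <- list(windows)
  if (length(windows) < 2) {
    stop_bbb("need at least 2 windows for the Bayesian bootstrap")
  }
  if (n_boot < 2) stop_bbb("n_boot must be at least 2")
  dots <- list(...)
  profile <- do.call(wham, c(list(windows), dots))
  dots$range <- NULL
  lo <- min(profile$xi) - attr(profile, "bin_width") / 2
  hi <- max(profile$xi) + attr(profile, "bin_width") / 2
  W <- length(windows)
  seeds <- replicate_seeds %||%
    vapply(seq_len(n_boot), \(r) child_seed(seed, r), integer(1))
  if (length(seeds) != n_boot) {
    stop_bbb("replicate_seeds must have length n_boot")
  }
  reps <- purrr::map(seeds, function(s) {
    wts <- withr::with_seed(s, rgamma(W, shape = 1))
    wts <- wts / sum(wts) * W
    suppressWarnings(do.call(
      wham_weighted,
      c(list(windows, weights = wts, range = c(lo, hi)), dots)
    ))
  })
  G <- do.call(cbind, reps)
  profile$g_error <- apply(G, 1, function(row) {
    if (all(is.finite(row))) sd(row) else NA_real_
  })
  profile
}

# WHAM with window weights applied to histogram counts and totals; returns
# the min-zero profile g vector on the fixed range
wham_weighted <- function(windows, weights, range, n_bins = 200,
                          kT = kT_kj_mol(310), tol = NULL, max_iter = 10000,
                          equilibration_fraction = 1/8) {
  tol <- tol %||% (1e-6 * kT)
  windows <- discard_equilibration(windows, equilibration_fraction)
  lo <- range[1]; hi <- range[2]
  edges <- seq(lo, hi, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  W <- length(windows)
  counts <- matrix(0, nrow = W, ncol = n_bins)
  for (i in seq_len(W)) {
    s <- windows[[i]]$samples
    s <- s[s >= lo & s <= hi]
    idx <- pmin(pmax(findInterval(s, edges, all.inside = TRUE), 1), n_bins)
    counts[i, ] <- tabulate(idx, nbins = n_bins) * weights[i]
  }
  N <- rowSums(counts)
  bias <- do.call(rbind, purrr::map(windows, function(w) {
    0.5 * w$force_constant * (centers - w$center)^2
  })) / kT
  log_num <- log(colSums(counts))
  logN <- log(N)
  f <- rep(0, W)
  for (iter in seq_len(max_iter)) {
    A <- (logN + f) - bias
    m <- apply(A, 2, max)
    log_den <- m + log(colSums(exp(sweep(A, 2, m, "-"))))
    log_p <- log_num - log_den
    B <- sweep(-bias, 2, log_p, "+")
    B[, !is.finite(log_p)] <- -Inf
    mB <- apply(B, 1, max)
    f_new <- -(mB + log(rowSums(exp(B - mB))))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta * kT < tol) break
  }
  g <- -kT * log_p
  g[!is.finite(log_p)] <- NA_real_
  g - min(g, na.rm = TRUE)
}

#' Summarise a free-energy profile for membrane permeation
#'
#' Three gauge-invariant summaries of a permeation profile:
#'
#' * `immersion_dg` - mean free energy over the bulk region minus the
#'   global minimum: the free-energy release on immersing into the
#'   bilayer (equivalently, the cost of leaving it);
#' * `central_barrier` - maximum within the bilayer-centre region minus
#'   the global minimum: the hump crossed on full immersion;
#' * `entry_barrier` - maximum between the bulk edge and the global
#'   minimum, minus the bulk level; 0 for a monotone descent into the
#'   well.
#'
#' All three are non-negative by construction and invariant to adding a
#' constant to the profile.
#'
#' @param profile A `free_energy_profile` (or any tibble with `xi`, `g`).
#' @param bulk_region Length-2 numeric: the reaction-coordinate interval
#'   taken as bulk solution.
#' @param center_region Length-2 numeric: the interval taken as the
#'   bilayer centre.
#' @return A one-row tibble with `entry_barrier`, `central_barrier`,
#'   `immersion_dg` (kJ/mol).
#' @export
profile_summary <- function(profile, bulk_region, center_region) {
  xi <- pull_col(profile, "xi")
  g <- pull_col(profile, "g")
  ok <- is.finite(g)
  xi <- xi[ok]; g <- g[ok]
  in_bulk <- xi >= bulk_region[1] & xi <= bulk_region[2]
  in_center <- xi >= center_region[1] & xi <= center_region[2]
  if (!any(in_bulk)) stop_bbb("bulk_region contains no profile bins")
  if (!any(in_center)) stop_bbb("center_region contains no profile bins")
  g_min <- min(g)
  i_min <- which.min(g)
  bulk_level <- mean(g[in_bulk])
  # bulk edge: the boundary of the bulk region nearer to the minimum
  edge <- if (xi[i_min] >= bulk_region[2]) bulk_region[2] else bulk_region[1]
  between <- if (xi[i_min] >= edge) {
    xi >= edge & xi <= xi[i_min]
  } else {
    xi >= xi[i_min] & xi <= edge
  }
  entry <- if (any(between)) max(g[between]) - bulk_level else 0
  tibble::tibble(
    entry_barrier = max(0, entry),
    central_barrier = max(g[in_center]) - g_min,
    immersion_dg = bulk_level - g_min
  )
}

#' Write a free-energy profile to TSV
#'
#' Columns `xi`, `g` and, when present, `g_error`.
#'
#' @param profile A `free_energy_profile`.
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, path) {
  keep <- intersect(c("xi", "g", "g_error", "n_samples"), names(profile))
  readr::write_tsv(tibble::as_tibble(profile)[keep], path)
  invisible(path)
}

#' @export
autoplot.free_energy_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  g <- ggplot2::ggplot(df[is.finite(df$g), ], ggplot2::aes(.data$xi, .data$g))
  if ("g_error" %in% names(df)) {
    g <- g + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$g - .data$g_error,
                   ymax = .data$g + .data$g_error),
      alpha = 0.25)
  }
  g + ggplot2::geom_line() +
    ggplot2::labs(x = expression(xi ~ "(nm)"),
                  y = expression(G ~ "(kJ/mol)")) +
    ggplot2::theme_minimal()
}
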