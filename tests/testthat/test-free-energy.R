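kT310 <- kT_kj_mol(310)

test_that("kT matches 310 K in kJ/mol", {
  expect_equal(kT310, 2.5775, tolerance = 1e-4)
})

test_that("window construction validates its fields", {
  expect_error(umbrella_window(0, -5, rnorm(10)), ">= 0")
  expect_error(umbrella_window(0, 100, numeric()), "non-empty")
})

test_that("unbiased uniform sampling gives a flat profile", {
  set.seed(1)
  w <- umbrella_window(0, 0, runif(200000, -1, 1))
  prof <- wham(w, n_bins = 50, kT = kT310)
  g <- prof$g[is.finite(prof$g)]
  # per-bin noise is ~ kT/sqrt(count) ~ 0.04 kJ/mol here
  expect_lt(max(g) - min(g), 0.5)
})

test_that("a biased harmonic window unbiases to the underlying potential", {
  # true potential 0.5 * ku * xi^2 sampled under an extra harmonic bias:
  # exact Gaussian samples with variance kT/(ku + kb)
  ku <- 500; kb <- 1000
  set.seed(2)
  w <- umbrella_window(0, kb, rnorm(200000, 0, sqrt(kT310 / (ku + kb))))
  prof <- wham(w, n_bins = 120, kT = kT310)
  sig <- sqrt(kT310 / (ku + kb))
  sel <- is.finite(prof$g) & abs(prof$xi) <= 2 * sig &
    prof$n_samples >= 25
  ref <- 0.5 * ku * prof$xi[sel]^2
  diffs <- prof$g[sel] - ref
  diffs <- diffs - mean(diffs)  # profiles agree up to a constant
  expect_lt(sqrt(mean(diffs^2)), 0.2)
})

test_that("WHAM is invariant to window order and robust to bin doubling", {
  U <- function(x) 8 * (x^2 - 1)^2
  win <- sample_umbrella(U, centers = seq(-1.8, 1.8, length.out = 12),
                         force_constant = 200, n_steps = 6000,
                         step_size = 0.15, seed = 31)
  rng <- range(unlist(lapply(win, `[[`, "samples")))
  # tight tolerance so the converged solution itself is compared
  prof <- wham(win, n_bins = 100, kT = kT310, range = rng, tol = 1e-11)
  prof_perm <- wham(win[sample(seq_along(win))], n_bins = 100, kT = kT310,
                    range = rng, tol = 1e-11)
  expect_lt(max(abs(prof$g - prof_perm$g), na.rm = TRUE), 1e-6)

  barrier <- function(p) {
    sel <- is.finite(p$g) & p$n_samples >= 25
    xi <- p$xi[sel]; g <- p$g[sel]
    max(g[abs(xi) < 0.5]) - min(g)
  }
  prof2 <- wham(win, n_bins = 200, kT = kT310, range = rng)
  expect_lt(abs(barrier(prof) - barrier(prof2)), 0.3)
})

test_that("non-overlapping windows raise an informative error", {
  set.seed(5)
  w1 <- umbrella_window(-3, 1000, rnorm(2000, -3, 0.05))
  w2 <- umbrella_window(3, 1000, rnorm(2000, 3, 0.05))
  expect_error(wham(list(w1, w2), n_bins = 100), "overlap")
})

test_that("hitting max_iter flags the result unconverged", {
  set.seed(6)
  win <- lapply(seq(-1, 1, length.out = 6), function(c0) {
    umbrella_window(c0, 100, rnorm(2000, c0, sqrt(kT310 / 100)))
  })
  expect_warning(prof <- wham(win, max_iter = 3), "not converge")
  expect_false(attr(prof, "converged"))
})

test_that("degenerate bootstrap replicas give zero error", {
  set.seed(7)
  win <- lapply(c(-0.3, 0, 0.3), function(c0) {
    umbrella_window(c0, 150, rnorm(3000, c0, sqrt(kT310 / 150)))
  })
  prof <- wham_bayesian_bootstrap(win, n_boot = 2,
                                  replicate_seeds = c(42L, 42L),
                                  n_bins = 60)
  expect_equal(max(prof$g_error, na.rm = TRUE), 0)
  expect_error(wham_bayesian_bootstrap(win, n_boot = 1), "at least 2")
  expect_error(wham_bayesian_bootstrap(win[1], n_boot = 5), "2 windows")
})

test_that("bootstrap errors shrink like one over sqrt(sample size)", {
  U <- function(x) 3 * x^2
  mk <- function(n, seed) {
    sample_umbrella(U, centers = seq(-1, 1, length.out = 6),
                    force_constant = 60, n_steps = n, step_size = 0.3,
                    seed = seed)
  }
  sizes <- c(1000, 4000, 16000, 64000)
  errs <- vapply(sizes, function(n) {
    p <- wham_bayesian_bootstrap(mk(n, 11), n_boot = 24, seed = 7,
                                 n_bins = 80)
    mean(p$g_error[is.finite(p$g_error) & p$n_samples >= 25])
  }, numeric(1))
  slope <- unname(coef(lm(log(errs) ~ log(sizes)))[2])
  expect_lt(abs(slope - (-0.5)), 0.15)
})

test_that("bootstrap errors track the spread of independent regenerations", {
  U <- function(x) 3 * x^2
  mk <- function(seed) {
    sample_umbrella(U, centers = seq(-1, 1, length.out = 20),
                    force_constant = 100, n_steps = 3000, step_size = 0.5,
                    seed = seed)
  }
  pb <- wham_bayesian_bootstrap(mk(43), n_boot = 30, seed = 23, n_bins = 80)
  rng <- range(pb$xi) + c(-1, 1) * attr(pb, "bin_width") / 2
  regen <- vapply(1:20, function(r) {
    wham(mk(23000 + r), n_bins = 80, range = rng)$g
  }, numeric(80))
  sd_regen <- apply(regen, 1, sd)
  sel <- is.finite(pb$g_error) & is.finite(sd_regen) & pb$n_samples >= 25
  ratio <- mean(pb$g_error[sel]) / mean(sd_regen[sel])
  expect_gt(ratio, 0.7)
  expect_lt(ratio, 1.3)
})

test_that("profile summaries reproduce hand arithmetic and are gauge invariant", {
  flat <- tibble::tibble(xi = seq(-5, 5, length.out = 101), g = 0)
  s0 <- profile_summary(flat, bulk_region = c(4, 5),
                        center_region = c(-0.5, 0.5))
  expect_equal(s0$entry_barrier, 0)
  expect_equal(s0$central_barrier, 0)
  expect_equal(s0$immersion_dg, 0)

  # piecewise membrane-like shape: bulk 0, wells -43, central hump -30
  xi <- seq(-5, 5, by = 0.05)
  g <- numeric(length(xi))
  g[abs(xi) <= 3] <- -43 * pmin(1, 3 - abs(xi[abs(xi) <= 3]))
  g[abs(xi) <= 0.5] <- -43 + 13 * (1 - (abs(xi[abs(xi) <= 0.5]) / 0.5)^2)
  prof <- tibble::tibble(xi = xi, g = g)
  s1 <- profile_summary(prof, bulk_region = c(4, 5),
                        center_region = c(-0.5, 0.5))
  expect_equal(s1$immersion_dg, 43)
  expect_equal(s1$central_barrier, 13)
  expect_equal(s1$entry_barrier, 0)  # monotone descent into the well

  prof$g <- prof$g + 17.3
  s2 <- profile_summary(prof, bulk_region = c(4, 5),
                        center_region = c(-0.5, 0.5))
  expect_equal(s2, s1)

  expect_error(profile_summary(prof, bulk_region = c(40, 50),
                               center_region = c(-0.5, 0.5)), "bulk")
})

test_that("an entry barrier above bulk level is detected", {
  xi <- seq(0, 5, by = 0.1)
  g <- rep(0, length(xi))
  g[xi <= 1] <- -20
  g[xi > 1.9 & xi <= 2.1] <- 4   # hump between bulk and the well
  prof <- tibble::tibble(xi = xi, g = g)
  s <- profile_summary(prof, bulk_region = c(4, 5),
                       center_region = c(0, 0.5))
  expect_equal(s$entry_barrier, 4)
  expect_equal(s$immersion_dg, 20)
})

test_that("window files round-trip through the pull-style reader", {
  set.seed(9)
  win <- lapply(c(-0.4, 0, 0.4), function(c0) {
    umbrella_window(c0, 250, rnorm(1500, c0, sqrt(kT310 / 250)))
  })
  dir <- withr::local_tempdir()
  meta <- write_umbrella_windows(win, dir)
  back <- read_umbrella_windows(meta)
  expect_length(back, 3)
  expect_equal(back[[2]]$center, 0)
  expect_equal(back[[2]]$force_constant, 250)
  expect_equal(back[[2]]$samples, win[[2]]$samples, tolerance = 1e-7)
  prof <- wham(back, n_bins = 50)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(prof, path)
  got <- readr::read_tsv(path, show_col_types = FALSE)
  expect_named(got, c("xi", "g", "n_samples"))
})
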