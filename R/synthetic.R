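# Seeded synthetic-data generators. Every generator is a pure function of
# its arguments (seed included): identical calls give identical output.
# Defaults mirror the printed study conditions (retention parameters per
# membrane-like system, the published logBB coefficient structure with
# residual scale 0.436, the printed viability anchors, and the 40-window
# umbrella layout).

#' Generate a synthetic retention table
#'
#' Draws `logk = logkw - s * phi + N(0, noise_sd)` per replicate and emits
#' the consistent raw chromatographic observables
#' (`t_retention = t_dead * (1 + k)`), in the exact layout
#' [read_retention_csv()] and [sw_fit_table()] consume. Defaults are the
#' printed IAM-system parameters; see
#' [retention_reference_parameters()] for all three systems. The default
#' noise (0.017 log units per injection) makes triplicate-averaged fits
#' come out near R^2 = 0.99, matching the reported fit quality.
#'
#' @param logkw,s True intercept and slope magnitude.
#' @param phis Organic-modifier fractions to measure at.
#' @param noise_sd Per-injection noise on log k (log10 units).
#' @param n_replicates Injections per composition.
#' @param t_dead Dead time, minutes.
#' @param system System label.
#' @param seed Integer seed.
#' @return A tibble with columns `system`, `phi`, `replicate`,
#'   `t_retention`, `t_dead`.
#' @export
gen_retention_table <- function(logkw = 1.656, s = 1.515,
                                phis = c(0.75, 0.80, 0.85, 0.90),
                                noise_sd = 0.017, n_replicates = 3,
                                t_dead = 1.10, system = "IAM", seed = 1) {
  if (length(phis) == 0) stop_bbb("phis must be non-empty")
  if (noise_sd < 0) stop_bbb("noise_sd must be >= 0")
  check_number(t_dead, "t_dead", positive = TRUE)
  grid <- tidyr::expand_grid(phi = phis, replicate = seq_len(n_replicates))
  logk <- withr::with_seed(seed, {
    logkw - s * grid$phi + rnorm(nrow(grid), sd = noise_sd)
  })
  tibble::tibble(
    system = system,
    phi = grid$phi,
    replicate = grid$replicate,
    t_retention = t_dead * (1 + 10^logk),
    t_dead = t_dead
  )
}

#' Generate a synthetic logBB training set
#'
#' Descriptors drawn uniformly over stated ranges, response generated from
#' a linear model plus Gaussian noise. Defaults reproduce the published
#' model's structure: 40 compounds, coefficients (-0.114, -0.098, 0.278,
#' 0.218) on (1, delta_logp, logkw, E) and residual scale 0.436 log units.
#' `delta_logp` is emitted both directly and through its parents (`logkw`,
#' `logpcw`), keeping the derived-descriptor invariant intact.
#'
#' @param n Number of compounds.
#' @param coefficients Named numeric: `intercept`, `delta_logp`, `logkw`,
#'   `E`.
#' @param sigma Residual standard deviation of the response.
#' @param ranges Named list of length-2 ranges for `logkw`, `logpcw`, `E`.
#' @param include_null Add a pure-noise descriptor column
#'   (`null_descriptor`) with true coefficient 0, for elimination tests.
#' @param seed Integer seed.
#' @return A tibble with columns `compound`, `logkw`, `logpcw`,
#'   `delta_logp`, `E` (optionally `null_descriptor`) and `logbb`.
#' @export
gen_qsar_dataset <- function(n = 40,
                             coefficients = c(intercept = -0.114,
                                              delta_logp = -0.098,
                                              logkw = 0.278, E = 0.218),
                             sigma = 0.436,
                             ranges = list(logkw = c(-1, 3),
                                           logpcw = c(2, 10),
                                           E = c(0, 3.5)),
                             include_null = FALSE, seed = 1) {
  if (n <= length(coefficients)) {
    stop_bbb("need n > number of model terms")
  }
  if (sigma < 0) stop_bbb("sigma must be >= 0")
  for (r in names(ranges)) {
    if (diff(range(ranges[[r]])) <= 0) {
      stop_bbb("degenerate range for ", r)
    }
  }
  withr::with_seed(seed, {
    logkw <- runif(n, ranges$logkw[1], ranges$logkw[2])
    logpcw <- runif(n, ranges$logpcw[1], ranges$logpcw[2])
    E <- runif(n, ranges$E[1], ranges$E[2])
    dlp <- delta_logp(logkw, logpcw)
    logbb <- coefficients[["intercept"]] +
      coefficients[["delta_logp"]] * dlp +
      coefficients[["logkw"]] * logkw +
      coefficients[["E"]] * E +
      rnorm(n, sd = sigma)
    out <- tibble::tibble(
      compound = sprintf("cmpd_%02d", seq_len(n)),
      logkw = logkw, logpcw = logpcw, delta_logp = dlp, E = E,
      logbb = logbb
    )
    if (include_null) {
      out$null_descriptor <- runif(n, -1, 1)
      out <- dplyr::relocate(out, "null_descriptor", .before = "logbb")
    }
    out
  })
}

#' Default MTT dose-response parameters from the printed anchors
#'
#' Least-squares fit of a two-parameter logistic (top fixed at 100%,
#' bottom at 0%) through the three printed viability anchors
#' ([viability_anchors()]). These are the default `ic50`/`hill` of
#' [gen_mtt_plate()]; the generated viabilities at the anchor doses fall
#' within 3 percentage points of the printed values.
#'
#' @return Named numeric vector with `ic50` (ug/mL) and `hill`.
#' @export
mtt_anchor_parameters <- function() {
  anchors <- viability_anchors()
  # log-linear solve as starting values, then least squares on viability
  y <- log(100 / anchors$viability - 1)
  x <- log(anchors$dose)
  f <- stats::lm(y ~ x)
  hill0 <- unname(coef(f)[2])
  mid0 <- exp(-unname(coef(f)[1]) / hill0)
  fit <- stats::nls(viability ~ 100 / (1 + (dose / ic50)^hill),
                    data = anchors,
                    start = list(ic50 = mid0, hill = hill0))
  c(ic50 = unname(coef(fit)["ic50"]), hill = unname(coef(fit)["hill"]))
}

#' Generate a synthetic MTT microplate
#'
#' Viabilities follow a four-parameter logistic at the stated dose grid;
#' optical densities are reconstructed through the blank/control scale
#' with Gaussian OD noise. The plate layout matches [read_plate_csv()]:
#' control wells carry `dose = 0`, blank wells `dose = NA`. The default
#' midpoint and Hill slope come from [mtt_anchor_parameters()].
#'
#' @param ic50,hill Logistic midpoint (ug/mL) and slope; defaults
#'   calibrated against the printed viability anchors.
#' @param top,bottom Upper/lower viability asymptotes (%).
#' @param doses Dose grid, ug/mL; all positive.
#' @param noise_sd OD noise standard deviation.
#' @param od_control,od_blank Mean control and blank optical densities.
#' @param n_replicates Wells per dose (also applied to control/blank).
#' @param seed Integer seed.
#' @return A tibble with columns `well`, `dose`, `od`.
#' @export
gen_mtt_plate <- function(ic50 = NULL, hill = NULL, top = 100, bottom = 0,
                          doses = c(100, 200, 300, 500, 700, 1000),
                          noise_sd = 0.01, od_control = 0.9, od_blank = 0.1,
                          n_replicates = 4, seed = 1) {
  if (any(doses <= 0)) stop_bbb("doses must be strictly positive")
  if (noise_sd < 0) stop_bbb("noise_sd must be >= 0")
  if (od_control <= od_blank) stop_bbb("od_control must exceed od_blank")
  defaults <- if (is.null(ic50) || is.null(hill)) mtt_anchor_parameters()
  ic50 <- ic50 %||% unname(defaults["ic50"])
  hill <- hill %||% unname(defaults["hill"])
  check_number(ic50, "ic50", positive = TRUE)

  grid <- tidyr::expand_grid(dose = sort(doses),
                             replicate = seq_len(n_replicates))
  viability <- fpl(grid$dose, bottom, top, ic50, hill)
  od_true <- od_blank + (od_control - od_blank) * viability / 100
  rows <- dplyr::bind_rows(
    tibble::tibble(kind = "treated", dose = grid$dose, od_true = od_true),
    tibble::tibble(kind = "control", dose = 0,
                   od_true = rep(od_control, n_replicates)),
    tibble::tibble(kind = "blank", dose = NA_real_,
                   od_true = rep(od_blank, n_replicates))
  )
  od <- withr::with_seed(seed, rows$od_true + rnorm(nrow(rows), sd = noise_sd))
  tibble::tibble(
    well = sprintf("W%02d", seq_len(nrow(rows))),
    dose = rows$dose,
    od = od
  )
}

#' Membrane-like permeation potential
#'
#' A smooth 1D potential shaped like a permeation free-energy profile
#' through a lipid bilayer: zero in bulk solution, two symmetric wells of
#' roughly `-well_depth` at the headgroup regions (`+/- well_position`)
#' and a local hump at the bilayer centre sitting `barrier_height` above
#' the wells but still below bulk. Built from three Gaussians whose
#' amplitudes are solved linearly so the well and centre levels match the
#' requested values (exact at those two points up to the neglected far
#' tails). Defaults follow the reported phosphatidylcholine-bilayer
#' narrative: ~43 kJ/mol immersion free energy and a 12-17 kJ/mol central
#' hump (midpoint 15).
#'
#' @param well_depth Depth of the headgroup wells below bulk, kJ/mol.
#' @param barrier_height Height of the central hump above the wells,
#'   kJ/mol (must not exceed `well_depth`).
#' @param well_position Well centre distance from the bilayer midplane,
#'   nm.
#' @param well_width,core_width Gaussian widths (nm) of the wells and the
#'   central feature.
#' @return A vectorised function `U(xi)` returning kJ/mol.
#' @export
#' @examples
#' U <- membrane_potential()
#' U(c(-5, -1.7, 0, 1.7, 5))
membrane_potential <- function(well_depth = 43, barrier_height = 15,
                               well_position = 1.7, well_width = 0.6,
                               core_width = 0.5) {
  check_number(well_depth, "well_depth", positive = TRUE)
  if (barrier_height < 0 || barrier_height > well_depth) {
    stop_bbb("barrier_height must lie in [0, well_depth]")
  }
  g <- function(x, s) exp(-x^2 / (2 * s^2))
  c0 <- well_position
  # solve amplitudes A (side wells), B (central) so that
  # U(c0) = -well_depth and U(0) = -(well_depth - barrier_height)
  m <- rbind(
    c(1 + g(2 * c0, well_width), g(c0, core_width)),
    c(2 * g(c0, well_width), 1)
  )
  ab <- solve(m, c(well_depth, well_depth - barrier_height))
  A <- ab[1]; B <- ab[2]
  function(xi) {
    -A * (g(xi - c0, well_width) + g(xi + c0, well_width)) -
      B * g(xi, core_width)
  }
}

#' Sample umbrella windows by Metropolis Monte Carlo
#'
#' For each window centre, runs a Metropolis chain in the biased potential
#' `U(xi) + kappa/2 (xi - center)^2` at thermal energy `kT`, exactly the
#' sampling a molecular-dynamics umbrella run emulates on this 1D
#' coordinate. Chains start at the window centre; an optional burn-in is
#' discarded here, and the WHAM step discards its own leading
#' equilibration fraction by default. Per-window acceptance rates are
#' recorded; an acceptance below 1% raises an error advising a step-size
#' change. Defaults mirror the reported umbrella layout: 40 windows
#' spanning -5..5 nm with a 1000 kJ mol^-1 nm^-2 restraint at 310 K.
#'
#' @param potential A vectorised function `U(xi)` in kJ/mol, e.g.
#'   [membrane_potential()], or `NULL` for a flat potential.
#' @param centers Window centres, nm.
#' @param force_constant Restraint force constant, kJ mol^-1 nm^-2.
#' @param n_steps Steps per window (>= 1000).
#' @param kT Thermal energy, kJ/mol.
#' @param step_size Proposal standard deviation, nm; default
#'   `2 * sqrt(kT / force_constant)` (or 0.5 nm when unrestrained).
#' @param burn_in Leading steps to discard per window.
#' @param domain Optional c(min, max) hard walls on the coordinate.
#' @param seed Integer seed.
#' @return A list of [umbrella_window()] objects; per-window acceptance
#'   rates in `attr(, "acceptance")`.
#' @export
sample_umbrella <- function(potential = membrane_potential(),
                            centers = seq(-5, 5, length.out = 40),
                            force_constant = 1000, n_steps = 5000,
                            kT = kT_kj_mol(310), step_size = NULL,
                            burn_in = 0, domain = c(-Inf, Inf), seed = 1) {
  if (n_steps < 1000) stop_bbb("n_steps must be at least 1000")
  if (force_constant < 0) stop_bbb("force_constant must be >= 0")
  U <- potential %||% function(xi) rep(0, length(xi))
  step_size <- step_size %||%
    if (force_constant > 0) 2 * sqrt(kT / force_constant) else 0.5

  windows <- vector("list", length(centers))
  acceptance <- numeric(length(centers))
  for (i in seq_along(centers)) {
    c_i <- centers[i]
    res <- withr::with_seed(child_seed(seed, i), {
      metropolis_chain(U, c_i, force_constant, n_steps, kT, step_size,
                       domain)
    })
    acceptance[i] <- res$acceptance
    if (res$acceptance < 0.01) {
      stop_bbb("Metropolis acceptance ", signif(res$acceptance * 100, 2),
               "% in window at ", signif(c_i, 3),
               " nm; decrease step_size")
    }
    samples <- res$chain
    if (burn_in > 0) {
      if (burn_in >= length(samples)) stop_bbb("burn_in >= n_steps")
      samples <- samples[-seq_len(burn_in)]
    }
    windows[[i]] <- umbrella_window(c_i, force_constant, samples)
  }
  attr(windows, "acceptance") <- acceptance
  windows
}

# one Metropolis chain in U + harmonic bias; returns chain and acceptance
metropolis_chain <- function(U, center, kappa, n_steps, kT, step_size,
                             domain) {
  energy <- function(x) U(x) + 0.5 * kappa * (x - center)^2
  x <- if (kappa > 0) center else mean(pmax(pmin(domain, 1e3), -1e3))
  if (x < domain[1] || x > domain[2]) x <- mean(domain)
  e <- energy(x)
  chain <- numeric(n_steps)
  steps <- rnorm(n_steps, sd = step_size)
  us <- runif(n_steps)
  accepted <- 0L
  for (t in seq_len(n_steps)) {
    prop <- x + steps[t]
    if (prop >= domain[1] && prop <= domain[2]) {
      e_prop <- energy(prop)
      if (e_prop <= e || us[t] < exp((e - e_prop) / kT)) {
        x <- prop
        e <- e_prop
        accepted <- accepted + 1L
      }
    }
    chain[t] <- x
  }
  list(chain = chain, acceptance = accepted / n_steps)
}

#' Generate a synthetic ligand-protein complex in PDB format
#'
#' Emits valid ATOM/HETATM text for controlled contact-analysis fixtures:
#'
#' * `kind = "cage"`: an aliphatic ring ligand (residue `LIG`) surrounded
#'   by aromatic side-chain rings (Phe by default) placed so the nearest
#'   ring atom sits at exactly `ring_distance` nm from the nearest ligand
#'   carbon, qualitatively mirroring an aromatic cage around an aliphatic
#'   core; plus a serine whose hydroxyl O sits `ser_distance` nm from the
#'   ligand hydroxyl O, and a remote control residue outside any cutoff.
#' * `kind = "probe_pair"`: two atoms at an exact distance, for boundary
#'   checks.
#'
#' @param kind Fixture kind.
#' @param n_aromatic Number of cage residues.
#' @param ring_distance Nearest aromatic-carbon distance, nm.
#' @param ser_distance Serine O to ligand O distance, nm.
#' @param aromatic_residue Cage residue name (`PHE`, `TYR`, `TRP`, `HIS`
#'   use their ring templates).
#' @param distance Probe-pair distance, nm.
#' @param elements,atom_names,residues Probe-pair atom descriptions
#'   (length 2).
#' @return Character vector of PDB lines.
#' @export
gen_toy_complex <- function(kind = c("cage", "probe_pair"),
                            n_aromatic = 4, ring_distance = 0.35,
                            ser_distance = 0.30,
                            aromatic_residue = "PHE",
                            distance = 0.38,
                            elements = c("C", "C"),
                            atom_names = c("C1", "CB"),
                            residues = c("LIG", "ALA")) {
  kind <- match.arg(kind)
  if (kind == "probe_pair") {
    if (distance < 0.05) {
      stop_bbb("generated geometry has overlapping atoms (min distance ",
               signif(distance, 3), " nm)")
    }
    atoms <- tibble::tibble(
      record = c("HETATM", "ATOM"),
      serial = 1:2,
      atom_name = atom_names,
      residue_name = residues,
      chain = c("A", "A"),
      residue_number = c(1L, 2L),
      x = c(0, distance), y = 0, z = 0,
      element = elements
    )
    return(format_pdb(atoms))
  }

  lig_r <- 0.154  # C-C bond length, nm
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  lig <- tibble::tibble(
    record = "HETATM",
    atom_name = sprintf("C%d", 1:6),
    residue_name = "LIG", chain = "A", residue_number = 1L,
    x = lig_r * cos(ang), y = lig_r * sin(ang), z = 0,
    element = "C"
  )
  # hydroxyl oxygen on ring carbon 1, pointing outward along +x
  lig <- dplyr::bind_rows(lig, tibble::tibble(
    record = "HETATM", atom_name = "O1", residue_name = "LIG",
    chain = "A", residue_number = 1L,
    x = lig_r + 0.143, y = 0, z = 0, element = "O"
  ))

  ring_tbl <- aromatic_ring_atoms()
  ring_names <- ring_tbl$atom_name[ring_tbl$residue == aromatic_residue]
  if (length(ring_names) == 0) {
    stop_bbb("no packaged ring template for residue ", aromatic_residue)
  }
  n_ring <- length(ring_names)
  prot <- list()
  resno <- 10L
  # cage residues above/below plus flanking, each ring face-on: nearest
  # ring vertex placed exactly ring_distance from the nearest ligand atom
  azimuths <- seq(0, 2 * pi, length.out = n_aromatic + 1)[-(n_aromatic + 1)]
  elevations <- rep(c(0.35, -0.35), length.out = n_aromatic)
  for (j in seq_len(n_aromatic)) {
    u <- c(cos(azimuths[j]), sin(azimuths[j]), 0)
    u3 <- u + c(0, 0, elevations[j])
    u3 <- u3 / sqrt(sum(u3^2))
    # nearest ligand heavy atom along that direction
    lig_xyz <- as.matrix(lig[, c("x", "y", "z")])
    proj <- lig_xyz %*% u3
    near <- lig_xyz[which.max(proj), ]
    v0 <- near + ring_distance * u3          # nearest ring vertex
    centre <- v0 + 0.139 * u3                # aromatic ring radius
    # ring plane orthogonal to u3
    ref <- if (abs(u3[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- ref - sum(ref * u3) * u3; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u3[2] * e1[3] - u3[3] * e1[2],
            u3[3] * e1[1] - u3[1] * e1[3],
            u3[1] * e1[2] - u3[2] * e1[1])
    th <- seq(0, 2 * pi, length.out = n_ring + 1)[-(n_ring + 1)]
    # rotate so one vertex points back toward the ligand (at -u3)
    pts <- t(vapply(th, function(a) {
      centre + 0.139 * (cos(a) * (-u3) + sin(a) * e1 * 0 + sin(a) * e2)
    }, numeric(3)))
    prot[[length(prot) + 1]] <- tibble::tibble(
      record = "ATOM",
      atom_name = ring_names,
      residue_name = aromatic_residue, chain = "A",
      residue_number = resno,
      x = pts[, 1], y = pts[, 2], z = pts[, 3],
      element = substr(ring_names, 1, 1)
    )
    resno <- resno + 1L
  }
  # serine: OG near the ligand hydroxyl oxygen, backbone further out
  oset <- c(lig_r + 0.143 + ser_distance, 0, 0)
  prot[[length(prot) + 1]] <- tibble::tibble(
    record = "ATOM",
    atom_name = c("OG", "CB", "CA", "N", "C", "O"),
    residue_name = "SER", chain = "A", residue_number = resno,
    x = oset[1] + c(0, 0.143, 0.25, 0.35, 0.32, 0.40),
    y = c(0, 0.05, -0.05, 0.05, -0.15, -0.20),
    z = c(0, 0, 0.05, 0.1, 0.05, 0.1),
    element = c("O", "C", "C", "N", "C", "O")
  )
  resno <- resno + 1L
  # remote control residue, far outside any sensible cutoff
  prot[[length(prot) + 1]] <- tibble::tibble(
    record = "ATOM",
    atom_name = c("N", "CA", "C", "O", "CB"),
    residue_name = "ALA", chain = "A", residue_number = resno,
    x = 2.0 + c(0, 0.1, 0.2, 0.3, 0.1),
    y = 2.0 + c(0, 0.1, 0, 0.1, 0.2),
    z = 0,
    element = c("N", "C", "C", "O", "C")
  )
  atoms <- dplyr::bind_rows(c(list(lig), prot))
  atoms$serial <- seq_len(nrow(atoms))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dmin <- min(stats::dist(xyz))
  if (dmin < 0.05) {
    stop_bbb("generated geometry has overlapping atoms (min distance ",
             signif(dmin, 3), " nm)")
  }
  format_pdb(atoms)
}

# fixed-width PDB ATOM/HETATM formatting; coordinates nm -> Angstrom,
# element right-justified in columns 77-78
format_pdb <- function(atoms) {
  name_field <- ifelse(nchar(atoms$atom_name) < 4,
                       sprintf(" %-3s", atoms$atom_name),
                       sprintf("%-4s", atoms$atom_name))
  lines <- sprintf(
    "%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    atoms$record, atoms$serial, name_field, atoms$residue_name,
    atoms$chain, atoms$residue_number,
    atoms$x * 10, atoms$y * 10, atoms$z * 10, 1.00, 0.00,
    atoms$element
  )
  c(lines, "END")
}
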