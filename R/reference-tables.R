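# Packaged reference tables: atomic weights, TPSA fragment contributions,
# aromatic ring-atom names, and the printed parameter sets the synthetic
# generators default to.

#' Standard atomic weights
#'
#' IUPAC 2021 conventional (abridged) standard atomic weights for the
#' elements a small drug-like molecule is likely to contain. Values are in
#' g/mol; rounding happens only at report time.
#'
#' @return A tibble with columns `element` and `weight`.
#' @export
#' @examples
#' atomic_weights()
atomic_weights <- function() {
  tibble::tribble(
    ~element, ~weight,
    "H", 1.008,
    "C", 12.011,
    "N", 14.007,
    "O", 15.999,
    "F", 18.998,
    "Na", 22.990,
    "Mg", 24.305,
    "P", 30.974,
    "S", 32.06,
    "Cl", 35.45,
    "K", 39.098,
    "Ca", 40.078,
    "Fe", 55.845,
    "Zn", 65.38,
    "Br", 79.904,
    "I", 126.904
  )
}

#' Topological polar surface area fragment contributions
#'
#' Published Ertl-scheme fragment contributions for the O- and N-containing
#' polar groups this package recognises, in square Angstroms. Composite
#' groups (carboxylic acid, ester, nitro) are sums of the published
#' single-atom-environment contributions; a carboxylic acid contributes one
#' carbonyl-type O (17.07) plus one hydroxyl-type O (20.23). Sulfur- and
#' phosphorus-containing contributions are an extension point and are not
#' packaged.
#'
#' @return A tibble with columns `group` and `contribution`.
#' @export
#' @examples
#' ertl_contributions()
ertl_contributions <- function() {
  tibble::tribble(
    ~group, ~contribution,
    "hydroxyl",        20.23,
    "carbonyl_O",      17.07,
    "ether_O",          9.23,
    "aromatic_ether_O", 13.14,
    "carboxylic_acid", 37.30,  # 17.07 + 20.23
    "ester",           26.30,  # 17.07 + 9.23
    "primary_amine",   26.02,
    "secondary_amine", 12.03,
    "tertiary_amine",   3.24,
    "aromatic_N",      12.89,
    "nitrile_N",       23.79,
    "nitro",           45.82
  )
}

#' Aromatic ring-atom names of the standard aromatic residues
#'
#' Per-residue ring-atom-name table used by the CH-pi contact classifier:
#' the side-chain atoms that belong to the aromatic ring(s) of Phe, Tyr,
#' Trp and His under PDB v3 naming.
#'
#' @return A tibble with columns `residue` and `atom_name`.
#' @export
aromatic_ring_atoms <- function() {
  ring <- list(
    PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
    HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
  )
  tibble::tibble(
    residue = rep(names(ring), lengths(ring)),
    atom_name = unlist(ring, use.names = FALSE)
  )
}

#' Printed membrane-like retention parameters
#'
#' The Soczewinski-Wachtmeister parameters reported for oleanolic acid on
#' the three anisotropic membrane-like stationary phases, together with the
#' acetonitrile volume-fraction grids each system was measured on. These
#' are the default parameter sets of [gen_retention_table()]; the raw
#' (phi, logk) series behind them were never published, so they serve as
#' generator truth, not as fit targets.
#'
#' @return A tibble with columns `system`, `logkw`, `s`, `r_squared` and a
#'   list-column `phis`.
#' @export
retention_reference_parameters <- function() {
  tibble::tibble(
    system = c("IAM", "CHOL", "ISRP"),
    logkw = c(1.656, 2.361, 0.637),
    s = c(1.515, 2.037, 1.853),
    r_squared = c(0.991, 0.993, 0.983),
    phis = list(
      c(0.75, 0.80, 0.85, 0.90),
      c(0.70, 0.75, 0.80, 0.85),
      c(0.60, 0.65, 0.70, 0.75)
    )
  )
}

#' Printed viability anchors of the MTT assay
#'
#' Reported SH-SY5Y viability percentages after 48 h at three oleanolic
#' acid concentrations. The MTT plate generator calibrates its default
#' dose-response parameters against these anchors.
#'
#' @return A tibble with columns `dose` (ug/mL) and `viability` (percent).
#' @export
viability_anchors <- function() {
  tibble::tibble(
    dose = c(100, 300, 1000),
    viability = c(71.5, 61, 43)
  )
}
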