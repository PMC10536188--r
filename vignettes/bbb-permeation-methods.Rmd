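---
title: "Methods: from biomimetic retention to membrane free-energy profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from biomimetic retention to membrane free-energy profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbbperm)
```

`bbbperm` implements the computational chain used to argue the
central-nervous-system potential of a lipophilic natural product such as
oleanolic acid (OA): chromatographic lipophilicity on membrane-like HPLC
phases, a blood–brain distribution (logBB) QSAR with full validation
machinery, IC50 calibration for enzyme-inhibition and viability assays,
distance-based ligand–protein contact classification, and 1D
umbrella-sampling free-energy profiles. This vignette explains each model,
its assumptions, the tunable parameters, and the deliberate design
choices; the companion README shows the worked end-to-end example.

## Lipophilicity from membrane-like chromatography

On a reversed-phase-like column the retention factor
$k = (t_R - t_0)/t_0$ decreases log-linearly with the organic-modifier
volume fraction $\varphi$:

$$\log k = \log k_w - s\,\varphi,$$

the Soczewiński–Wachtmeister relation. The intercept $\log k_w$ — retention
extrapolated to a purely aqueous mobile phase — is the lipophilicity
descriptor; the slope magnitude $s$ characterises the solute/system pair.
`fit_sw()` is ordinary least squares of $\log k$ on $\varphi$ (base-10
logs throughout, the chromatographic convention). Assumptions and
conventions:

* replicate injections are aggregated as the **mean of retention times**
  per $(\text{system}, \varphi)$ before $k$ is computed; averaging
  $\log k$ instead differs only for unequal replicates, and the
  time-domain mean matches how dead times are usually averaged;
* $\varphi$ is stored as a fraction in $[0, 1)$; the CSV reader accepts
  percentages and normalises them, logging the interpretation;
* a series whose retention *increases* with $\varphi$ violates the
  retention model; the fit is flagged and the stored $s$ goes negative,
  but no error is raised — upstream data problems should be visible, not
  fatal.

With two points the line is exact ($R^2 = 1$, zero residual SE, zero
residual degrees of freedom). The packaged reference parameters
(`retention_reference_parameters()`) are the published per-system values
for OA on phosphatidylcholine (IAM), cholesterol-bonded (CHOL) and
internal-surface-reverse-phase (ISRP) columns, with the acetonitrile
gradients each system was measured on; the raw series behind them were
never published, so they act as generator truth, not fit targets.

## The logBB QSAR

The built-in model (`logbb_model()`) relates blood–brain distribution to
three descriptors:

$$\log BB = -0.114 - 0.098\,\Delta\log P + 0.278\,\log k_w + 0.218\,E,$$

with $n = 40$, cross-validated $R^2 = 78.25\%$, external-prediction
$R^2 = 74.02\%$ and residual scale $S = 0.436$ log units. Here $E$ is
Abraham's excess molar refraction and $\Delta\log P$ the hydrogen-binding
potential. The source legend describes $\Delta\log P$ verbally as
"logkw minus logPcw", which would be negative, while the accompanying
descriptor table prints positive values equal to
$\log P_{cw} - \log k_w$; the printed arithmetic wins here, and
`delta_logp()` returns $\log P_{cw} - \log k_w$. Because $\Delta\log P$
is derived, `predict_logbb()` always recomputes it from its parents when
both are supplied and warns if a free-set value disagrees. A related
narrative claim — that only the CHOL-derived prediction is negative — is
inconsistent with direct arithmetic on the printed descriptors (ISRP is
negative, CHOL positive); the package documents the discrepancy and
asserts only the arithmetic.

The model-building machinery mirrors how such models are made:

* **Backward elimination** (`fit_mlr_backward()`): start from all
  candidates, repeatedly drop the descriptor with the largest partial-*t*
  p-value above `alpha_remove` (default 0.05, one variable per
  iteration). The removal threshold is a convention; the source names the
  procedure but not the criterion.
* **Leave-ten-out cross-validation** (`cross_validate_lto()`): seeded
  random partition into disjoint folds of 10, refit on each complement,
  $PRESS = \sum (y - \hat y_{cv})^2$, $R^2_{CV} = 1 - PRESS/TSS$,
  $RMSECV = \sqrt{PRESS/n}$. "Replicated several times" is exposed as
  `n_repeats`, reporting the mean and SD over partitions.
* **Applicability domain** (`applicability_domain()`): the source names
  no method, so the conventional leverage/Williams approach is used:
  $h = x(X^TX)^{-1}x^T$ with intercept, warning threshold
  $h^* = 3(p+1)/n$. This is documented as a convention, not a source
  claim. The built-in published model ships without its training design
  (the 40-compound literature set is not redistributed), so its leverage
  and domain flags are `NA`; an external-prediction $R^2$ is likewise
  carried as metadata only and never imputed.

## IC50 machinery

Two assay families are covered.

**TLC-bioautography** (enzyme inhibition read densitometrically): a
linear calibration `response = slope * amount + intercept` is fitted by
OLS (`fit_linear_calibration()`); `ic50_tlc()` solves the amount at half
of a user-supplied maximal-inhibition reference response. The assay never
defines an absolute 100% point, and the published unit path from its
calibration line to a molar IC50 is not reconstructible from what is
printed, so every conversion constant (molar mass, stock concentration,
zone volume) is an explicit parameter and the molar result is exercised
as a round-trip, not reproduced.

**MTT viability**: the printed viability formula is internally
inconsistent (its numerator and denominator repeat the control term), so
the standard blank-corrected form is used:
$\mathrm{viability} = 100\,(OD_t - OD_b)/(OD_c - OD_b)$, with inhibition
its exact complement. `ic50_dose_response()` fits a four-parameter
logistic $r(d) = b + (t - b)/(1 + (d/m)^h)$ by seeded multi-start
bounded Levenberg–Marquardt (bottom $\in [0, 50]$, top $\in [50, 120]$)
and solves the 50% crossing analytically; when the logistic fit fails the
fallback interpolates linearly **in concentration** between the
bracketing doses — on the printed viability triplet (71.5/61/43% at
100/300/1000 µg/mL) that convention lands near 728 µg/mL, closer to the
published ~714 µg/mL than a log-linear interpolation would be, which is
why linear-in-dose is the fallback. Responses must bracket 50%;
otherwise the IC50 is declared unidentifiable rather than extrapolated.

The plate generator's default midpoint and Hill slope (620 µg/mL, 0.53)
are the least-squares solution of the two-parameter logistic through the
three printed anchors; generated anchor viabilities land within 1.6
percentage points of the printed ones.

## Contact classification

`parse_structure()` reads ATOM/HETATM records (through bio3d) into a flat
atom tibble in nanometres, inferring elements from columns 77–78 with an
atom-name fallback. Analysis is **heavy-atom and distance-only** — the
0.38 nm cutoff is a heavy-atom convention, and no angular criteria are
applied. `contact_residues()` lists residues with any heavy-atom pair
strictly closer than the cutoff; `classify_contacts()` then assigns, per
residue, every class supported by at least one pair:

| class | criterion (windows closed on both ends) |
|---|---|
| `hydrogen_bond` | O/N–O/N pair at 0.25–0.35 nm |
| `nonpolar_CC` | C–C pair at 0.30–0.38 nm |
| `CH_pi` | ligand aliphatic C within cutoff of a Phe/Tyr/Trp/His ring atom |
| `other_polar` | any other pair within cutoff involving O or N |

"Aliphatic" is approximated structurally as a ligand carbon with no O/N
neighbour within 0.18 nm — a proxy for an sp³ C–H carbon that needs no
connectivity records. Ring membership comes from a packaged per-residue
ring-atom-name table. Boundary ties are included (the source is silent);
residue numbering follows the input PDB verbatim. The synthetic
aromatic-cage fixture places ring atoms at exact distances so the CH-π
class dominates, qualitatively mirroring an aromatic cluster enclosing an
aliphatic core; the actual docked pose of the OA–acetylcholinesterase
complex is not deposited, so no specific residue list is asserted.

## Umbrella sampling and WHAM

`wham()` combines biased histograms by the standard self-consistent
iteration (probabilities $p_j$ and window free energies $f_i$ updated
until the largest $f_i$ change falls below `tol`), computed in log space
for numerical safety. Conventions and defaults:

* `kT = 2.5775` kJ/mol (310 K);
* 200 uniform bins over the union of sampled ranges (bin count is not
  stated by the source; doubling it moves a recovered double-well barrier
  by well under 0.3 kJ/mol);
* the first 1/8 of each window's samples is discarded as equilibration,
  mirroring a 5-of-40 time-unit discard convention;
* `tol` defaults to $10^{-6}\,kT$, deterministic initialisation
  $f_i = 0$; hitting `max_iter` flags the profile unconverged instead of
  erroring;
* profiles are reported min-zero; adjacent windows must share an
  occupied bin or an explicit overlap error is raised.

Bins with very few counts carry statistical noise of order
$kT/\sqrt{n_{\mathrm{eff}}}$ — several kJ/mol at the sampling fringe
where only an autocorrelated tail of the outermost window reaches.
Summaries and oracle comparisons therefore evaluate bins with adequate
occupancy (the tests use a total count of at least 25); values in
near-empty bins are reported but should not be over-read.

Errors come from `wham_bayesian_bootstrap()`: whole-histogram window
weights drawn from a flat Dirichlet, WHAM re-solved per replica, per-bin
SD after min-zero alignment. Reweighting whole histograms cannot see
within-window histogram-shape noise, so with few, strongly overlapping
windows the bootstrap SD underestimates the true regeneration spread by
roughly 20–25%; with a study-like 20-window layout it tracks the spread
of independent regenerations to well within 30%. This is a known
characteristic of histogram-level bootstrapping, documented here so error
bars are read accordingly.

`profile_summary()` reduces a profile to three gauge-invariant numbers:
immersion free energy (bulk mean minus global minimum), central barrier
(centre-region maximum minus global minimum) and entry barrier (maximum
between the bulk edge and the minimum, above bulk level; zero for a
monotone descent). The published molecular-dynamics magnitudes (~43 and
~23 kJ/mol immersion for the two bilayer chemistries, 12–17 kJ/mol
central humps) are cluster-scale results and are **not** reproduced here;
they parameterise the synthetic membrane-like potential
(`membrane_potential()`, a three-Gaussian shape whose well and centre
levels are solved linearly to the requested landmarks) and the
constructed profiles on which the summaries are verified exactly.

The toy sampler (`sample_umbrella()`) is Metropolis Monte Carlo in
$U(\xi) + \tfrac{1}{2}\kappa(\xi - \xi_0)^2$ — a deliberate stand-in for
molecular dynamics that preserves exactly the statistical structure WHAM
consumes (harmonically biased Boltzmann samples) and nothing else. Chains
start at the window centre; the default proposal scale
$2\sqrt{kT/\kappa}$ keeps acceptance near 50% for pure restraints, and an
acceptance below 1% errors with advice to shrink the step.

## The synthetic generators and what passing tests show

Every generator is a pure function of its seed and emits the exact
layouts the analysis functions read, so the whole pipeline runs without
external data. They emulate: log-linear retention with Gaussian
log-k noise (default 0.017 log units, set analytically so
triplicate-averaged fits give $R^2 \approx 0.99$); uniform descriptor
designs with Gaussian response noise at the published residual scale;
logistic viability plates anchored at the printed percentages; Boltzmann
samples from known 1D potentials; and exact-geometry PDB complexes. What
they do **not** emulate: correlated descriptor structure of real compound
sets, heteroscedastic or drifting assay noise, instrument artefacts, MD
autocorrelation beyond the Metropolis chain's own, or real binding-pocket
geometry. Passing tests therefore demonstrate correctness of the
estimators under their stated statistical assumptions — not field
performance on laboratory data.

## Numerical choices at a glance

| choice | value | why |
|---|---|---|
| log base (chromatography) | 10 | field convention |
| replicate aggregation | mean of times | matches dead-time practice |
| backward-elimination α | 0.05 | partial-t convention |
| LTO fold size | 10 | the named procedure |
| leverage threshold | $3(p+1)/n$ | Williams-plot convention |
| 4PL bounds | bottom 0–50, top 50–120 | viability-scale plausibility |
| contact cutoff | 0.38 nm (strict <) | stated convention; windows closed |
| kT | 2.5775 kJ/mol | 310 K |
| WHAM bins / tol / equilibration | 200 / $10^{-6} kT$ / 1/8 | conventions, source silent |
| problem sizes in tests | 200 QSAR replicates; 20×20,000 umbrella samples | desk-scale sizes that make the Monte-Carlo bands tight |

## Known limitations

* Structure descriptors are count-based; no SMILES perception is
  attempted, and only O/N Ertl contributions are packaged (S/P are an
  extension point). A printed in-silico $\log P_{ow}$ of 11.108 for OA
  far exceeds the 6.5–8.5 range the same source cites elsewhere; the
  package treats all partition coefficients as inputs and does not
  attempt a reconciliation.
* The published 40-compound training set is unavailable, so the built-in
  model cannot expose leverage, and its printed validation statistics are
  carried, not recomputed.
* Bootstrap error bars are mild underestimates in few-window layouts
  (above).
* Contact classes are distance-only; genuinely angular interactions
  (bifurcated hydrogen bonds, tilted CH-π geometries) are beyond its
  resolution.
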