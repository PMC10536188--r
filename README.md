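# bbbperm

Can a lipophilic plant triterpenoid such as oleanolic acid reach the
central nervous system, and would it stick to its target once there?
`bbbperm` implements the desk-side computational chain used to answer
that question for blood–brain-barrier (BBB) permeation studies built on
biomimetic chromatography:

* **Lipophilicity from membrane-like HPLC phases** — retention factors
  `k = (t_R − t_0)/t_0` extrapolated to pure water through the
  Soczewiński–Wachtmeister relation `log k = log k_w − sφ`; the intercept
  `log k_w` is the lipophilicity descriptor.
* **A blood–brain distribution QSAR** — the published model
  `logBB = −0.114 − 0.098 ΔlogP + 0.278 logkw + 0.218 E`
  (n = 40, R²_CV = 78.25%, S = 0.436), where `ΔlogP = logPcw − logkw` is
  the hydrogen-binding potential and `E` Abraham's excess molar
  refraction — plus the full machinery to build such models:
  backward-elimination MLR, leave-ten-out cross-validation
  (PRESS, R²_CV, RMSECV) and a leverage-based applicability domain.
* **IC50 calibration** — linear densitometry calibration for
  TLC-bioautography enzyme assays and four-parameter-logistic (with
  interpolation fallback) dose–response fitting for MTT viability plates.
* **Ligand–protein contact classification** — heavy-atom,
  distance-window analysis of PDB complexes (contacts < 0.38 nm;
  hydrogen bonds 0.25–0.35 nm; C–C 0.30–0.38 nm; CH-π against the
  aromatic rings of Phe/Tyr/Trp/His).
* **1D free-energy profiles** — the weighted histogram analysis method
  (WHAM) over umbrella-sampling windows, Bayesian bootstrap of complete
  histograms for error bars, and permeation summaries (immersion ΔG,
  central and entry barriers).
* **Seeded synthetic generators** for every input, so the entire chain is
  testable without downloads, plus structure-derived descriptors
  (molecular weight, Ertl fragment-sum TPSA).

Everything is data-frame-first and pipe-friendly: tibbles in, tibbles
out, `tidy()`/`glance()` on fitted objects, `autoplot()` on every result
type.

## Worked example

Simulate a retention table on the phosphatidylcholine-like (IAM) phase,
fit the retention line, and push the result through the logBB pipeline
with the printed cyclohexane/water partition coefficient and excess molar
refraction for oleanolic acid:

```r
library(bbbperm)

retention <- gen_retention_table(system = "IAM", seed = 42)
fit_sw(retention)
#> <sw_fit> system: IAM
#>   logk = 1.579 - 1.405 * phi   (n = 4, R^2 = 0.998)

desc <- tibble::tibble(system = "IAM", logpcw = 8.995, E = 1.46)
run_logbb_pipeline(list(retention = retention, descriptors = desc))
#> <logbb_report> model: published-logbb
#>   retention fits:
#>     IAM    logkw = 1.579, s = 1.405, R^2 = 0.998
#>   predictions:
#>     IAM    logBB = -0.0837
```

The fitted intercept (1.579) sits close to the generating value of 1.656
— the printed IAM parameter — and the predicted logBB of −0.08 says such
a compound partitions nearly equally between brain and blood
(logBB = log10 of the brain/blood concentration ratio; 0 means equal).
Feeding the printed descriptor table directly reproduces the
hand-evaluated predictions for the three membrane-like systems: −0.4377
(ISRP), −0.0546 (IAM), +0.2105 (CHOL).

A viability plate goes the same way:

```r
plate <- gen_mtt_plate(seed = 42)           # anchored at 71.5/61/43 %
plate |> plate_viability() |> ic50_dose_response()
#> <ic50_fit> method: logistic-4p
#>   IC50 = 589.7 +/- 28.5
```

The generator's default dose–response midpoint (620 µg/mL, from the
printed viability anchors) is recovered within the plate noise.

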