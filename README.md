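# pkddi

Pharmacokinetic drug–drug interaction (DDI) analysis for bioanalytical
LC-MS/MS studies in small animals, end to end:

* **Calibration** — least-squares response-ratio lines with the full set of
  regression statistics (r, S_a, S_b, S_y/x), back-calculation with
  out-of-range flagging, LLOD/LLOQ determination by signal-ratio plus
  accuracy/precision rules, dilution correction.
* **Method validation** — accuracy/precision (intra-/inter-day), extraction
  recovery, matrix effect, selectivity, carryover, stability and dilution
  integrity, each evaluated against FDA-style acceptance limits
  (±20% at the LLOQ, ±15% above it) with an overall battery verdict.
* **Non-compartmental analysis (NCA)** — Cmax and tmax by inspection,
  terminal elimination rate from a best-adjusted-R² log-linear window,
  t½ = 0.693/Kel, linear-trapezoid AUC0-t, AUC0-∞ = AUC0-t + C_last/Kel,
  CL/F = dose/AUC0-∞.
* **DDI statistics** — relative bioavailability
  R.B.% = 100·AUC0-∞(combination)/AUC0-∞(single), animal-paired
  metabolite/parent ratio M.R.%, and pooled two-sample t-tests at α = 0.05.
* **A seeded study simulator** — one-compartment oral absorption with
  first-order metabolite formation, log-normal inter-animal variability,
  proportional assay noise and LLOQ censoring, emulating a three-arm rat
  design (DSV 50 mg/kg; TAM 10 mg/kg with metabolite TOH measured; the
  combination; n = 5/arm, sampling 0–48 h), plus calibration/QC response
  batches with stage-specific attenuation. Everything downstream is
  testable with known truth and no laboratory data.

## Worked example

```r
library(pkddi)

bp <- config_simulation(default_config())$base_params
ds <- simulate_study(study_design(seed = 42), bp)        # 30 profiles
tab <- nca_table(ds, partial = TRUE)                     # per-subject NCA
s <- build_summary_table(tab[tab$group != "III", ],      # single arms
                         tab[tab$group == "III", ])      # combination arm
cat(format_summary_table(s), sep = "\n")
```

```
analyte  parameter                  single (mean +/- SD)      combo (mean +/- SD)        p
DSV      Cmax (ng/mL)                   155.15 +/- 56.20         143.10 +/- 30.37   0.6843
DSV      t1/2 (h)                         19.52 +/- 2.66           20.93 +/- 4.08   0.5368
DSV      AUC0-inf (ng.h/mL)          4993.36 +/- 2023.65      5150.83 +/- 1944.08   0.9032
DSV      R.B. (%)                                      -                   103.15        -
TAM      Cmax (ng/mL)                  332.04 +/- 100.01         316.88 +/- 76.82   0.7950
TAM      AUC0-inf (ng.h/mL)          9123.74 +/- 2692.22      9444.52 +/- 3226.23   0.8687
TAM      R.B. (%)                                      -                   103.52        -
TOH/TAM  M.R. (%), single               128.15 +/- 54.98                        -        -
TOH/TAM  M.R. (%), combo                               -         139.27 +/- 64.23        -
```
(excerpt; the full table also reports tmax, CL/F and the TOH rows)

Read it as a DDI study would be read: no parameter differs significantly
between single and co-administration (all p ≫ 0.05), relative
bioavailability sits near 100%, and the metabolite/parent ratio is
unchanged — the simulated world here contains no true interaction
(`ddi_effect()` with all factors 1), and the pipeline correctly reports
its absence. Simulating with `ddi_effect("TAM", f_scale = 2)` doubles the
victim's exposure and the AUC t-test flags it with >80% power.

Operating characteristics of the whole pipeline:

```r
summarize_replicates(replicate_studies(500, seed = 1))
#   per analyte: mean R.B.% ~101-103, null rejection rates ~5% per parameter
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/pkddi", package = "pkddi"))')
Rscript $CLI simulate --seed 5 --out runs/demo          # profiles.csv
Rscript $CLI nca      --input runs/demo/profiles.csv --out runs/demo/nca.csv
Rscript $CLI compare  --input runs/demo/profiles.csv --out runs/demo
Rscript $CLI validate --input qc_tables/ --out runs/val --strict
```

`validate --strict` exits nonzero when the battery verdict is FAIL.

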