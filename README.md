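# nirperm

Analysis toolkit for near-infrared (NIR) readouts of intestinal
permeability and neutrophil elastase (NE) activity in preclinical
colitis models.

## The problem

In mouse models of inflammatory bowel disease (DSS and anti-CD40
colitis), gut barrier damage lets an orally dosed ~1 kDa polyanionic NIR
dye leak from the colon lumen into blood, where small serial blood
samples quantify permeability far more sensitively than classical
FITC-dextran. A second, intravenously dosed fluorogenic probe is
unquenched by neutrophil elastase at sites of inflammation, and confocal
laser endomicroscopy (CLE) plus ex vivo organ imaging turn that signal
into severity readouts. `nirperm` implements the quantitative chain
behind those assays, for researchers who need to analyse (or simulate
and power) such studies:

* **Pharmacokinetics** — a mechanistic three-compartment model of the
  oral tracer: gut → central ⇄ peripheral, with systemic elimination
  `k10` and colonic loss `kce` of unabsorbed tracer,

  dG/dt = −(ka+kce)·G,
  dAc/dt = ka·G − (k10+k12)·Ac + k21·Ap,
  dAp/dt = k12·Ac − k21·Ap,  C(t) = Ac/Vc,

  solved in closed form (matrix exponential), with constrained
  least-squares fitting of (ka, kce) on log(C + LOD/2) while the
  IV-derived disposition constants stay fixed, an optional delayed
  second absorption site for bimodal disease profiles, and Cmax/Tmax
  and bioavailable-fraction summaries.
* **Permeability assay** — plate-reader standard curves, blank + 3·SD
  limit of detection, fluorescence→concentration conversion with blood
  dilution and censoring, one-way ANOVA with Tukey HSD, percent
  reduction and fold change.
* **CLE severity rubric** — the ordinal 0–5 scoring of frame-level
  crypt-architecture and NE-probe features, with per-animal
  aggregation.
* **Imaging quantification** — ROI mean fluorescence intensity,
  cohort min–max normalization, distal/proximal organ segmentation,
  IHC percent-positive pixels, and histology erosion-length /
  inflammation-extent interval arithmetic.
* **Synthetic cohorts** — seeded generators for every input above,
  with ground-truth sidecars for recovery studies.

The numbered scripts under `analysis/` run the stages as a workflow
(simulate → fit → assay statistics → CLE scores → imaging → report) and
write tables under `results/`.

## Worked example

```r
library(nirperm)

p <- default_pk_params("dss")              # disease-state kinetics
d <- pk_dose(mg_per_kg = 2, route = "oral") # 40,000 ng in a 20 g mouse
tc <- simulate_pk(p, d, times = c(1, 2, 4, 8, 14, 24, 48))
tc
#>   animal_id group time_h conc_ng_ml censored
#> 1       sim   sim      1   4.127506    FALSE
#> 2       sim   sim      2   7.175247    FALSE
#> 3       sim   sim      4  10.919780    FALSE
#> 4       sim   sim      8  13.006893    FALSE
#> 5       sim   sim     14  11.179299    FALSE
#> 6       sim   sim     24   6.797960    FALSE
#> 7       sim   sim     48   1.803517    FALSE

peak <- cmax_tmax(p, d)
sprintf("Cmax %.1f ng/ml at Tmax %.1f h; bioavailable fraction %.4f",
        peak$cmax, peak$tmax, bioavailable_fraction(p))
#> "Cmax 13.0 ng/ml at Tmax 8.0 h; bioavailable fraction 0.0027"
```

The curve peaks at 13 ng/ml around 8 h — a diseased animal's profile —
and only ~0.3% of the oral dose is ever absorbed; the rest exits with
feces. Refitting the curve recovers the generating rates:

```r
fit <- fit_oral(tc, list(k10 = 0.15, k12 = 0.05, k21 = 0.08, Vc = 2),
                d, lod = 0.5)
round(fit$estimate, 6)
#>       ka      kce
#> 0.000238 0.087300
```

Assay calibration and the severity rubric work the same way:

```r
sc <- fit_standard_curve(c(1, 5, 10, 50), 100 * c(1, 5, 10, 50) + 48,
                         blanks = c(50, 52, 48))
sc$lod                     # (blank mean − intercept + 3·SD) / slope
#> [1] 0.08                 # ng/ml

score_frame(frame_annotation(healthy_crypt_fraction = 0.8,
                             crypt_architecture_change = "present",
                             ne680_lumen = "high",
                             collapsed_crypts = "present"))
#> [1] 2                    # >50% healthy crypts, high luminal NE, collapse
```

See `vignettes/nirperm-methods.Rmd` for the model, fitting objective,
rubric formalisation and the synthetic cohorts' assumptions, and
`analysis/01_simulate_cohorts.R` … `06_report.R` for the full workflow.

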