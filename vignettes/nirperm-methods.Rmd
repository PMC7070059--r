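---
title: "Models and methods behind nirperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nirperm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirperm)
```

# Scope

`nirperm` implements the quantitative chain of a near-infrared readout of
intestinal permeability and neutrophil elastase (NE) activity in mouse
colitis models: an oral-absorption compartment model with constrained
fitting, plate-reader calibration of blood fluorescence with
limit-of-detection handling and ANOVA/Tukey group statistics, an ordinal
endomicroscopy severity rubric, and organ/IHC fluorescence
quantification. Seeded generators produce synthetic cohorts with the
statistical structure each stage assumes, so the entire chain is testable
without animal data. The `analysis/` scripts run the stages in order and
write their tables under `results/`.

# The compartment model

An orally dosed, poorly absorbed tracer is modelled with a gut
compartment feeding a central–peripheral disposition pair:

$$
\begin{aligned}
\dot G &= -(k_a + k_{ce})\,G \\
\dot A_c &= k_a G - (k_{10} + k_{12})\,A_c + k_{21} A_p \\
\dot A_p &= k_{12} A_c - k_{21} A_p, \qquad C(t) = A_c(t)/V_c
\end{aligned}
$$

with all amounts in ng, times in hours, concentrations in ng/ml.
The gut empties through two competing first-order routes: net absorption
$k_a$ (lumping small-intestinal and colonic uptake) and colonic (fecal)
loss $k_{ce}$ of tracer that is never absorbed, so the bioavailable
fraction is $k_a/(k_a + k_{ce})$. The system is linear, so
concentration scales exactly with dose, and is solved in closed form via
eigendecomposition of the rate matrix (with a `Matrix::expm` fallback
for the measure-zero defective coincidences, e.g. $k_a + k_{ce}$ equal
to a disposition eigenvalue). Two extra bookkeeping states accumulate
colonic and renal losses, so the summed state equals the dose at all
times — the mass-balance identity the tests check at $10^{-6}D$. An
adaptive ODE integrator (deSolve) serves as an independent oracle in the
test suite only; the solver of record is the closed form.

Diseased animals can show a second, later absorption wave. This is
modelled as an optional second gut site with its own rate $k_{a2}$,
activated at a lag $\ell_2$ and holding a fraction `frac2` of the oral
dose (the dose share is a parameter this package adds: a second site is
not meaningful without one). With $k_{a2} = 0$ or `frac2 = 0` the model
reduces *exactly* to the unimodal form, which the tests assert
bitwise.

# Fitting

Disposition constants ($k_{10}, k_{12}, k_{21}, V_c$) are estimated from
IV data (`fit_iv`), then held fixed while `fit_oral` estimates
$(k_a, k_{ce})$ — mirroring the practice of anchoring exchange rates in
intravenously dosed animals. Both fits minimise squared residuals on the
log scale; `fit_oral` uses $\log(C + \mathrm{LOD}/2)$ so that the
objective spans the assay's full dynamic range (oral data cover more
than an order of magnitude, roughly 2–13 ng/ml) without letting
near-censored points dominate. Censored observations enter at LOD/2.
Optimisation is multi-start: a 5-point log-space grid over
$(k_a, k_{ce})$ for the oral fit (L-BFGS-B, bounds $10^{-12}$–$10^2$
1/h), and a fixed perturbation design around data-driven starts
(terminal slope, back-extrapolated intercept) for the IV fit. No
randomness is involved, so fits are reproducible by construction.

Two quality flags accompany `fit_oral`: `at_boundary` is raised when
$k_a$ is pinned at its lower bound *or* when the fitted curve never
clears the LOD — for a flat naive-like profile the absorption rate is
then indistinguishable from zero at the assay's sensitivity; and
`wide_uncertainty` is raised when a finite-difference curvature probe
finds a nearly flat direction in the loss surface (e.g. $k_{ce}$ when
the signal saturates).

Recovery behaviour, measured by the test suite: noise-free oral fits
return both rates to better than $10^{-3}$ relative; with 10% CV
multiplicative noise on 12 sampling times over 1–48 h, the median
relative error on $k_a$ across 200 simulated animals is about 3%. The
IV simulation study uses a disposition set with well-separated
distribution and terminal phases ($k_{10}=0.3$, $k_{12}=0.2$,
$k_{21}=0.1$ 1/h, $V_c=2$ ml) and a sampling grid covering 5 min–36 h;
with weakly expressed distribution phases the exchange rates are poorly
identified at this noise level, which is a property of the design, not
of the optimiser.

# Permeability assay

Calibration is an ordinary least-squares line of fluorescence on known
concentration. The assay's "detection limit" is never defined in the
source material, so the package adopts the standard analytical
convention: the LOD is the concentration whose expected signal equals
the blank mean plus three blank standard deviations,
$(\bar F_{blank} - b + 3 s_{blank})/m$ for slope $m$ and intercept $b$.
Back-calculated concentrations are multiplied by the blood dilution
factor (default 3: 10 µL blood into 20 µL EDTA/PBS) and censored when
the in-well concentration falls below the LOD; censored values enter
group summaries at LOD/2 with an audit flag rather than being dropped,
which preserves below-LOD groups in plots and statistics.

Group inference is one-way ANOVA with Tukey HSD pairwise comparisons
(Tukey–Kramer for unequal group sizes), computed by `stats::aov` and
`stats::TukeyHSD`. When every group mean is identical the F statistic is
defined as 0 with p = 1 (the 0/0 case). The suite verifies the
two-group identity $F = t^2$ against `t.test`, the nominal 5% type-I
error and p-value uniformity on 10,000 null simulations, and that Tukey
adjustment never undercuts the unadjusted pairwise p. Derived effect
summaries are `percent_reduction` ($100\,(1 - \text{treated}/\text{control})$,
clipped at 0 with a flag) and `fold_change`; the worked numbers from
published group means (2.6 → 0.02 µg/ml gives 99.2%; 6.7 → 1.3 ng/ml
gives 80.6%) are frozen in the tests. Note the latter differs from the
rounded "85%" sometimes quoted for this comparison; the package reports
what the formula gives and does not hard-code a target.

# The severity rubric

The endomicroscopy rubric maps categorical frame features — crypt
architecture and acriflavine staining on one channel, NE probe signal on
the other — to an ordinal 0–5 score. Each grade's criteria are read as
*minimum-severity requirements* and a frame receives the most severe
matching grade. This resolves two ambiguities in a table-style rubric:
overlapping descriptions (a frame matching both grade 2 and grade 3
descriptions is grade 3, the convention of clinical severity indices),
and non-monotone gates. In particular the grade-2 phrase "more than 50%
healthy crypt structure" describes that grade's typical appearance and
distinguishes it from higher grades; treating it as a hard gate would
let a *worse* frame (fewer healthy crypts, same NE signal) drop to a
*lower* score. With upward-closed criteria, worsening any single
feature can never decrease the score — a property the suite checks
exhaustively over the full annotation lattice (8,640 valid feature
combinations). A frame with faint NE signal but mild architectural
change falls to grade 1 under the fallback; this is a documented
decision, as the rubric itself does not define the case.

Per-animal aggregation is not specified by the rubric; the default is
the modal frame score with ties broken toward the higher score
(`max` and `median` are selectable). ">50%" thresholds are strict
inequalities.

# Imaging quantification

Organ-level analysis consumes per-ROI pixel sums and counts (or raw
intensity matrices with masks); proprietary pixel classifiers are out of
scope, as the quantitative content is the arithmetic after segmentation.
`roi_mfi` is the masked mean; `min_max_normalize` rescales a cohort to
[0, 1] (errors on a constant cohort, where the scale is undefined);
`segment_rois` partitions a mask along its long axis at a configurable
fraction (default 0.5 — the distal/proximal boundary is not defined in
the source, so it is exposed as a parameter), guaranteeing that
distal + proximal pixel counts recombine to the whole-organ count and
hence that count-weighted MFIs recombine to the whole-organ MFI to
$10^{-9}$. IHC readouts are percent marker-positive pixels of the
mucosal area. Histology uses interval arithmetic: total erosion length
sums merged half-open intervals, and inflammation extent is the length
of the contiguous run from the rectal squamous junction (position 0)
over which crypt loss exceeds 50% — loss beginning away from the
junction contributes nothing, the reading most consistent with
"measuring proximally from the rectal squamous junction".

# Synthetic cohorts

The generators define the study conditions the tests run under:

* **PK cohorts** — per-animal $k_a$ lognormal around the group mean
  (default CV 30%), multiplicative lognormal measurement noise (default
  CV 10%, mean-preserving), constant blood background added before
  noise, censoring at LOD 0.5 ng/ml, 12 sampling times over 1–48 h,
  n = 10 per group. The disease parameter set is calibrated once so a
  2 mg/kg oral dose in a 20 g mouse peaks at 13 ng/ml near 8 h
  ($k_a = 2.38\times10^{-4}$, $k_{ce} = 0.0873$ 1/h, giving a
  bioavailable fraction of ~0.3%, consistent with a ~1 kDa polyanionic
  dye); naive animals absorb essentially nothing and sit at the flat
  ~2 ng/ml background. The disposition constants are illustrative
  stand-ins for IV-derived values, which are not published.
* **Plates** — standards, blanks and samples on a known line with
  multiplicative noise; truth emitted alongside.
* **CLE cohorts** — frames drawn as the defining annotation of the
  target grade; with noise rate ε a frame steps one grade up or down.
  At ε = 0 the modal animal score equals the target for every grade,
  a round-trip the acceptance suite asserts.
* **Imaging tables** — lognormal MFIs with a configurable group
  ordering (the default mirrors disease > treated ≈ naive) and
  beta-distributed positive fractions.

Lognormal noise was chosen for positivity and CV-scaling of
fluorescence data, beta for bounded fractions; only means and dispersions
are constrained by the emulated designs, so the distribution families are
modelling choices recorded here. All randomness in a generator flows
from the single seed in its spec (generators restore the caller's RNG
state), and identical seeds are bit-reproducible.

What passing tests on these cohorts does *not* show: real blood
measurements have matrix effects, hemolysis variation and day effects
the multiplicative-noise model ignores; real CLE frames are scored by
humans with inter-rater disagreement; and organ MFIs inherit tissue
thickness and vascularisation gradients that the proximal/distal boost
parameter only caricatures. The generators validate the arithmetic and
the statistical plumbing, not the biology.

# Numerical and design notes

* Problem sizes in the default suite: 1,000 random parameter sets for
  mass balance, 50 for the ODE cross-check, 200 simulated animals per
  recovery study, 10,000 null replicates for the type-I error — chosen
  to make Monte-Carlo error small relative to the tolerances tested.
* Tolerances: mass balance $10^{-6}D$; closed form vs ODE $10^{-6}$
  relative; MFI recombination $10^{-9}$; noise-free recovery $10^{-3}$
  relative.
* Degenerate inputs fail loudly: empty masks, constant cohorts,
  all-censored time courses, zero denominators and invariant-violating
  annotations all raise errors rather than returning defaults.
* The `cli_report` surface of the pipeline is the set of numbered
  scripts under `analysis/` plus the report helpers
  (`group_stats_table`, `significance_marker`, `write_provenance`);
  each stage writes its outputs and a provenance record (seed, config,
  package version) into its own `results/` subdirectory and never
  mutates its inputs.
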