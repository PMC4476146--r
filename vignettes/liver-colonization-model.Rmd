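---
title: "Quantifying liver-metastasis burden: model, estimators and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying liver-metastasis burden: model, estimators and simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaburden)
```

## The experimental system and its abstraction

In the intrasplenic-injection model of hepatic metastasis, a known dose of
tumor cells (typically 2×10^6) is injected into the spleen, travels the
portal circulation, and a tiny fraction founds macroscopic liver colonies.
Cells double-labeled with a luciferase and a fluorophore give two optical
readouts: whole-body bioluminescence (photon flux, p/sec/cm²/sr) measured
weekly in vivo, and ex vivo fluorescence (radiant efficiency) of the
harvested liver, where individual colonies are resolvable.

`metaburden` abstracts this experiment into three quantitative layers:

1. **Calibration** — a linear map between cell number and optical signal,
   fitted on a dilution plate and inverted to infer cell numbers in vivo.
2. **Burden metrics** — the colonizing fraction `Fc`, the per-colony
   doubling time `Td`, division counts and sphere-model volumes.
3. **A generative model** — a stochastic simulator parameterized by the same
   `(Fc, Td)` pair, used to validate the estimators and to generate
   realistic fixtures and images.

## Assumptions of the burden metrics

**Single founder, pure exponential growth.** Each colony is assumed to
descend from exactly one cell that begins dividing immediately:
`N(t) = 2^(t/Td)`, so `Td = t·ln2/ln N` and the division count is `log2 N`.
One founding cell is the minimal assumption consistent with equating the
tumor count to the number of cells that colonized; it makes `Fc` a per-cell
clonogenic probability. A lag phase or cell loss would inflate the apparent
`Td`; neither is modeled. A colony of fewer than 2 inferred cells is
indistinguishable from its founder and `doubling_time()` refuses it.

**Linear calibration with intercept.** `fit_calibration()` is ordinary least
squares of signal on cell count *with* an intercept: real wells carry
background signal, and the zero-cell wells of the plated design
(`default_plate_densities()`) anchor it. Whether the original plate fits
were forced through the origin is not documented anywhere we could rely on;
keeping the intercept is the safer choice and `cells_from_signal()` clamps
sub-background signals to zero (with a warning) rather than extrapolating
negative cell numbers. Replicates are pooled, not averaged, so the reported
Pearson R reflects the replicate variance structure. No axis is
log-transformed.

**Which curve for which task.** Per-colony cell inference uses the
fluorescence curve only (`colony_cells()` rejects a luminescence curve);
the luminescence curve drives longitudinal whole-body simulation. This
mirrors the role of each modality: fluorescence resolves colonies ex vivo,
bioluminescence integrates the whole animal in vivo.

**Dispersion conventions.** All summaries are mean ± sample SD (n−1
denominator). `Fc` dispersion is computed across mice; `Td` dispersion
across sampled colonies pooled within the clone. A single mouse or a single
colony yields an `NA` SD with a warning, never a silent zero.

**Colony sampling for Td.** Quantifying a handful of representative
colonies per liver is standard practice; `estimate_td()` therefore samples
up to 5 colonies per liver uniformly at random (seeded), with
`all_colonies = TRUE` to use everything. How "representative" colonies are
chosen by hand in a real experiment is unknowable; uniform sampling is the
only choice that does not bias `Td`.

## The generative model and its defaults

`sim_params()` fixes the study conditions; `scenario_params()` provides the
three characterized clone phenotypes (at the standard dose of 2×10^6 cells):

| clone | Fc | Td (h) | harvest (h) | phenotype |
|-------|-----|--------|-------------|-----------|
| P1 | 8.2e-5 | 26.5 | 504 | many small tumors |
| P2 | 1.1e-5 | 22.7 | 504 | few large tumors |
| O1 | 6.0e-6 | 26.5 | 672 | few small tumors (oligometastatic-like) |

Harvest defaults follow the measurement schedules of the two groups:
polymetastatic clones are followed weekly to 3 weeks (504 h),
oligometastatic clones to 4 weeks (672 h). Both are per-mouse parameters,
because the elapsed time entering `Td` is the single most consequential
input and should never be implicit. Note that when comparing colony sizes
*between* clones, equal harvest times must be used; at 504 h the fast P2
clone produces larger colonies than P1, as observed macroscopically.

Choices a simulator must make that the experiment does not dictate:

- **Seeding is Binomial per mouse**, `Binomial(dose, Fc)` — cells act
  independently and the dose is finite, keeping `Fc ≤ 1` enforceable. No
  Poisson approximation.
- **Inter-colony growth heterogeneity** is lognormal on `Td` with CV 0.05 by
  default. No direct estimate of inter-colony variability exists; a 5% CV is
  consistent with the small (±0.2–0.3 h) SDs reported for clone-level mean
  doubling times and is surfaced as `td_cv` in every configuration.
- **Measurement noise is multiplicative lognormal** (CV 0.05 default):
  optical signals are positive and heteroscedastic, with error roughly
  proportional to intensity.
- **Packing density** 10^6 cells/mm³ (order-of-magnitude solid-tumor
  cellularity) links cell number to macroscopic diameter through sphere
  geometry. It affects only diameters, never `Fc` or `Td`.
- **Week length** is fixed at 168 h.

**Reproducibility contract.** A single integer master seed is split
hierarchically into sub-streams — stream 1 for a mouse's colony draws
(count, then per-colony `Td`s, then measurement noise, in that order),
stream 2 for each (mouse, week) longitudinal measurement, stream 3 for
per-liver colony sampling in `estimate_td()`, stream 4 for replicate
cohorts in `recover_params()`, stream 5 for image pixel noise — via a 31-bit
linear-congruential hash (`R/utils.R`). Mouse *i* is bit-for-bit identical
whether simulated alone or inside a cohort, and the harvested burden is the
endpoint of the longitudinal trace for the same seed. The scheme is part of
the package's public contract and will not change silently.

### What the simulator does *not* emulate

Mechanistic circulation and extravasation, immune editing, spatial
competition between colonies, Gompertzian growth deceleration, inter-mouse
random effects beyond seeding stochasticity, and luciferin kinetics are all
absent. Passing parameter-recovery tests therefore show that the estimators
invert the model's own assumptions correctly — not that those assumptions
hold in animals. In particular, recovery of `Td` to well under 5% at 20 mice
says nothing about lag phases or cell death, which the model excludes by
construction.

## Numerical choices

- `cells_from_signal()` clamps at 0 and warns; `colony_cells()` floors
  detected colonies at 1 cell so `Fc` and `n_av` stay well-defined for faint
  colonies.
- Degenerate calibration designs (fewer than 2 distinct cell counts) and
  non-monotone fits (slope ≤ 0) are hard errors, not warnings.
- In vitro growth curves are fitted as OLS of `log2(signal)` on time, so the
  slope is directly divisions/hour and `Td = 1/slope`; a flat curve returns
  `Td = Inf` with a warning rather than an error. Time-zero normalization is
  offered but the fitted `Td` is scale-invariant either way.
- Classification thresholds (`fc_threshold = 2e-5`, `td_threshold = 24.5` h)
  are explicit arguments chosen to separate the characterized clones; they
  are never hard-coded into analyses.
- Image rendering renormalizes the discrete Gaussian kernel over its support
  (radius 5σ), so each blob's integrated signal equals the colony's radiant
  efficiency exactly; the conservation property holds to better than 1%
  whenever colonies stay ≥5σ from the border, which placement enforces.
- Colony detection thresholds at median + k·MAD (k = 5 default); on a
  noiseless image (MAD = 0) the threshold falls back to 10^-6 of the dynamic
  range above background. Labeling is 8-connected; greedy matching breaks
  ties by smallest distance, then lowest label — all deterministic.
- 32-bit float TIFF files store pixels normalized to [0, 1]; the scale
  factor, pixel size and background travel in a JSON sidecar
  (`<image>.tif.json`), restoring radiant-efficiency units on read.

## Problem sizes in the test suite

The shipped tests run the full surface at desk scale: 200-seed calibration
ensembles, 400–1000 simulated mice for binomial calibration of the seeding
model, 50-replicate × 20-mouse recovery studies, 100-seed scenario-ordering
ensembles with 3-mouse cohorts, and rendered fields up to 460×460 px with
up to ~40 colonies. These sizes make the whole suite complete in well under
a minute while keeping Monte-Carlo error far below every asserted bound.

## Known limitations

- Overlapping or touching colonies are not split (no watershed); dense
  burdens (hundreds of colonies in a small field) under-count, as real
  macroscopic counting would. The placement sampler refuses configurations
  it cannot separate rather than silently overlapping them.
- The detector is a documented stand-in for vendor ROI software, not a
  reconstruction of it.
- `Td` inference is only as good as the harvest-time bookkeeping; with
  ambiguous elapsed time the per-mouse `harvest_hours` field is the
  single source of truth.
- No joint likelihood for `(Fc, Td)` is attempted; estimators are
  method-of-moments style, matching the mean ± SD reporting convention of
  the field.

```{r example}
params <- scenario_params("P1", seed = 7)
cohort <- simulate_cohort(params, n_mice = 3)
clone_phenotype(cohort$burdens, params$fluor_curve)
```
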