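---
title: "Modelling the operational carbon footprint of deep learning in digital pathology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the operational carbon footprint of deep learning in digital pathology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbonpath)
```

## The problem and the model

Digital pathology turns histology glass slides into gigapixel whole-slide
images (WSIs), and deep-learning models increasingly analyse those images
tile by tile. Every inference costs electricity, and electricity carries a
grid-dependent carbon price. `carbonpath` models the *operational*
greenhouse-gas emissions of this workflow — the electricity consumed while
running models — and deliberately excludes training, retraining and embodied
(manufacturing, buildings, storage) emissions, which belong to a different
layer of a lifecycle assessment.

The accounting identity is linear throughout. For one task applied to a
workload of $T$ tiles with a model consuming $e$ kWh per $10^7$ tiles on a
grid of intensity $I$ (kg CO$_2$eq/kWh):

$$\mathrm{kg\ CO_2eq} = T \cdot \frac{e}{10^7} \cdot I,$$

and a deployment scenario is a sum of such terms over its tasks. Everything
else in the package either produces the inputs of this identity (workloads,
calibrated energies, intensities) or transforms its output (offset
equivalents, extrapolation, projection).

## Workloads: from slide metadata to tile counts

A slide enters the model through metadata only: pixel count, file size, the
fraction of its area covered by tissue, and the fraction covered by a region
of interest (ROI). With non-overlapping square tiles of edge $p$ pixels
(default 512, a common computational-pathology patch size), the three
data-input modes give

- **wsi**: $\lceil \text{pixels}/p^2 \rceil$ tiles,
- **tissue**: $\lceil \text{wsi tiles} \times \text{tissue fraction} \rceil$,
- **roi**: $\lceil \text{wsi tiles} \times \text{roi fraction} \rceil$.

Because ROI lies within tissue and tissue within the slide, counts are
always ordered roi ≤ tissue ≤ wsi — the two data-reduction modes can only
shrink the workload. Computing tissue/ROI tiles from area fractions rather
than spatial masks is a deliberate simplification: it preserves exactly the
quantities the emission identity consumes without requiring any image data.
The ceiling means a partially covered tile still costs a full inference.

## The synthetic cohort generator

Real WSI archives are not shippable, so the generator emulates the
*statistical structure* of a two-organ (breast/prostate) cohort:

- cases per organ: 5 prostate + 8 breast by default, the shape of a
  two-week digitisation sample at a university pathology institute;
- slides per case and pixels per slide: log-normal (right-skewed positive
  quantities; a prostatectomy case can carry many times the slides of a
  biopsy);
- tissue fraction: Beta(2, 2); ROI fraction: tissue fraction times a
  Beta(2, 3) draw, which structurally enforces roi ≤ tissue;
- file size: $a\,\mathrm{pixels}^{\,b}$ with $b = 0.8$ (scanner compression
  makes bytes grow sublinearly in pixels) times log-normal noise whose
  standard deviation is *solved in closed form* so the raw-scale Pearson
  correlation between pixels and bytes hits a configured target (default
  0.58, a moderate correlation: file size alone does not determine
  workload). For jointly log-normal variables the correlation has an
  analytic expression, so no tuning loop is needed; a 10 000-slide cohort
  lands within ±0.05 of the target.

One root seed drives named substreams (cases, slides, bootstraps) so every
downstream confidence interval is reproducible. What the generator does
**not** emulate: spatial tissue arrangement, scanner-specific compression
beyond the power-law shape, organ-specific staining, or inter-institute
case-mix differences. Tests passing on synthetic cohorts therefore validate
the accounting machinery, not any claim about a particular archive.

## Energy calibration

Measured runs are integrated by the trapezoidal rule over component draws
(DRAM, CPU, GPU, data in/out, cooling) — exact for piecewise-linear traces
and checkable against a brute-force 1-second summation — then normalised to
kWh per $10^7$ tiles so models of very different throughput become
comparable. Per task type (classification/segmentation), the calibration
table is classed into **small** (minimum energy), **medium** (lower median:
rank $\lceil n/2 \rceil$, so "medium" is always a real model) and **large**
(maximum), with lexicographic tie-breaks for determinism.

No per-model energy measurements are published for this domain, so the
packaged 30-model table (20 classification, 10 segmentation, Quadro-6000
class device) is synthetic, drawn once from a log-log power law with slope
0.8 and frozen; its filename says so. Real audits must substitute measured
values — every reader accepts a path.

For a hypothetical very large multitask model, energy is extrapolated from
the scaling law $\log_{10} e = \alpha + \beta \log_{10}(\text{params})$,
fitted by OLS over the calibration table with a nonparametric bootstrap
(models resampled with replacement, 2000 draws, seeded). The default
prediction point is 540 billion parameters. Extrapolating four orders of
magnitude beyond the data is the single most uncertainty-laden step in the
pipeline, which is why the bootstrap interval — typically spanning an order
of magnitude — is carried, not hidden.

## Emissions, uncertainty and offsets

Scenario emissions apply the linear identity per task and sum. The 95% CI
is a percentile bootstrap with per-run energies jittered log-normally
(default $\sigma = 0.02$, consistent with the narrow run-to-run spread of
repeated hardware measurements). For the institute's own workload the slide
set is a census, not a sample, so cases are *not* resampled by default and
the CI collapses as $\sigma \to 0$; the extrapolation layer, whose
mean-tiles-per-case comes from a 13-case sample, additionally resamples
cases with replacement to propagate workload uncertainty.

Offsets follow fixed conversions: one mature tree absorbs about 21.8 kg
CO$_2$eq per year (counts rounded up — a fraction of a tree cannot absorb
the remainder); forest area uses the world forests' yearly capacity of
7.6 Gt over 40.6 million km², about 187.2 t/km²/yr (areas kept as reals).
Grid intensity uses a direct measured value where available (0.40 kg/kWh
for the German runs, which reproduces the published scanner arithmetic) and
otherwise a linear mix of a 0.70 fossil and 0.03 renewable endpoint by
renewable share — an approximation to actual grid databases, flagged as
such.

The pruning comparator is a piecewise-linear curve from (0, 1) to
(0.40, 0.75): a 25% energy saving at 40% pruning, the midpoint of the
20–30% band reported for accuracy-preserving pruning of VGG16/ConvNeXt-class
classifiers. Extrapolation beyond the last knot is refused because nothing
is known about accuracy there. The pathomics comparator prices two
sequential inference passes (tissue detection + segmentation) over tissue
tiles plus a configurable relative overhead for feature extraction
(default 0).

## Extrapolation

No national or global registries of pathology-case counts exist, so regional
totals are anchored: the institute saw 4 804 cancer cases among 40 356
total cases in a year, and a region with $C$ yearly cancer cases is assigned
$C \times 40356 / 4804$ pathology cases (cross multiplication). The anchor
reading "total = 4 804 + 35 552" is the default because it reproduces the
published German figure (552 800 cancer cases → 4 643 837 total cases;
this package computes 4 643 796 from the rounded published inputs, within
$10^{-5}$). A survey-based German count of 17 550 000 cases implies the
anchor underestimates absolute volume by ≈3.8×, which the package reports
as an explicit caveat rather than a correction. Extrapolations use tissue
tiles by default: whole-WSI input wastes computation on empty glass, while
ROI-only input discards diagnostic context.

The packaged region table is synthetic scaffolding (only Germany's entries
trace to published figures); its "Rest of world" cancer count was chosen so
the fixture world total lands near the ~173 million world pathology cases
implied by the published world anchor, since the underlying world cancer
input is not printed anywhere.

## Projection 2023–2052

Four drivers move future emissions: renewable share $R(y)$ (lowers
intensity), model complexity $M(y)$ (raises energy per tile), hardware
efficiency $H(y)$ (lowers it) and case counts $N(y)$. Each is fitted
through anchor points — log-linear (geometric) interpolation for positive
drivers, linear clamped to [0, 1] for the share — with end-segment
extrapolation, plus 2000 seeded bootstrap paths from per-anchor
perturbations (log-normal for positive drivers, logit-normal for shares).
The "mean" renewables scenario is the year-wise arithmetic mean of the
planned and below-2°C paths.

Drivers combine multiplicatively and separably:

$$E(y) = E_0 \cdot \frac{M(y)}{M(y_0)} \cdot \frac{N(y)}{N(y_0)} \cdot
\frac{I(R(y))}{I(R(y_0))} \Big/ \frac{H(y)}{H(y_0)},$$

the only combination rule consistent with the linear accounting identity.
The mean path uses driver means; best/worst are the 2.5/97.5 percentiles of
the drawn paths, and the exceedance year is the first year a path's forest
requirement reaches the whole world's forest. The packaged anchor table is
synthetic (chosen to resemble published renewable-energy outlooks and the
observed growth of model sizes and hardware efficiency) and fully editable;
no figure-derived numbers are hard-coded as truth.

## Numerical choices and degenerate inputs

- Trapezoidal integration; traces with non-increasing timestamps are
  rejected as malformed.
- Ceilings for tiles and trees; case counts rounded to nearest integer;
  emissions kept at full precision until report formatting (3 significant
  figures in printed summaries, full precision in JSON).
- Ties in size classing broken by model name; bootstrap resamples that
  collapse the regression design (all identical parameter counts) are
  redrawn; an all-identical calibration table is a hard error.
- Zero workloads yield exactly zero emissions and offsets; empty cohorts,
  missing calibrations and mode mismatches are explicit, named errors.
- Problem sizes in the shipped tests and scripts (13-case cohorts, 30-model
  tables, 400–2000 bootstrap draws, 200-replicate coverage studies) were
  chosen as the smallest sizes at which the statistical properties under
  test are stable.

## Known limitations

Operational emissions only; one device class at a time; adoption of digital
pathology assumed uniform across regions (it is not); the multitask energy
rests on a long extrapolation; all packaged tables other than the
desk-arithmetic constants are synthetic stand-ins. The package is a
calculation frame for auditing a pathology centre with *its own* measured
tables, and the synthetic defaults exist so the frame is testable end to
end.

## A worked example

```{r example, eval = FALSE}
cohort <- generate_cohort(cohort_config(seed = 1))
sizes <- select_size_classes(read_model_calibration(), "quadro_6000")
wl <- cohort_workload(cohort, tiling_spec(512, "tissue"))
scenario_emission(wl, scenario("seven_task", "tissue", "small"), sizes,
                  intensity_kg_per_kwh = 0.40, seed = 1)
run_published_checks()
```

The numbered scripts under `analysis/` run the same pipeline end to end and
write their tables under `results/`.
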