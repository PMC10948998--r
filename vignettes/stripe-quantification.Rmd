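---
title: "Quantifying pair-rule stripe dynamics from MS2 live imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pair-rule stripe dynamics from MS2 live imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stripedyn)
```

## The measurement problem

In the *Drosophila* blastoderm, the pair-rule gene *even-skipped* (*eve*)
resolves into seven anterior-posterior (AP) stripes during nuclear cycle 14
(NC14), the ~50-minute interphase between the 13th mitosis and
gastrulation.  MS2/MCP live imaging makes nascent transcription visible as
a fluorescent punctum in each active nucleus, so stripe formation can be
followed nucleus by nucleus and frame by frame.  Comparing wild-type
embryos with embryos carrying a halved dosage of the gap gene *Krüppel*
(*Kr*) requires turning those movies into comparable per-embryo
quantities: stripe boundaries and widths over time, activation kinetics,
per-nucleus mRNA output, and cross-embryo variability.  This package
implements that quantification pipeline, together with a synthetic-embryo
generator that plants known genotype effects so every stage can be
validated against ground truth.

## Quantification conventions

All conventions are fixed, deliberately simple, and exposed as defaults:

* **AP coordinate.**  Positions are % egg length (%EL), measured from the
  anterior tip (anterior = 0%).  Profiles use 50 bins of 2 %EL
  (`bin_profile`); FISH profiles use 100 bins of 1 %EL.  Bins are
  half-open `[lo, hi)` with the last bin closed; a nucleus exactly on a
  left edge belongs to that bin.
* **DV window.**  Analysis is restricted to nuclei within a fixed
  282 µm dorsoventral window (~17 nucleus rows) centered on the embryo's
  DV midline (`select_dv_window`), minimizing DV-extent variation across
  embryos.
* **Time.**  NC14 (end of 13th mitosis, `t = 0`, to gastrulation,
  `t = 1`) is normalized to 100 time points; each nucleus's trace is
  linearly interpolated onto this grid (`normalize_traces`).  Grid points
  outside a nucleus's observed frames are NA and contribute nothing.
* **Active calls.**  A nucleus is active where its signal strictly
  exceeds a threshold; a value exactly at the threshold is inactive.  In
  automatic mode the background is estimated from the lowest decile of
  nuclei (ranked by mean signal): the traces are corrected by the
  background mean, and the threshold is 4 background SDs.  The multiplier
  is 4 rather than the more conventional 3 because with ~1700 nuclei and
  100 time points per embryo a 3-SD cut admits roughly two false active
  calls per frame, and even one false call in the final frame can bridge
  the gap between adjacent stripes in the clustering step below; at 4 SD
  the expected number of false calls per frame is ~0.05.  Both the
  multiplier (`sd_mult`) and the threshold itself are overridable, and
  every run logs the threshold actually used.
* **mRNA output and amplitude.**  Per-nucleus mRNA production is the
  trapezoidal integral of the fluorescence trajectory over normalized
  time, on the observed support only (`mrna_output`); units are
  a.u. × normalized NC14.  Transcriptional amplitude is output divided by
  the active duration expressed as a fraction of NC14, so a constant
  always-active trace of height *c* has amplitude *c* (fluorescence
  units).  An alternative convention divides by the raw grid-point count;
  we use the fluorescence-unit form because it is directly comparable to
  the loading amplitude of the burst model.
* **Mature stripes and domains.**  Nuclei active in the last frame before
  gastrulation define the mature stripes: their AP positions are sorted
  and split where consecutive gaps exceed 2 internuclear spacings
  (configurable), clusters of fewer than 3 nuclei are discarded, and
  stripes are numbered anterior to posterior.  Each stripe's *domain*
  runs from its anterior border to the next stripe's anterior border
  (the last runs to the posterior end), so the domains tile the trunk and
  every active nucleus belongs to exactly one stripe.
* **Boundaries, width, position.**  The DV window is divided into five
  equal sections.  Per section and time point, the most anterior and most
  posterior active nuclei of a stripe mark its boundaries; the boundary
  position is the mean over sections containing active nuclei (empty
  sections are omitted rather than propagating NA).  Width is posterior
  minus anterior (%EL, convertible to nuclei via the internuclear
  spacing); position is the midpoint of the two boundaries.  The paper
  trail behind "position" is ambiguous (anterior border, centroid and
  midpoint are all plausible); the midpoint is used because it responds
  symmetrically to changes at either edge.
* **Summaries.**  Mature-stripe width and position are averaged over
  normalized time points 0.80-0.90; the transient stripe-2 expansion is
  the largest heterozygote-minus-wild-type difference in cohort-mean
  width over the mid-NC14 window 0.40-0.70; aligned per-stripe output
  profiles integrate time points 0.61-0.70, re-origin each embryo at its
  anteriormost stripe nucleus, and drop 1 %EL bins with fewer than 10
  pooled nuclei.
* **Kinetics.**  Activation onset is the first normalized time at which
  at least 10% of a domain's nuclei are active (the curves rise steeply,
  so the delay estimate is insensitive to this fraction within a frame or
  two); onset delays are reported in minutes.
* **Cohort statistics.**  Width/position error bars are mean ± s.e.m.
  across embryos.  Per-nucleus cumulative outputs of ever-active nuclei
  within the mature stripe are pooled across embryos and compared with a
  two-sample Student's t-test (pooled variance; Welch optional).  The
  cross-embryo coefficient of variation is computed per 2 %EL bin on
  per-embryo cumulative output (the exact quantity behind published CV
  curves is not fully specified; cumulative output is the stable choice
  and other quantities can be binned the same way).  No multiple-testing
  correction is applied across stripes.
* **FISH profiles.**  Single-frame images use the middle 40 pixel rows,
  1 %EL bins, and subtraction of the lowest binned value whose bin center
  lies in 10-90 %EL (per embryo); bins outside that range may go
  negative and are reported as-is.

## The synthetic-embryo generator

The generator (`embryo_sim`, `simulate_traces`) emulates the study
conditions rather than the full physics of an embryo:

* **Geometry.**  A monolayer lattice: by default 100 nucleus columns
  along a 500 µm AP axis and 17 rows across the 282 µm DV window, imaged
  every 61 s over a 3050 s NC14.  One column is exactly 1 %EL, so planted
  effect sizes stated in "nuclei" are exact on the grid; the lattice is
  therefore anisotropic (5 µm AP vs 16.6 µm DV spacing), a deliberate
  bookkeeping choice with no effect on the pipeline, which never assumes
  isotropy.
* **Transcription.**  Each stripe is a two-state telegraph promoter:
  exponential ON/OFF switching (defaults `k_on = 0.1/s`,
  `k_off = 0.02/s`, stationary occupancy 0.83), constant loading
  amplitude (100 a.u.) while ON, plus a constant baseline (10 a.u.,
  emulating camera offset/autofluorescence) and additive Gaussian noise
  (SD 5 a.u.) clipped at zero.  States are sampled exactly at frame times
  from the closed-form two-state transition probabilities with
  piecewise-constant rates, so stationary occupancy is analytically
  checkable.  The baseline keeps the clipped noise floor approximately
  Gaussian, which is what makes the decile background estimator unbiased.
* **Stripes.**  Seven stripes, 4 %EL wide, centers 8 %EL apart from 28 to
  84 %EL, switching on sequentially between normalized times 0.08 and
  0.25.  Each embryo draws a uniform ±0.5 %EL rigid displacement per
  stripe (embryo-to-embryo variability); without it, grid quantization
  would bias cohort-mean boundary differences.
* **Genotype presets.**  The Kr-heterozygote preset plants the reported
  effects directly in the stripe rules: a transient posterior expansion
  of stripe 2 peaking at 1.6 nuclei around mid-NC14 (triangular time
  course on normalized time 0.35-0.75); stripes 3 and 4 narrowed by
  0.9 nuclei with loading amplitudes scaled by 0.75 and 0.70; stripe 4
  shifted 1 nucleus anterior, delayed 360 s, and made sporadic
  (on-rate × 0.75); stripe 5 shifted 3 nuclei anterior.  Stripe 3 narrows
  from its posterior edge only.  The same regulatory logic is also
  encoded redundantly as logistic gap-gene-like fields (`gap_profile`:
  Kr halved exactly, the posterior *gt* and *kni* domains shifted
  anteriorly, anterior *hb* reduced) with a repression rule mapping
  weighted regulator concentrations to burst propensity (`stripe_rate`);
  the direct deltas are the default because they give an unambiguous
  recovery target.  Wild-type embryos additionally express a posterior
  PP7 reporter (70-96 %EL), which is how genotypes are classified.
* **Rendering.**  `render_frames` draws already-max-projected 2D frames:
  filled discs in the nuclei channel and one Gaussian punctum
  (σ = 3 px) per transcribing nucleus whose peak equals the trace value,
  quantized to the pixel grid so the top-2-pixel readout recovers the
  peak to within ~3%.  Nuclei must not overlap (the renderer refuses
  radii above half the internuclear spacing).

What the generator does **not** emulate: nuclear divisions and packing
rearrangements, photobleaching, depth-of-field and z-resolved spot
structure, mitotic waves, tile stitching, spatial gradients in noise, or
any mechanistic coupling from the regulator fields to the planted effect
sizes (the effects are planted, not derived from the network).  Passing
recovery tests therefore demonstrates that the *quantification* is
correct and unbiased at realistic noise levels -- not that the biology of
real embryos is this simple.

## Numerical choices and degenerate inputs

Linear interpolation for time normalization (exact on piecewise-linear
signals, idempotent on its own output); trapezoidal integration; strict
inequality with ties inactive at thresholds; half-open intervals with
closed right ends for bins and stripe domains; boundary sections with no
active nuclei omitted from the five-section mean; an all-empty time point
is NA; zero active nuclei at the last frame is an error ("no mature
stripes"); a label with no pixels is a corrupted mask and errors; a blank
image segments to zero labels without error; amplitude is NA for
never-active nuclei while their sub-threshold signal still integrates to
a (small) output.

## Validation strategy and problem sizes

The test suite validates each operation against independently coded
brute-force oracles (top-2-pixel readout, binning, CV, per-section
boundaries, trapezoid, interpolation, gap-splitting, background
subtraction), checks the pipeline constants (50 bins, 100 time points,
5 sections, 282 µm, 10-nucleus bin exclusion), and exercises three
recovery surfaces: exact boundary and amplitude recovery on noise-free
step-edged embryos; recovery of all planted genotype effects from
10 + 10 embryo cohorts at default noise; and an end-to-end image path
(simulate, render, segment, track, measure) on sparse lattices.  The
t-test is calibrated on 500 null cohort pairs built from a compact
single-stripe lattice (15 × 4 nuclei, 31 frames), where the rejection
rate at α = 0.05 must fall in 5% ± 2%.  These sizes were chosen as the
smallest that leave the statistics stable.

## Known limitations

Segmentation is a deliberately simple blur/Otsu/connected-components
chain suited to non-overlapping synthetic nuclei; real movies should come
in as pre-extracted trace tables (`read_traces`).  Tracking is greedy
nearest-neighbour with no gap closing, appropriate only because
blastoderm nuclei barely move between 61 s frames.  The top-2-pixel
readout is restricted to the nuclear mask; implementations that search a
dilated neighbourhood will differ slightly.  Whether output integration
should run on raw frames instead of the normalized grid is not settled;
the normalized grid is used for consistency with every reported time
axis, and on linear interpolants the two differ only through frame-edge
effects.
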