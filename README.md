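# stripedyn

Quantification of pair-rule stripe transcription dynamics from MS2/MCP
live imaging of the *Drosophila* blastoderm.

During nuclear cycle 14 (NC14), *even-skipped* (*eve*) resolves into seven
anterior-posterior stripes whose boundaries are positioned by gap-gene
repressors.  MS2/MCP imaging shows nascent transcription as a nuclear
punctum, so the formation of each stripe can be measured nucleus by
nucleus.  `stripedyn` turns per-nucleus fluorescence traces (or rendered
two-channel time-lapse stacks) into the quantities used to compare
wild-type embryos with *Kr* heterozygotes — for example, the transient
posterior expansion of stripe 2, the anterior shift of stripe 5, and the
narrowing, delay and reduced mRNA output of stripes 3 and 4 under halved
*Kr* dosage.  It is aimed at quantitative developmental biologists
analyzing blastoderm live-imaging experiments, and ships a
synthetic-embryo generator so the entire pipeline is testable against
planted ground truth without any microscopy data.

## What it computes

For each embryo, with positions in % egg length (%EL, anterior = 0) and
time normalized to 100 points over NC14 (t = 0 end of 13th mitosis,
t = 1 gastrulation):

* per-nucleus traces restricted to a 282 µm dorsoventral window,
  background-corrected, with active calls `F(t) > θ` (θ = background
  mean + 4 SD by default);
* cumulative mRNA output `M = ∫ F(t) dt` (trapezoid over normalized
  time), active duration, and transcriptional amplitude
  `A = M / (active fraction of NC14)`;
* mature stripes from the nuclei active in the last frame
  (1-D gap clustering), and stripe domains tiling the trunk;
* per-stripe boundary tracks: anterior/posterior = mean over five DV
  sections of the extreme active nuclei, width = posterior − anterior
  (in %EL and nuclei), position = midpoint, summarized over time points
  80–90;
* activation kinetics (fraction of domain nuclei active; onset = first
  crossing of 10%), 50 × 2 %EL spatial profiles, and aligned per-stripe
  output profiles (time points 61–70, 1 %EL bins, bins with < 10 pooled
  nuclei dropped);
* cohort comparisons: genotype classification from the posterior PP7
  reporter, cross-embryo coefficient-of-variation profiles
  (CV = SD/mean per bin), mean ± s.e.m. width/position, onset delays,
  the mid-NC14 stripe-2 expansion metric, and pooled-variance Student's
  t-tests on per-nucleus output;
* FISH images: middle-40-pixel band, 1 %EL bins, subtraction of the
  10–90 %EL minimum.

The synthetic generator simulates bursty transcription with a two-state
telegraph promoter (exponential switching, constant loading while ON) on
a nucleus lattice, with wild-type and *Kr*-heterozygote presets carrying
planted effect sizes, and can render the traces into 2-channel image
stacks for the segmentation/tracking path.

## Worked example

Simulate 10 wild-type and 10 *Kr*-heterozygous embryos under the default
presets, run the full pipeline on each, and compare the cohorts:

```r
library(stripedyn)
res <- run_pipeline(run_config(seed = 11, n_wt = 10, n_het = 10,
                               log_level = "quiet"))
print(res$report)
#> Genotype comparison: 10 wild-type vs 10 Kr-het embryos
#> Transient stripe-2 expansion: 1.30 nuclei
#> stripe 1: width 2.99 vs 3.00 nuclei (deficit -0.01); shift -0.00 nuclei; delay 0.0 min; t=-0.2 p=0.847
#> stripe 2: width 3.00 vs 2.99 nuclei (deficit 0.01); shift 0.00 nuclei; delay 0.0 min; t=-2.8 p=0.00586
#> stripe 3: width 2.99 vs 2.09 nuclei (deficit 0.90); shift 0.45 nuclei; delay 0.0 min; t=67.0 p=0
#> stripe 4: width 2.99 vs 2.09 nuclei (deficit 0.90); shift 0.75 nuclei; delay 6.2 min; t=105.8 p=0
#> stripe 5: width 3.00 vs 3.00 nuclei (deficit -0.00); shift 3.00 nuclei; delay 0.0 min; t=-1.9 p=0.0569
#> stripe 6: width 3.00 vs 3.00 nuclei (deficit 0.00); shift 0.00 nuclei; delay 0.0 min; t=-1.1 p=0.279
#> stripe 7: width 3.00 vs 3.00 nuclei (deficit 0.00); shift 0.00 nuclei; delay 0.0 min; t=-1.7 p=0.0897
```

Reading this: each line compares wild-type vs heterozygote mature
stripes.  The heterozygote cohort recovers the planted effects — stripes
3 and 4 are ~0.9 nuclei narrower with massively reduced per-nucleus
output (pooled-variance t, p < 0.0001), stripe 4 activates ~6 min late,
stripe 5 sits 3 nuclei closer to the anterior tip, and stripe 2 shows a
transient mid-NC14 expansion (peak cohort difference 1.3 nuclei here,
against a planted peak of 1.6) that has vanished by the late-NC14 summary
window, where its width matches wild type.  Unperturbed stripes 1, 6 and
7 show null differences.

Per-embryo analysis of a single trace table (simulated here; real data
enter the same way via `read_traces()`):

```r
tr  <- simulate_traces(embryo_sim("wt", seed = 1))
rec <- analyze_embryo(tr)      # DV window, normalization, stripes,
print(rec)                     # boundaries, kinetics, metrics, profile
#> Embryo record (wt): 1700 nuclei, 7 stripes, threshold 19.1
```

A thin command-line wrapper (`inst/cli/stripedyn`) exposes
`simulate`, `quantify`, `demo` and `fish` subcommands over the same
functions.

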