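Package: stripedyn
Title: Quantification of Pair-Rule Stripe Transcription Dynamics from
    MS2 Live Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the transcriptional dynamics of
    pair-rule stripes in the Drosophila blastoderm from MS2/MCP (and
    PP7/PCP) live-imaging data: nucleus segmentation and tracking on
    two-channel time-lapse stacks, per-nucleus spot quantification,
    normalized developmental-time alignment over nuclear cycle 14,
    egg-length binning, mature-stripe definition, boundary and width
    tracking via dorsoventral sections, activation kinetics, cumulative
    mRNA output, cross-embryo variability profiles, and wild-type versus
    Kr-heterozygote cohort comparisons.  Includes a synthetic-embryo
    generator (telegraph-model bursting on a nucleus lattice with
    gap-gene-like regulator fields and genotype presets) so that every
    pipeline stage can be validated against planted ground truth, plus
    quantification of single-frame FISH intensity profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
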