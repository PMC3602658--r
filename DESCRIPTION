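Package: localmotif
Title: Detection of Locally Enriched Transcription Factor Binding Sites
    in Promoter Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects regions around transcription start sites (TSSs) in
    which predicted transcription factor binding sites (TFBSs) are locally
    over-represented within a set of co-regulated promoters.  Site
    positions are converted into a continuous local enrichment score by a
    Parzen-window (Gaussian or uniform kernel) estimator with a
    zero-or-one-occurrence-per-sequence (ZOOPS) normalization, and the
    significance of peaks is evaluated against GC-content-matched sets of
    promoters resampled from a genomic background, yielding empirical
    position-dependent and position-independent p-values.  Also provides
    width-dependent region calling with redundancy removal, a global
    Over-Representation Index (ORI) with its resampling p-value, weak-site
    enrichment and conservation Z-score tests, PWM scanning of JASPAR and
    TRANSFAC matrices, and a synthetic promoter-universe generator with
    controlled GC structure and motif implantation for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
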