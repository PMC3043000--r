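Package: circaseq
Title: Circadian ChIP-Seq Binding-Site Deconvolution, Rhythm Statistics and
    Tandem E-Box Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for time-resolved transcription-factor ChIP-Seq,
    built around circadian designs (six timepoints at 4-h intervals over one
    light-dark cycle). Provides strand-model deconvolution of tag profiles
    into point binding sites, an exact Fisher specific-period rhythmicity
    test with amplitude and phase estimation, circular-phase statistics
    including a Rao equality-of-dispersions test, a weighted hidden Markov
    model of tandem E-box (E1-E2) elements with variable spacer, nearest-TSS
    site annotation with conservation scoring, and MARA-style inference of
    motif activities from expression time series by conservation-weighted
    least squares. A synthetic-data module generates toy genomes, planted
    motif sites, strand-specific circadian ChIP tags and matched expression
    matrices with known ground truth, so the full pipeline can be exercised
    end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
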