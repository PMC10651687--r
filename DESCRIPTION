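Package: clockprot
Title: Classification of Clock-Dependent Proteomes from Multiplexed TMT Experiments
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing multi-plex TMT (tandem mass tag) tissue
    proteomes from circadian genetic-rescue designs. Provides pooled-reference
    normalization across plexes, Perseus-style feature filtering, PCA quality
    control with parametric outlier flagging, pairwise differential abundance
    with Benjamini-Hochberg FDR control, multi-contrast decision rules that
    classify proteins as clock-dependent, rescued or feeding-responsive,
    two-group cosinor (harmonic regression) rhythmicity and mean-model
    selection by BIC weights for diurnal transcriptomes,
    proteome-transcriptome concordance summaries, hypergeometric
    overrepresentation analysis, and a synthetic-data generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
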