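Package: focalDrivers
Title: Driver-Gene Prioritization from Focal and Recurrent Somatic Alterations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate cancer driver genes across a tumor cohort by
    integrating segmented somatic copy-number calls with point-mutation
    calls. Each alteration event is modeled as a lesion (an amplitude plus
    the set of genes it covers) and two Bayesian posteriors are computed per
    sample: a recurrence score, which spreads weight over all altered genes,
    and a focality score, which concentrates weight on genes in small
    lesions. Per-sample posteriors are aggregated over the cohort, optionally
    iterated to an empirical-prior fixed point with a Kullback-Leibler
    stopping rule, combined multiplicatively, and integrated with a
    recurrent-mutation score. Ranked genes are stratified into
    entropy-defined tiers and grouped into contiguous genomic regions, each
    labeled with its highest-scoring leader gene. Includes a
    synthetic-cohort generator with implanted drivers for end-to-end
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'geneModel.R'
    'alterationInput.R'
    'lesions.R'
    'scoring.R'
    'priorFixedPoint.R'
    'tiers.R'
    'regions.R'
    'synthetic.R'
    'pipeline.R'
    'cli.R'
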