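Package: evopop
Title: Whole-Population Sequencing Analysis for Laboratory Evolution Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for analysing whole-population, whole-genome time-series
    sequencing from long-term microbial evolution experiments. Filters
    per-variant allele-depth tables into credible mutations, groups linked
    variants, and calls presence, fixation and loss of heterozygosity over
    time in haploid and diploid populations; detects copy-number variants
    from windowed read depth with a fixed-parameter Gaussian hidden Markov
    model; quantifies genetic parallelism (gene multiplicity, multi-hit
    genes) and historical contingency (strain/environment enrichment,
    pairwise mutual information, over-dispersion) against simulation-based
    null models; estimates competitive fitness from fluorescent-reference
    competition assays and mutation rates from fluctuation assays via the
    Ma-Sandri-Sarkar maximum-likelihood estimator. A synthetic-data module
    generates every input the pipeline consumes, with planted ground truth,
    for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
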