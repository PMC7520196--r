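Package: haremark
Title: Noninvasive Genetic Monitoring of Hare Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for noninvasive genetic capture-mark-recapture
    monitoring from replicated microsatellite genotypes of fecal samples:
    multi-tube consensus genotype calling with sex determination, genotyping
    error quantification (missing replicates, false homozygotes), individual
    identification by mismatch-tolerant genotype clustering, per-locus
    population-genetic summaries (heterozygosity, PIC, probability of
    identity, Hardy-Weinberg tests), maximum-likelihood robust-design
    capture-mark-recapture with misidentification (ghost genotypes), AICc
    model ranking and model averaging with derived abundance, density and
    sex ratio, and PCA-based species assignment against a labeled tissue
    reference panel. Includes a synthetic-data generator reproducing the
    statistical structure the downstream analysis assumes, with ground
    truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
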