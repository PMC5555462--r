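Package: rcscan
Title: Genome Scans for Quantitative Traits in Recombinant Congenic Strain Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of quantitative-trait genome scans in
    recombinant congenic strain (RCS) panels of inbred mice. Provides an
    explicit breeding-scheme simulator (Haldane meiosis, backcrossing,
    sib-mating to fixation) for AcB/BcA-style panels and chromosome
    substitution strains, QTL-driven log-normal phenotype generation,
    strain-level summary statistics with many-to-one Dunnett and Bonferroni
    comparisons, a marker-by-marker linear-regression scan of log2 strain
    means on parental-origin genotype, permutation-derived genome-wide
    significance thresholds, contiguous-marker region delimitation, Manhattan
    plots, and tab-separated input/output for genotype, phenotype and marker
    map tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mvtnorm,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr
Config/testthat/edition: 3
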