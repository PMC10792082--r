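Package: oralgut
Title: Oral-Gut Microbiota Overlap and Marker-Gene Strain Consistency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of species-level overlap between paired stool and oral
    shotgun metagenomic samples from the same individuals. Computes pairwise
    overlap frequencies between stool and each of four oral sites (saliva,
    buccal mucosa, supragingival plaque, tongue dorsum) after prevalence
    filtering of relative-abundance tables, compares fecal versus oral
    abundances of overlapping species with a paired Wilcoxon signed-rank test
    and Benjamini-Hochberg correction, and calls individuals whose stool and
    oral samples carry identical clade-specific marker-gene presence/absence
    patterns, consistent with same-strain colonization. Ships a seeded
    synthetic paired-cohort generator (niche-adapted species pools, sparse
    log-normal relative abundances, strain repertoires perturbed by gene
    gain/loss, depth-dependent marker dropout, planted shared-strain
    individuals) so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
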