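Package: prevderep
Title: Prevalence-Ranked Genome Dereplication and k-mer Classification for
    Gut Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds prevalence-ranked, dereplicated genome collections for
    human gut metagenomics and profiles metagenomes against them. Candidate
    genomes are screened for containment in a panel of gut metagenomes using
    bottom-s MinHash sketches of canonical k-mers, scored by their mean
    screen identity across the panel, and dereplicated by a greedy
    rank-ordered clustering with a coarse sketch-distance pre-filter and
    fragment-based average nucleotide identity confirmation at two
    resolutions. Near-duplicate metagenome samples are removed per project
    by complete-linkage clustering with medoid retention. A lowest-common-
    ancestor k-mer classifier with exact per-taxon unique-k-mer accounting,
    a depth-scaled unique-k-mer false-positive filter, and Bayesian
    species-level read redistribution profiles samples against the
    collection. Downstream community statistics include core-species
    prevalence, centered log-ratio transformation with PCA ordination,
    project-level average-linkage clustering, and genome-accumulation
    curves. Seeded simulators for genomes, strain variants, taxonomies and
    read sets provide a fully reproducible test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    ape,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
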