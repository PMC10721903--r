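Package: icevir
Title: Viral Ecogenomics of Cellular Metagenomes from Ice-Covered Oceans
Version: 0.1.0
Authors@R:
    person("RIS", "Viromics", email = "icevir@example.org", role = c("aut", "cre"))
Description: Tools for mining viral genomes out of cellular metagenomes,
    metatranscriptomes, MAGs and SAGs when no virome is available: multi-round
    triage of candidate viral contigs (length, hallmark-gene, host:viral gene
    ratio and origin-score rules), protein- and genome-level gene-sharing
    networks (hypergeometric similarity plus Markov clustering), VIRIDIC-style
    intergenomic similarity with ICTV-style genus/species demarcation,
    fragment-recruitment abundance and activity profiles normalised as
    recruited kilobases per genome kilobase per gigabase (KPKG), multi-evidence
    virus-host assignment (CRISPR spacer-protospacer, shared tRNA, k-mer Markov
    log-likelihood, codon usage, auxiliary metabolic genes, binning
    co-occurrence), Kyte-Doolittle hydropathy, and a lifestyle summary. A
    fully seeded synthetic-community generator with planted ground truth makes
    every stage testable end to end without external data or tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    data.table,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
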