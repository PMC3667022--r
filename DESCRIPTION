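Package: txmine
Title: Digital Gene Expression, Enrichment and EST-SSR Mining for De Novo Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-library RNA-seq analysis of de novo transcriptome
    assemblies without a reference genome: k-mer seeded read-to-unigene
    assignment with a mismatch budget, RPKM normalization, the Audic-Claverie
    exact test for two-library differential expression with
    Benjamini-Hochberg false discovery control, hypergeometric term
    over-representation with Bonferroni or FDR correction, perfect
    microsatellite (EST-SSR) detection with canonical motif classification
    and marker-locus selection filters, six-frame open reading frame triage
    of putative coding unigenes, and a seeded synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    Rcpp,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
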