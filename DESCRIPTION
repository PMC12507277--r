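Package: clustkmer
Title: Alignment-Free Assignment of Metagenomic Reads to Protein Clusters
    via Amino-Acid k-mer Frequencies
Version: 0.1.0
Authors@R:
    person("clustkmer", "developers", email = "clustkmer@example.org",
           role = c("aut", "cre"))
Description: Builds a two-level amino-acid k-mer frequency model over
    clusters of homologous proteins and assigns nucleotide sequencing
    reads to a single cluster by six-frame translation and cumulative
    k-mer frequency scoring. Includes a k hyperparameter selection
    protocol based on simulated protein truncations, simulators for
    mutation-bearing reads with truth labels (binomial per-base rates and
    guaranteed amino-acid changes), segmenters for unseen proteins via
    stop-avoiding reverse translation, and evaluation statistics:
    accuracy/coverage, multimap resolution, agreement against external
    aligner hit tables, per-cluster concordance, keyword homogeneity, and
    ROC-based score thresholding.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
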