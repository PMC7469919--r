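Package: tdfe
Title: Tensor-Decomposition-Based Unsupervised Feature Extraction for
    Multi-Tissue Drug-Response Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised selection of drug-responsive, tissue-group-specific
    genes from gene x tissue x treatment x replicate count tensors.  Counts
    are standardized per sample, decomposed by higher-order singular value
    decomposition (HOSVD, Tucker form), and gene-mode singular vectors are
    chosen through the core tensor; genes are then assigned chi-squared
    P-values from their standardized loadings, corrected by the
    Benjamini-Hochberg criterion, and thresholded.  Includes per-tissue
    count-table input/output, a planted-signal synthetic count generator
    with retained ground truth, pooled two-group validation tests, gene-set
    overlap summaries, and an end-to-end pipeline driver with a
    reproducible run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
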