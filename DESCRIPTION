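Package: hearsel
Title: Branch-Site Tests of Positive Selection and Accelerated-Region
    Annotation for Hearing-Loss Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A screening pipeline for lineage-specific adaptive evolution in
    gene panels, built around the Goldman-Yang codon substitution model.
    Implements maximum-likelihood fits of the one-ratio (M0) model and the
    branch-site Model A test of positive selection on a labelled foreground
    branch, likelihood-ratio testing against chi-square with one degree of
    freedom, Benjamini-Hochberg FDR control across genes, and Bayes empirical
    Bayes posterior identification of positively selected sites.  A second
    arm classifies accelerated noncoding regions and assigns them to genes by
    gene body, GREAT-style regulatory domain, or topologically associating
    domain.  Includes simulators for codon alignments, ortholog tables and
    genome annotations with machine-readable ground truth, used to validate
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
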