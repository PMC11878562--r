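Package: lcrsurvey
Title: Low-Complexity Region Detection, Classification and Enrichment Statistics for Protein Sets
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects low-complexity regions (LCRs) in protein sequences with an
    entropy-based segmentation algorithm (sliding-window Shannon entropy with
    trigger/extension thresholds, region merging and minimum-probability
    refinement), classifies detected regions as homopolymeric or complex, by
    protein-domain overlap and by relative position along the protein, and
    computes amino-acid composition profiles, observed/expected category
    enrichment, chi-squared contingency tests and Pearson correlations over
    proteome sets. Ships a synthetic proteome generator with recorded ground
    truth so the whole pipeline is testable without external data, plus
    readers for FASTA, pfam_scan, pfam2go, TMHMM and SignalP summary tables
    and an integrated per-protein dataset writer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
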