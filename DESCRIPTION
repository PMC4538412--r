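Package: fluorosnc
Title: Short Noncoding RNA Analysis for Fluoride-Exposed Osteoblast-Lineage Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for short noncoding RNA responses to sodium
    fluoride exposure: microarray probe-intensity normalization (background
    adjustment, quantile normalization, median-polish summarization) and
    one-way ANOVA screening with signed fold-change cuts; C/D-box snoRNA
    sequence features (UGAUGA/CUGA motif scanning with terminal/internal
    classification, UG/CG dinucleotide counts, interquartile-range length
    outlier detection, Kimura two-parameter distances over globally aligned
    pairs); relative quantification of qPCR data by the delta-delta-Ct method
    with multi-reference normalization and signed fold-change reporting; LC50
    interpolation from dose-viability curves; and canonical miRNA seed-site
    scanning of UTR sequences (6mer, 7mer-A1, 7mer-m8, 8mer). A synthetic-data
    module generates probe matrices, snoRNA sequence sets, Ct tables and
    viability curves with known ground truth so every stage is testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    ape,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
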