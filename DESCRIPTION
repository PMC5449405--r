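Package: foldspec
Title: Fold-Change-Specific Functional and Motif Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stratifies directional lists of differentially expressed genes
    into fold-change quantiles, enumerates contiguous quantile intervals, and
    tests gene-set (GO term) and promoter-hexamer enrichment within specific
    fold-change windows using a two-step Fisher exact procedure with
    Bonferroni family-wise control: step one tests over-representation of a
    term or motif within an interval against a genome-wide background, step
    two tests fold-change specificity of the selected terms or motifs against
    the whole directional gene list. Includes strand-aware promoter
    extraction, canonical (reverse-complement-collapsed) hexamer scanning,
    readers for annotation formats (two-column TSV, GAF 2.x, minimal OBO with
    ancestor propagation), and a synthetic-data generator that plants
    fold-change-specific structure with known ground truth for type-I-error
    and parameter-recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    graphics,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
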