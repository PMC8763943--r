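Package: micromodal
Title: Multimodal Deep Learning Classification of Host Phenotype from
    Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds three feature modalities from shotgun metagenome
    derived inputs - taxonomic clade profiles, genome-level contig
    abundance (RPKM with breadth-of-coverage filtering), and KEGG
    ortholog functional abundance - and classifies host disease status
    with a two-stage multimodal feedforward neural network (per-modality
    encoders, embedding concatenation, fusion classifier) evaluated by
    leave-one-out cross-validation. Includes read preprocessing rules
    (quality trimming, N removal, host-read classification), parsers for
    MetaPhlAn-style profiles, SAM alignments and BLAST/DIAMOND tabular
    hits, a synthetic-data generator with ground-truth bookkeeping for
    end-to-end verification, ROC/AUC computation and ensemble voting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    GenomicAlignments,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
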