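Package: clonotrack
Title: Tandem Single-Cell and Bulk TCR Repertoire Clonotype Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tracks antigen-specific T cell receptor (TCR) beta-chain CDR3
    clonotypes, identified in sorted single cells, into bulk-sequenced
    peripheral CD4+ T cell repertoires (true naive, central memory,
    regulatory and stem-cell-like memory subsets). Computes nucleotide- and
    amino-acid-level tracking rates, clonotype convergence (the number of
    distinct nucleotide rearrangements encoding one amino-acid CDR3),
    publicity categories across individuals, cohort-exclusive clonotype
    sets and sequence-feature summaries. Also provides clonal-expansion
    detection among single cells, single-cell qPCR preprocessing (Ct to
    expression), two-part hurdle-model marker testing with Bonferroni
    correction, graph-based expression clustering, per-cluster cohort
    composition tests, ELISPOT stimulation-index scoring, activation-induced
    marker phenotype gating, and a synthetic paired single-cell/bulk data
    generator with a planted-truth manifest for end-to-end validation.
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
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
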