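Package: cfhl
Title: Cell-Free DNA Profiling and Circulating Tumor DNA Tracking in
    Classic Hodgkin Lymphoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tumor-naive molecular profiling of cell-free DNA (cfDNA) for
    classic Hodgkin lymphoma. Merges per-sample output of multiple somatic
    variant callers into consensus calls, applies a panel-of-normals and
    annotation-based filter cascade with a per-variant audit trail, derives
    copy-number summaries (fraction of genome altered, estimated tumor
    fraction) from bin-level log2 ratios, quantifies circulating tumor DNA
    in haploid genome equivalents per mL plasma, tracks variants across
    longitudinal samples for residual-disease monitoring, and performs
    supervised EBV/SOCS1 cluster comparisons with rank-based statistics.
    Ships a synthetic-cohort generator with full ground truth so every
    stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    vcfR,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
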