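Package: cinscores
Title: Karyotypic Complexity Scoring and Pan-Cancer Chromosomal Instability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-sample karyotypic complexity scores from segmented
    absolute somatic copy-number profiles: the numerical complexity score
    (NCS, whole-chromosome gains/losses relative to integer ploidy), the
    structural complexity score (SCS, intra-chromosomal segments deviating
    from the chromosome modal copy number) and the weighted genome
    instability index (WGII). Provides readers for TCGA-dialect SEG files
    and ABSOLUTE-style ploidy tables, a synthetic pan-cancer cohort
    generator with planted ground truth, cohort-adjusted association
    screens (Spearman, recurrence filtering, OLS alteration regression
    with Benjamini-Hochberg FDR), median-stratified Kaplan-Meier/log-rank
    and Cox survival analysis, responder rank tests, and a drug-sensitivity
    index with candidate-compound selection from dose-response AUC screens.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    survival,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
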