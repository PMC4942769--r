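Package: netrank
Title: Cross-Species Biomarker Selection via PageRank on miRNA-mRNA
    Correlation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects candidate disease biomarkers from paired miRNA and mRNA
    expression profiles of a multi-condition animal experiment and validates
    them on independent case/control cohorts. Differentially expressed mRNAs
    (one-way ANOVA across experimental conditions) are linked to miRNAs by
    significant negative Pearson correlation to form a weighted bipartite
    regulatory network; nodes are scored by weighted PageRank and the
    top-ranked mRNAs form the biomarker panel. Panels are evaluated by
    two-cluster average-linkage hierarchical clustering of validation cohorts,
    against a differential-expression baseline ranking. Includes a synthetic
    paired-expression generator with planted negatively regulated hub genes
    and training-specific decoy genes for end-to-end benchmarking, plus
    readers for tab-delimited expression matrices, phenotype tables and
    probe-to-gene maps, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
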