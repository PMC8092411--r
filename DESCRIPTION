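Package: tempomics
Title: Temporal Multi-Omics Analysis of Drug-Induced Stress Buildup and Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how cancer cells build up and resolve
    drug-induced stress over a multi-day time course, profiled at the
    transcript, protein and metabolite level. Provides per-timepoint
    deregulation calling with an empirical-Bayes moderated t-statistic,
    similarity-graph construction from temporal response profiles,
    multiscale Markov stability community detection with robustness
    selection across Markov times, rank-based single-sample gene-set
    enrichment, metabolite exchange-rate estimation from supernatant
    concentrations and viable-cell densities, and derivation and
    tumor-projection of gene-expression signatures of genetic dependency
    from CRISPR screen data. A synthetic-data module generates
    time-course studies, supernatant series and dependency cohorts with
    known ground truth so that every stage of the pipeline can be tested
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
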