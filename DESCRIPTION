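Package: memoryscreen
Title: Multi-Gradient Permutation Survival Screening for Steadily Prognostic Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a multi-gradient permutation survival screen (MEMORY) that
    identifies genes steadily associated with prognosis (GEARs) from a TPM
    expression matrix and right-censored survival data: repeated subsampling at
    increasing cohort fractions, median-split Mantel-Haenszel log-rank testing,
    a significance-probability matrix with saturation detection, a
    survival-analysis-similarity (SAS) core survival network with degree-based
    hub-gene selection, hub-gene molecular subtyping by Ward hierarchical
    clustering, tumor mutation burden and differential-mutation comparison
    between subtypes, and mutant-versus-wild-type CRISPR dependency scoring.
    Includes a synthetic cohort generator with planted proportional-hazards
    effects so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
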