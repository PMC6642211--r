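Package: structint
Title: Structure-Driven Protein Interactivity of RNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the relationship between the secondary-structure
    content of RNA molecules and the number of proteins they interact with.
    Aggregates per-nucleotide structure-probing evidence (PARS-type nuclease
    reads, DMS reactivities, predicted per-nucleotide scores) into
    transcript-level structural-content scores; filters CLIP peak tables and
    counts unique protein binders per transcript; fits exponential and
    reciprocal models linking structural content to binder counts; computes
    normalized intra-RNA and RNA-protein contact statistics from 3D complex
    coordinates; analyses ribonucleoprotein condensate remodelling from
    label-free-quantification proteomics (differential tests,
    released/kept/static classification, stringency tiers, ROC evaluation);
    and scores protein sequences on amino-acid property scales. A synthetic
    data generator with planted ground truth makes the whole pipeline testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    Biostrings,
    bio3d
Suggests:
    jsonlite,
    pROC,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
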