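Package: scnalnc
Title: Discovery of Copy-Number-Altered lncRNAs from Segmented Tumor Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for finding long noncoding RNAs under recurrent
    somatic copy-number alteration in tumor cohorts. Scores marker-level
    recurrence per direction (G-score = frequency x mean amplitude), assigns
    empirical q-values against a circular-permutation null, calls significant
    alterations at nested region/enlarged/focal levels with peel-off for
    independent co-located events, classifies alterations by the biotypes of
    contained genes, tests promoter transcription-factor enrichment by
    hypergeometric upper tail, screens alterations for direction-consistent
    tumor-versus-normal expression change, contrasts CpG methylation, and
    scores rank-based single-sample immune signatures contrasted by
    amplification status. Includes a synthetic cohort generator with planted
    ground truth so the whole screen is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
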