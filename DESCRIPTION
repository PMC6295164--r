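Package: karyocin
Title: Karyotype Calling and Copy-Number Interaction Analysis for CIN Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing how chromosomally unstable (CIN) yeast
    populations acquire complex aneuploid karyotypes. Calls whole-chromosome
    copy numbers from read-depth profiles with telomere exclusion and
    second-lowest-quartile normalization, computes cohort statistics
    (aneuploidy frequencies, DNA-content-change burden, pooled karyotype SD,
    pairwise copy-number correlations and hypergeometric co-occurrence or
    mutual-exclusivity tests), scores chromosome copy-number interactions
    (CCNIs) from double-disome colony-size matrices, builds arm-level tumor
    karyotypes from copy-number segment tables, and includes synthetic-data
    generators (a Wright-Fisher CIN adaptation simulator, Poisson read
    sampling, colony matrices and segment tables) so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
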