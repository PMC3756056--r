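Package: subtypemap
Title: Cross-Species Transfer of Breast Cancer Expression Subtypes and
    Mapping of Subtype Susceptibility Loci
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Transfers intrinsic breast-cancer subtype labels (the five
    PAM50 classes) from a labeled human reference cohort to unlabeled
    tumors profiled on other platforms or in other species, by joint
    hierarchical co-clustering with multi-resolution tree cuts, and maps
    inherited loci associated with the derived subtype calls in backcross
    and multi-founder outbred designs.  Includes restriction of cohorts to
    an unambiguous one-to-one ortholog panel, unitization normalization of
    the merged expression matrix into [-1, 1], a nearest-centroid
    comparator classifier, exact and founder-regression genome scans with
    Benjamini-Hochberg FDR control, a subtype-metastasis independence
    test, and a synthetic-data module that emulates the statistical
    structure the analysis assumes so every stage is testable at desk
    scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
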