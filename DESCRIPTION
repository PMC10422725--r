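Package: rootmorph
Title: 3D Quantification of External Root Resorption from Longitudinal Tooth Surface Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to quantify external root resorption (ERR) between two
    imaging timepoints from segmented tooth surface meshes. Implements STL/PLY
    mesh input and output, watertight volume computation, plane cutting with
    cap generation, landmark (Kabsch) pre-alignment followed by iterative
    closest point (ICP) surface registration, cementoenamel-junction based
    root isolation, signed surface-deviation analysis with a tolerance
    matching percentage, maxillary arch expansion metrics, and the cohort
    statistics layer used in longitudinal tooth-borne versus bone-borne
    rapid maxillary expansion comparisons (Shapiro-Wilk, Levene, one-way
    ANOVA with Bonferroni post hoc, unpaired t tests, chi-square, multiple
    linear regression, intraclass correlation, power-based sample size).
    A synthetic tooth generator produces multi-rooted tooth meshes with
    simulated apical and buccal resorption of known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, car
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
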