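Package: reyscore
Title: Automated Scoring of Tablet-Recorded Rey Complex Figure Drawings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring the Rey Complex Figure copy task from a
    time-stamped pen trajectory recorded on a digitising tablet. Given a pen
    recording, a machine-readable reference figure (48 basic elements grouped
    into 18 units and 4 structures) and a stroke-to-element classification,
    the package removes global distortion with a rotation/anisotropic-scale/
    translation fit, computes 12 spatial, procedural and kinematic performance
    indices, and runs a cohort pipeline (outlier exclusion, KMO and Bartlett
    factorability checks, PCA with varimax rotation, Horn parallel analysis,
    composite SPA/PRO/KIN scores, Cronbach reliability, split-sample
    validation, partial correlation). A synthetic drawing simulator with known
    ground truth makes every stage testable without tablet data.
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
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
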