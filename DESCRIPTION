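Package: nestedfsi
Title: Nested Fluid-Structure Interaction Model of Fetal Cushioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale simulation of the nested fluid layers that cushion a
    fetus during maternal convulsive motion. Two weakly compressible smoothed
    particle hydrodynamics domains (amniotic fluid and cerebrospinal fluid)
    are coupled by penalty contact to explicit viscoelastic finite element
    solids (uterine wall, fetal body, skull, brain) arranged concentrically.
    Seizure roll kinematics matching instrumented-mannequin summary statistics
    drive the uterine wall, and the package reports the cushioning observables:
    normalized landmark-to-surface separation series, brain stress scalars
    (von Mises, mean stress, triaxiality, first deviatoric principal stress),
    and protected-versus-unprotected attenuation percentages.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    jsonlite,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
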