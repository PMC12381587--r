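Package: wingbeat
Title: Quasi-Steady Blade-Element Analysis of Flapping Flight with Body
    Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing forward flapping flight of insects whose
    bodies pitch and bob in synchrony with the wingbeat, such as wild silk
    moths. The package represents periodic wing and body kinematics as
    third-order Fourier series, extracts kinematic angles from
    three-dimensional landmark tracks, computes strip-wise quasi-steady
    aerodynamic forces (translational lift and drag, rotational, and
    added-mass components), wing inertial reaction forces, and aerodynamic
    power, and searches for trim equilibria of the wingstroke-averaged
    forces and pitch moment inside bounded parameter spaces. Comparative
    body-kinematics configurations (oscillating, averaged, and antiphase)
    quantify how body oscillations redirect aerodynamic force and change
    power requirements. A synthetic-data generator produces complete moth
    configurations and noisy landmark tracks so that every stage of the
    pipeline can be exercised without measurement data.
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
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
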