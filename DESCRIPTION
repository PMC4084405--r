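Package: swimcpg
Title: Hidden Synaptic Variability and Lesion Susceptibility in the Tritonia Swim Central Pattern Generator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico pipeline for studying how hidden animal-to-animal
    variability in the inhibitory component of the C2-to-VSI synapse of the
    Tritonia diomedea swim central pattern generator determines the
    susceptibility of the swim motor pattern to disconnection of the pedal
    commissure PdN6. Implements the first-order-kinetics artificial synapse
    used in dynamic-clamp conductance addition and subtraction, a hybrid
    integrate-and-fire model of the three-cell swim circuit with a
    two-spike-initiation-zone VSI and a commissural delay line, burst
    detection and spike-propagation classification from simulated soma and
    nerve recordings, postsynaptic-potential quantification, and the cohort
    statistics (coefficient of variation, Brown-Forsythe Levene test,
    regression, paired comparisons) used to characterise lesion
    susceptibility across virtual-animal populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
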