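Package: chondrosim
Title: Reaction-Diffusion-Delay Simulation of Cartilage Lesion Expansion and Abatement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the spread and abatement of articular cartilage lesions
    after an acute injury, driven by the balance between pro-inflammatory
    (TNF-alpha, DAMPs, reactive oxygen species) and anti-inflammatory
    (erythropoietin) cytokine signaling. Four diffusing chemical species and
    four immobile chondrocyte cell-state densities evolve on a circularly
    symmetric spatial domain as a semi-discrete system of delay-differential
    equations (method of lines with a conservative finite-volume radial
    diffusion operator), integrated by an embedded Runge-Kutta 2(3) method of
    steps with cubic dense output. Ships calibrated reference scenarios for
    the unabated-expansion and EPO-mediated-abatement regimes, lesion and
    penumbra metrics, a regime classifier, and a one-at-a-time parameter
    sensitivity protocol with qualitative response labels.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
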