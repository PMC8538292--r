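Package: ustekisim
Title: Population PK-PD Simulation of Ustekinumab in Crohn's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates serum ustekinumab, latent p40 target and fecal
    calprotectin trajectories in Crohn's disease using a two-compartment
    quasi-equilibrium target-mediated drug disposition model linked to an
    indirect-response turnover model. Provides the published covariate model
    (fat-free mass, serum albumin, prior biologic exposure, FCGR3A rs396991
    genotype, C-reactive protein), a virtual-population generator matched to
    the study cohort's covariate marginals, weight-banded induction and
    response-adaptive maintenance dosing scenarios, and a study runner that
    estimates biochemical-remission proportions (fecal calprotectin
    < 100 mg/kg) and steady-state trough exposure across dosing regimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
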