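Package: vvdadapt
Title: Kinetic Modelling of VVD-Mediated Photoadaptation in Neurospora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic kinetic model of blue-light signalling in
    Neurospora crassa, in which the photoreceptor VIVID (VVD) both inhibits
    the light-activated White Collar Complex (WCC) by sequestration and
    replenishes the light-activatable WCC pool through futile cycling of
    LOV-domain photoadducts. Provides stiff ODE simulation under
    piecewise-constant light protocols, derived observables (peak metrics,
    refractory periods, circadian phase and period, steady-state dose
    responses), a synthetic qRT-PCR time-course generator, maximum-likelihood
    and adaptive-Metropolis Bayesian parameter estimation with a two-stage
    mutant-then-wild-type fitting protocol, reproductions of the canonical
    in-silico light experiments, and SBML import/export of the reaction
    network.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
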