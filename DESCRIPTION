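Package: soilfoodweb
Title: Daily Soil Carbon, Food Web and Pore-Structure Simulation with
    Bayesian Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates daily soil carbon cycling through a nine-guild soil
    food web (bacteria, fungi, mycorrhiza, bacterivores, fungivores,
    detritivores, ecosystem engineers, herbivores, predators) coupled to a
    dynamic five-class pore-size distribution and a spilling-bucket water
    balance with macropore bypass flow. Guild growth follows Monod kinetics
    on accessible substrate, modified by temperature (Q10 with a plateau),
    moisture, pH, substrate C:N and recalcitrance. Ecosystem engineers
    create macropores and export carbon by bioturbation; dissolved organic
    matter is produced, adsorbed and leached. Guild maximum growth rates can
    be calibrated by Metropolis-Hastings random walk with reflection against
    pool-stability observations, and posterior ensembles propagated through
    single-override evaluation scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
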