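Package: lungalloc
Title: Supply/Demand-Ratio Redistricting and Offer Simulation for Lung
    Allocation Policy
Version: 0.1.0
Authors@R:
    person("Analytics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and evaluating geographic organ allocation
    policies. Local allocation units (sets of organ procurement centres
    serving one lung transplant centre) are redesigned by constrained
    enumeration of procurement-centre combinations under travel-time and
    unit-size constraints, selecting a disjoint assignment that equalises
    the supply/demand ratio across transplant centres. Includes an offer
    cascade simulator for the local/regional/national tier schemes, the
    equity metrics used to compare allocation maps, non-parametric
    competing-risks (Aalen-Johansen) and Kaplan-Meier estimators for
    waitlist and post-transplant outcomes, and a synthetic geography
    generator emulating heterogeneous procurement and demand.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    knitr
Config/testthat/edition: 3
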