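Package: meicost
Title: Monte Carlo Lifetime Costs of Middle Ear Implant Treatment Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic lifetime-cost model comparing three surgical treatment
    pathways for conductive and mixed hearing loss from a payer perspective:
    direct implantation of an active middle ear implant, hearing-improvement
    surgeries followed by an implant, and hearing-improvement surgeries only.
    Per-patient treatment trajectories (implant lifetimes, revisions, audio
    processor upgrades, repeat tympanoplasties) are drawn from published input
    distributions, event costs are discounted to present value, and cohorts of
    simulated patients are summarised with capability-style error rates, cost
    homogeneity coefficients, group comparison tests and an age-threshold
    treatment strategy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
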