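Package: aquarisk
Title: Groundwater Quality Indices and Probabilistic Health Risk Assessment
Version: 0.1.0
Authors@R:
    person("Aquarisk", "Developers", email = "aquarisk@example.org", role = c("aut", "cre"))
Description: Tools for screening groundwater chemistry and quantifying the
    risks that potentially toxic elements (Fe, Mn, Cu, Zn) pose to drinking
    water users. Implements charge-balance quality assurance, chloro-alkaline
    indices, Piper/Gibbs/Sulin facies and origin classification, an
    entropy + CRITIC integrated-weight drinking water quality index (WQI),
    the heavy-metal pollution index (HPI), the Hakanson ecological risk
    index (RI), the USEPA deterministic non-carcinogenic exposure chain
    (chronic daily intake, hazard quotient, hazard index) for oral and
    dermal routes in adults and children, and seeded Monte Carlo simulation
    of hazard quotients. A synthetic-cohort generator produces
    charge-balanced sample tables matched to published per-parameter summary
    statistics so the full pipeline can be exercised without access to raw
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
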