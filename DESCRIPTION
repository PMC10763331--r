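Package: methflux
Title: Constraint-Based Analysis of Methanol Bioconversion in Methylotrophic Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Flux balance analysis of methanol-based production of malate,
    acetone, and isoprene in a methylotrophic yeast. Provides a curated core
    metabolic network of methylotrophic yeast metabolism (methanol oxidation,
    xylulose-monophosphate assimilation, dissimilation, TCA cycle, glyoxylate
    shunt, cytosolic reductive TCA route, acetone and mevalonate/isoprene
    pathways, respiration, biomass), an exact bounded-variable simplex solver
    for the underlying linear programs, flux variability analysis, production
    envelopes, scenario-constrained yield simulations, principal component
    analysis of flux distributions, and the unit/yield arithmetic used for
    shake-flask methanol fermentations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
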