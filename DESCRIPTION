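Package: hswvalue
Title: Monetary Valuation of Sanitized Human-Solid-Waste Soil Amendments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-track monetary valuation of soil amendments produced from
    human solid waste (HSW) by composting, torrefaction, or pyrolysis. A
    'bottom-up' track values an amendment as the price-weighted sum of ten
    agronomic components (plant-available N, P, K, Ca, Mg, S, micronutrients,
    CEC-retained base cations, CaCO3 liming equivalency, and century-scale
    persistent carbon), evaluated at five empirical price quantiles with a
    0.9-minus-0.1 quantile sensitivity. A 'top-down' track inverse-solves
    N/P/K unit prices against benchmark commercial amendments by least
    absolute deviations under fixed P/N and P/K price ratios. Supporting
    tools cover derived chemistry indices (cation retention from CEC,
    H/C_org-based persistent-carbon prediction, organic carbon), regulatory
    toxicity screening (heavy metals, PAH/PCB, dioxin TEQ), community-scale
    waste-stream arithmetic, l1 quantile-regression trends of value against
    treatment temperature, a seeded synthetic-data generator, and an
    end-to-end reporting pipeline with packaged composition tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
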