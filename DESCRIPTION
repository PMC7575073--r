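Package: reefcool
Title: Cool-Water Injection Feasibility Analysis for Coral Reefs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Assesses where and at what cost pumping cool water onto a coral
    reef can reduce thermal stress during marine heatwaves. Provides an
    idealized island-reef and tidal-flow generator, a conservative
    finite-volume solver for the "reef age" residence-time tracer and for
    temperature transport with point cool-water sources, reduction-footprint
    statistics (area per cooling bin, threshold areas, Degree Heating Week
    reduction), and a complete pipe-flow energy and cost model (Haaland
    friction factor, friction/momentum/lift/cooling powers, operating and
    capital costs).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
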