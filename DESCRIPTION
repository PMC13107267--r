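Package: metawebr
Title: Semi-Quantitative Multilayer Metawebs from Literature Interaction Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for converting heterogeneous literature-derived measurements of
    species interactions into a scaled, semi-quantitative, seasonal, multilayer
    ecological metaweb, in the style of Arctic food-web syntheses. Implements
    per-study standardization of incommensurable diet metrics, log2 ordinal
    binning of interaction strength, seasonal averaging with a case-study floor
    and opt-in winter extrapolation, multilayer network assembly with sparse-layer
    exclusion and subweb extraction, marine-terrestrial energy-crossover
    summaries, per-node literature knowledge-bias scores, and a seeded synthetic
    literature generator so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
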