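Package: photonet
Title: Connectance Analysis of Photosynthetic Physiological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the modulation of leaf physiological networks under
    environmental constraints through Amzallag's global connectance: absolute
    Pearson correlations between predefined pairs of gas-exchange and
    chlorophyll-fluorescence variables are Fisher z-transformed and averaged
    per network module, and the module means are aggregated into a global
    photosynthetic connectance. Includes bootstrap and permutation inference
    for connectance statistics, standard C3 (Farquhar-von Caemmerer-Berry)
    and simplified C4 leaf photosynthesis models with A/Ci and light-response
    curve fitting, PSII fluorescence parameter derivation, and two tiers of
    synthetic-data generation (direct correlation-matrix sampling and a
    mechanistic leaf simulator) emulating factorial temperature and
    water-deficit experiments on C3 and C4 species.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
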