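Package: fireconn
Title: Spatiotemporal Fire Connectivity and the Odds of Catching
    Fire-Favoured Beetles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes a spatiotemporal connectivity statistic for sampling
    sites from a fire-history register (an exponential distance- and
    time-decay kernel over log burned area), builds ln-odds responses from
    per-site beetle catch counts, optimizes the two decay scales by a
    deviance-profile grid search of a normal-family generalised linear
    model, and validates the whole chain by parameter recovery on
    simulated fire landscapes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
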