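Package: coprune
Title: Pruning Species Co-Occurrence Networks into Biotic Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing bipartite species co-occurrence networks
    with networks of realized biotic interactions. Builds co-occurrence
    frequency matrices from site-level presence records, fits and selects
    among candidate degree-distribution families (exponential, power law,
    truncated power law, log-normal) by discrete maximum likelihood and
    AIC, and fits a frequency-based interaction-rate pruning model in
    which a consumer-resource pair interacts with probability
    1 - (1 - p)^N, where N is the number of sites the pair shares and p
    is a per-site interaction rate calibrated so the conditional expected
    link count matches the observed one. Includes a random-pruning null
    model, ensemble simulation, and a synthetic metacommunity generator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
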