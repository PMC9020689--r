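Package: cultne
Title: Effective Population Sizes for Culturally Transmitted Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward-time Wright-Fisher simulation of a single cultural trait
    under an infinite-alleles innovation model. Implements unbiased,
    one-to-many and frequency-dependent (conformist/anti-conformist) cultural
    transmission, two-population connectedness through migration, cultural
    exchange and fixed immigrant influx, and transmission constrained to
    Erdos-Renyi, Barabasi-Albert and Watts-Strogatz social networks. Tracks
    each individual's cultural influence (number of cultural offspring) and
    derives inbreeding and variance effective population sizes, Simpson
    diversity and unique-variant counts, with seeded replicate experiments,
    tidy tabular results and plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
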