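Package: coopnet
Title: Monitoring and Punishment Networks for Group Cooperation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how groups sustain cooperation through
    institutional networks of monitoring and punishment. Individuals play a
    linear public goods game while embedded in a directed network whose links
    assign responsibility for monitoring others and punishing free-riders.
    The package computes per-individual allocations and payoffs for any
    strategy profile, evaluates the analytic conditions under which universal
    contribution is socially efficient and a Nash equilibrium (a public-goods
    efficiency condition plus minimum in-degree and maximum out-degree
    constraints), verifies equilibria by brute force on small groups,
    constructs and randomly samples socially optimal degree-constrained
    networks, and scores networks on Krackhardt's hierarchy dimensions
    (connectedness, graph hierarchy, graph efficiency, least upper
    boundedness) to map when optimal organizations are distributed versus
    hierarchical.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
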