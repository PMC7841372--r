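Package: skillflock
Title: Skill-Modulated Agents with Gradient Taxis and Vicsek Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based simulations of minimal proprioceptive-kinesthetic
    agents moving at constant speed on a periodic square. A single skill
    parameter divides every noise term, so skilled agents hold a heading and
    unskilled agents diffuse; optional couplings steer agents up the gradient
    of a static Gaussian concentration field and align their headings with
    neighbours inside an interaction radius (a two-agent Vicsek rule).
    Provides seeded ensemble runners and parameter sweeps with the standard
    observables: the velocity order parameter, task success rate, and mean
    first-arrival time at the field centre, all returned as tidy tibbles with
    ggplot2 plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
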