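Package: crowdrank
Title: Multimodal Crowd Estimate Aggregation for Ordering Tasks
Version: 0.1.0
Authors@R:
    person("crowdrank", "maintainers", email = "maintainers@crowdrank.dev",
           role = c("aut", "cre"))
Description: Tools for eliciting-style simulation and aggregation of multimodal
    (ordinal + numerical) crowd estimates on ordering tasks, such as ranking
    images by the number of dots they contain.  Implements distance functions
    for incomplete tied rankings and numerical estimate vectors (Kemeny-Snell,
    Cook-Kress and their normalized projected extensions), classical voting
    rules (plurality, Borda, Copeland) extended to mixed ordinal/numerical
    ballots, an exact and a mixed-integer-programming formulation of the
    cardinal-and-ordinal aggregation (COA) consensus model with optimality-gap
    reporting, a synthetic crowd generator with permutation-partition task
    allocation and log-normal perception noise, and evaluation pipelines for
    self-consistency, individual error distributions, group-size accuracy
    sweeps and coupled- versus separate-estimate-group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
SystemRequirements: python (>= 3.8) with scipy (>= 1.9) on the PATH, used as
    the linear/mixed-integer programming backend (HiGHS via scipy.optimize).
Config/testthat/edition: 3
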