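Package: ascotval
Title: Valuation of ASCOT SCT4 Social Care States by Best-Worst Scaling
    and Time Trade-Off
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for preference valuation of Adult Social Care Outcomes
    Toolkit (ASCOT) SCT4 states. Implements the profile-case (case 2)
    best-worst scaling analysis used in national valuation studies:
    sequential best/worst/second-best/second-worst choices are exploded
    into sign-coded conditional-logit choice sets, utility parameters are
    estimated by maximum likelihood (plain conditional logit or mixed
    logit via simulated maximum likelihood with Halton draws), item
    coefficients are rescaled to a tariff anchored at the control domain,
    and latent scores are mapped to the SC-QALY scale by a constrained
    regression against composite time trade-off valuations. Ships the
    published Japanese and United Kingdom tariffs and conversion formulas,
    scores and compares all 65,536 ASCOT states under both, and includes a
    synthetic-survey generator so the full estimation pipeline can be
    exercised and validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Collate: 
    'RcppExports.R'
    'anchoring.R'
    'ascotval-package.R'
    'domains.R'
    'coding.R'
    'coefficients.R'
    'compare.R'
    'mixed.R'
    'mnl.R'
    'pipeline.R'
    'rescale.R'
    'scoring.R'
    'synthetic.R'
    'tariffs.R'
    'tto.R'
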