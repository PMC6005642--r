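Package: noisyspread
Title: Rumor Spreading and Information-Flow Limits in Noisy Stochastic Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Agent-based simulation and analysis of rumor spreading in
    well-mixed populations whose pairwise communication is corrupted by
    message confusion. Provides constructors for confusion (noise)
    matrices over finite message alphabets, synchronous and sequential
    PULL/PUSH interaction engines, reference protocols (attracting-sink
    relay, static displays with an exact Bayesian observer, a two-stage
    push booster), exact enumeration machinery for sequential hypothesis
    testing (chain-rule Kullback-Leibler divergence, Bayes error, error
    lower bounds), closed-form evaluation of convergence-time lower
    bounds, and estimators of the communication-noise parameter from
    behavioural interaction records such as ant recruitment data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    readxl,
    optparse,
    withr
Config/testthat/edition: 3
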