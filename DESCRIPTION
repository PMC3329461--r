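Package: ctmcexp
Title: Endpoint-Conditioned Expectations of Sufficient Statistics for
    Continuous-Time Markov Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes conditional expectations of the sufficient statistics
    of a continuous-time Markov chain -- the time spent in each state and the
    number of jumps between states -- given the states at the two endpoints
    of an interval. Three O(n^3) backends are provided: eigenvalue
    decomposition, uniformization with Poisson-tail truncation, and the
    auxiliary block-matrix exponential. On top of these the package
    implements expectation-maximization estimation of the Goldman-Yang codon
    substitution model on a fixed phylogeny, and robust labeled evolutionary
    distances for pairwise nucleotide alignments. Closed-form Jukes-Cantor
    and HKY oracles, a random reversible rate-matrix generator, and
    endpoint-conditioned path simulation support validation throughout.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Matrix,
    stats,
    utils
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
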