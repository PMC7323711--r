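Package: stratatips
Title: Bayesian Tip Dating with Linked Fossil-Site Ages and Stratigraphic
    Ordering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tip dating of fossil taxa with Markov chain Monte Carlo under a
    Lewis Mk/Mkv morphological likelihood, discrete-gamma among-character rate
    variation, an uncorrelated lognormal relaxed clock and a serially-sampled
    birth-death tree prior. The distinctive machinery is a pair of tip-age
    proposals that (i) update the ages of all fossils from one fossil site
    jointly, so that taxa from a single locality keep a single shared age while
    the age itself remains uncertain within stratigraphic bounds, and (ii)
    enforce the known stratigraphic ordering of fossil sites whose absolute age
    bounds overlap, by rejecting proposals that would invert the sequence.
    Includes readers and writers for NEXUS character matrices, tree logs,
    fossil-site occurrence tables and parameter traces, posterior summaries
    (highest posterior density intervals, effective sample sizes, majority-rule
    consensus trees), and a synthetic-data module for birth-death tree and
    Mk character simulation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
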