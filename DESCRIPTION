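Package: stepstone
Title: Markovian Rates for Protein Structure Evolution over Stepping-Stone Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models protein structural evolution as a continuous-time Markov
    process over a network of "stepping stone" structures intermediate between
    two folds. Provides a secondary-structure string grammar with edit rules
    and exhaustive enumeration of parsimonious element-correspondence pathways
    between two endpoint folds; synthetic stepping-stone structures as contact
    maps with hydrogen-bond bookkeeping; an entropy-regularized sequence-design
    Monte Carlo with replica exchange; committor-based transition-rate
    estimation in a biased joint two-structure ensemble with an exact
    enumeration oracle; fitting of an analytic detailed-balance rate surface in
    the hydrogen-bond and contact-count differences with a common-contact
    factor; and assembly, stationary analysis and master-equation propagation
    of the resulting rate matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    seqinr,
    bio3d,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
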