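Package: coalroot
Title: Rooting Species Trees Without Outgroups Using Site Pattern Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Roots species-level phylogenies under the multispecies coalescent
    without an outgroup. Two Z-tests on the frequencies of one-off site pattern
    categories (yxxx, xyxx, xxyx, xxxy) decide the root position of a four-taxon
    quartet under a molecular clock; weighted quartet scores accumulated over
    sampled quartets locate the root branch on larger unrooted species trees.
    Includes a multispecies-coalescent gene-tree simulator and a nucleotide
    sequence simulator (JC69, HKY85, GTR with invariant sites and gamma rate
    variation) for power studies, plus readers for common alignment and tree
    formats and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phytools,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
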