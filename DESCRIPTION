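Package: flowdedup
Title: Flow-Space Duplicate Read Filtering for 454 Pyrosequencing Data
Version: 0.1.0
Authors@R:
    person("flowdedup", "developers", email = "flowdedup@example.org",
           role = c("aut", "cre"))
Description: Identifies and removes artificial duplicate reads from 454
    pyrosequencing runs by clustering reads in flow space rather than
    nucleotide space. Reads and writes the binary standard flowgram format
    (SFF), models per-flow signal values with a Bayesian posterior over
    homopolymer lengths, computes pairwise flowgram distances from the
    probability that two reads call the same homopolymer at every flow,
    preclusters reads on flow-sign seeds, performs agglomerative clustering
    with per-flow-median consensus flowgrams, and emits one representative
    per duplicate cluster. Includes a synthetic flowgram simulator with
    known duplicate structure, ground-truth construction from SAM
    alignments, and pair-counting Jaccard evaluation of clusterings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
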