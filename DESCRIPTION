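Package: fordalpha
Title: Exact Probabilities of Cladograms and Tree Shapes Under Ford's
    Alpha-Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact toolkit for Ford's alpha-model of random rooted bifurcating
    phylogenetic trees. Computes the corrected closed-form probabilities of
    cladograms, tree shapes, ordered cladograms and ordered tree shapes, either
    symbolically as canonically reduced rational functions of the parameter
    alpha or exactly at a rational alpha, together with the Yule (alpha = 0)
    and uniform/PDA (alpha = 1/2) limit laws. Includes the sequential
    leaf-addition growth process (a seeded sampler and an exhaustive
    growth-history enumerator that serves as a brute-force oracle), exhaustive
    enumeration of shapes and cladograms for small leaf counts, the Markov
    branching recurrences, and a comparator implementing the erroneous
    published product formula whose factor-of-two discrepancy the corrected
    formulas repair. All headline computations use exact integer and rational
    arithmetic with overflow guards; floating point is a convenience layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
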