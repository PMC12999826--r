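Package: spinalnets
Title: Enumeration, Encoding and Sampling of Spinal Phylogenetic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for spinal phylogenetic networks, the network analogue of
    caterpillar trees: a rooted network is spinal when a single directed path
    from the root to a leaf passes through every non-leaf vertex. The package
    implements the expanding-cover encoding of labellable networks and the
    deterministic vertex-labelling algorithm, the LRP-sequence encoding of
    binary spinal network shapes, exact closed-form counts and recursions for
    six network classes (spinal; binary spinal tree-child, stack-free, fully
    tree-sibling; binary spinal with and without parallel arcs) in exact
    arbitrary-precision integer arithmetic, exhaustive brute-force enumerators
    that serve as independent oracles for every formula, and seeded uniform
    random samplers. Networks are read and written as extended Newick strings,
    directed edge lists, or cover text.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
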