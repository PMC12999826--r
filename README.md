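# spinalnets

Exact combinatorics of **spinal phylogenetic networks** — rooted networks in
which a single directed path from the root to a leaf passes through every
non-leaf vertex, the network analogue of a caterpillar tree. Spinal networks
are the maximal-height extreme of network space, the shape rapidly evolving
clades tend towards, and a tractable base case for the (still open) problem
of counting tree-child networks in general. The package is for
mathematical phylogeneticists and method developers who need exact class
sizes (e.g. to normalise priors for MCMC over network space), canonical
encodings, exhaustively enumerated small cases, and uniform samplers.

It provides:

* **Expanding covers** — the set-system encoding of labellable networks
  (`parse_cover()`, `validate_expanding()`, `cover_to_network()`,
  `network_to_cover()`, the deterministic labelling algorithm
  `label_vertices()`), with cover-level class tests
  (`is_spinal_cover()`, `is_tree_child_cover()`, `is_binary_cover()`, ...).
* **LRP sequences** — canonical words for binary spinal network shapes
  (`encode_lrp()`, `decode_lrp()`, `check_rules()`) and the bijections onto
  singleton/doubleton partitions, set partitions and permutations by cycle
  count that drive the counting formulas.
* **Exact counts** for six classes in arbitrary-precision integer
  arithmetic: all spinal networks by cover size, `count_spinal(n, c) =
  2^C(c-1,2) (c^n - (c-1)^n)`; binary spinal tree-child networks,
  `count_stc(n, k) = n! B(n-1,k) - (n!/2) B(n-2,k)` with `B` the Bessel
  numbers; stack-free `count_ssf()` via Stirling numbers of the second
  kind; fully tree-sibling `count_fts()` via unsigned Stirling numbers of
  the first kind; binary spinal with/without parallel arcs (`count_bsp()`,
  `count_bs()` with the shape recursion `count_bss_shapes()`).
* **Exhaustive enumerators** that act as independent oracles for every
  formula (`enumerate_lrp()`, `enumerate_spinal_covers()`,
  `brute_force_covers()`, `enumerate_networks()`), and **seeded uniform
  samplers** (`sample_network()`).
* I/O in extended Newick (`to_enewick()` / `from_enewick()`), directed
  edge lists, and a line-based cover format, plus a command-line tool
  (`inst/scripts/spinalnet`) with `count`, `table`, `enumerate`,
  `classify`, `convert` and `sample` subcommands.

## A worked example

```r
library(spinalnets)

# a labellable network given as an expanding cover
cov <- parse_cover("{2,3};{1,5};{5};{4,7};{5,6};{5,7,9};{8,10}")
cov
#> Expanding cover: {2,3};{1,5};{5};{4,7};{5,6};{5,7,9};{8,10}
#>   m = 10 (non-root vertices),  |C| = 7 (non-leaf vertices),  n = 4 (leaves)
is_spinal_cover(cov)
#> [1] FALSE

# a binary spinal tree-child shape from its LRP word: 4 leaves, 2 reticulations
net <- decode_lrp("R1,L,P1,R2,L,P2,L")
classify_network(net)
#>             binary      nondegenerate             spinal         tree_child
#>               TRUE               TRUE               TRUE               TRUE
#>         stack_free fully_tree_sibling  has_parallel_arcs
#>               TRUE               TRUE              FALSE
attr(lrp_to_bessel_partition("R1,L,P1,R2,L,P2,L"), "text")
#> [1] "12|34|5"

# exact class counts at n = 4 leaves, k = 2 reticulations
sapply(list(tree_child = count_stc(4, 2), stack_free = count_ssf(4, 2),
            fully_tree_sibling = count_fts(4, 2), binary_spinal = count_bs(4, 2),
            parallel_allowed = count_bsp(4, 2)), format)
#>         tree_child         stack_free fully_tree_sibling      binary_spinal
#>              "324"              "516"              "708"             "1068"
#>   parallel_allowed
#>             "1980"

# the counts are exact far beyond double precision
format(count_bsp(8, 8))
#> [1] "16987548201624000"

# exhaustive enumeration agrees with the formula, and sampling is uniform
length(enumerate_networks("BS", 2, 2))
#> [1] 11
to_enewick(sample_network("STC", 4, 2, seed = 7))
#> [1] "(((((((4)#H1,2))#H2,1),3),#H2),#H1);"
```

The increasing counts 324 ≤ 516/708 ≤ 1068 ≤ 1980 reflect the class
inclusions: every tree-child network is stack-free and fully tree-sibling,
every one of those is binary spinal, and allowing parallel arcs enlarges
the class further.

From a shell:

```sh
Rscript inst/scripts/spinalnet count --class stc -n 4 -k 2       # 324
Rscript inst/scripts/spinalnet table --class stc --n-max 8 --k-max 7 --total
Rscript inst/scripts/spinalnet classify '{1,4};{3,5};{2,6};{5,6,7};{7,8}'
Rscript inst/scripts/spinalnet sample --class bs -n 3 -k 2 --seed 7 --size 5
```

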