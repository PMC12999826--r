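test_that("network construction enforces the structural invariants", {
  cherry <- phylo_network(rbind(c("r", "1"), c("r", "2")))
  expect_equal(cherry$n, 2)
  expect_identical(cherry$root, "r")
  expect_error(phylo_network(rbind(c("a", "b"), c("b", "a"))), "cycle|in-degree")
  expect_error(phylo_network(rbind(c("r", "1"), c("r", "1"))), "parallel")
  expect_silent(phylo_network(rbind(c("r", "x"), c("r", "x"), c("x", "1")),
                              allow_parallel = TRUE))
  expect_error(phylo_network(rbind(c("r", "leafA"))), "labelled 1..n")
})

test_that("the labelling algorithm reproduces the reference labels and detects ties", {
  net <- cover_to_network(hub_cover_text)
  lab <- label_vertices(net)
  expect_equal(lab$status, "ok")
  # reconstruction names vertices by their labels, so the algorithm must
  # reproduce them: the vertex with children {2,3} gets 5, and so on
  nonroot <- setdiff(net$vertices, "rho")
  expect_identical(unname(lab$labels[nonroot]), as.integer(nonroot))

  cherry <- phylo_network(rbind(c("r", "1"), c("r", "2")))
  expect_equal(label_vertices(cherry)$status, "ok")

  # two internal vertices with identical children sets (both parents of the
  # same two reticulations): not labellable
  twin <- phylo_network(rbind(c("r", "a"), c("r", "b"),
                              c("a", "c"), c("b", "c"), c("a", "d"), c("b", "d"),
                              c("c", "1"), c("d", "2")))
  expect_equal(label_vertices(twin)$status, "not_labellable")
  expect_error(network_to_cover(twin), "not labellable")
})

test_that("cover <-> network conversions are mutually inverse", {
  expect_identical(format(network_to_cover(cover_to_network(hub_cover_text))),
                   hub_cover_text)
  net <- cover_to_network(hub_cover_text)
  expect_equal(sum(net$arcs[, "child"] == "5"), 4)   # the in-degree-4 hub
  expect_setequal(net$arcs[net$arcs[, "parent"] == "rho", "child"], c("8", "10"))
  expect_identical(format(network_to_cover(cover_to_network(spinal5_cover_text))),
                   spinal5_cover_text)
  single <- cover_to_network("{1}")
  expect_equal(single$n, 1)
  expect_identical(format(network_to_cover(single)), "{1}")
  # every expanding cover on a small ground set round-trips
  for (m in 4:6) for (cc in 2:(m - 1)) {
    for (cov in brute_force_covers(m, cc)) {
      expect_identical(format(network_to_cover(cover_to_network(cov))), format(cov))
    }
  }
})

test_that("spines exist exactly for spinal covers, with the right starting leaves", {
  sp <- find_spine(cover_to_network(spinal5_cover_text))
  expect_s3_class(sp, "network_spine")
  expect_equal(sp$start_leaf_choices, c(1L, 4L))
  expect_identical(sp$vertices[1], "1")             # canonical smaller leaf
  expect_identical(find_spine(cover_to_network(hub_cover_text)), "NOT_SPINAL")
  cat3 <- decode_lrp("L,L")
  sp3 <- find_spine(cat3)
  expect_length(sp3$start_leaf_choices, 2)          # the cherry pair
  # agreement with the cover-level characterisation on all small covers
  for (m in 4:6) for (cc in 2:(m - 1)) {
    for (cov in brute_force_covers(m, cc)) {
      expect_equal(!identical(find_spine(cover_to_network(cov)), "NOT_SPINAL"),
                   is_spinal_cover(cov))
    }
  }
})

test_that("height counts arcs and is maximal exactly on spinal networks", {
  expect_equal(network_height(phylo_network(rbind(c("r", "1"), c("r", "2")))), 1)
  # binary spinal with n = 4, k = 2: n + 2k - 2 = 6 internal vertices, height 7
  net <- decode_lrp("R1,L,P1,R2,L,P2,L")
  expect_equal(network_height(net), 7)
  hub <- cover_to_network(hub_cover_text)
  expect_lt(network_height(hub), 7 + 1)             # below (#non-leaf)+... non-spinal
  # among labellable binary (n, k) networks, spinal <=> maximal height
  for (nk in list(c(2, 1), c(3, 1))) {
    n <- nk[1]; k <- nk[2]
    covs <- Filter(is_binary_cover, brute_force_covers(2 * n + 2 * k - 2, n + 2 * k - 1))
    hs <- vapply(covs, function(cov) network_height(cover_to_network(cov)), integer(1))
    sp <- vapply(covs, is_spinal_cover, logical(1))
    expect_equal(max(hs), n + 2 * k - 1)
    expect_identical(hs == max(hs), sp)
  }
})

test_that("graph-level classification matches the worked shapes and cover predicates", {
  # the two shapes on 2 leaves / 2 reticulations that are FTS but not stack-free
  fts_only <- decode_lrp("R1,R2,L,P2,P1")
  cl <- classify_network(fts_only)
  expect_true(cl[["fully_tree_sibling"]])
  expect_false(cl[["stack_free"]])
  # the one that is stack-free but not FTS
  sf_only <- decode_lrp("R1,L,R2,P1,P2")
  cl2 <- classify_network(sf_only)
  expect_true(cl2[["stack_free"]])
  expect_false(cl2[["fully_tree_sibling"]])
  # any tree is tree-child, stack-free and fully tree-sibling
  tree <- decode_lrp("L,L,L")
  expect_true(all(classify_network(tree)[c("tree_child", "stack_free",
                                           "fully_tree_sibling")]))
  # agreement with cover-level predicates on all small expanding covers
  for (m in 4:6) for (cc in 2:(m - 1)) {
    for (cov in brute_force_covers(m, cc)) {
      cl <- classify_network(cover_to_network(cov))
      expect_equal(cl[["tree_child"]], is_tree_child_cover(cov))
      expect_equal(cl[["nondegenerate"]], is_nondegenerate_cover(cov))
      expect_equal(cl[["binary"]], is_binary_cover(cov))
    }
  }
})

test_that("cherry reduction and re-cherrying are mutually inverse", {
  two <- decode_lrp("L")
  single <- cherry_reduce(two)
  expect_equal(single$n, 1)
  expect_length(single$vertices, 2)
  cat3 <- decode_lrp("L,L")
  expect_identical(as.character(encode_lrp(cherry_reduce(cat3))), "L")
  expect_identical(as.character(encode_lrp(recherry(cherry_reduce(cat3)))),
                   c("L", "L"))
  # every cherry-bearing shape with n = 3, k = 1 round-trips
  for (s in enumerate_lrp(3, 1, "BS")) {
    net <- decode_lrp(s)
    if (as.character(s)[1] == "L") {
      expect_identical(as.character(encode_lrp(recherry(cherry_reduce(net)))),
                       as.character(s))
    } else {
      expect_error(cherry_reduce(net), "no cherry")
    }
  }
  # reduction maps (n,k)-shapes to (n-1,k)-shapes
  red <- cherry_reduce(decode_lrp("L,R1,L,P1"))
  expect_equal(red$n, 2)
})

test_that("eNewick serialisation round-trips through parsing", {
  expect_identical(to_enewick(cover_to_network("{1,2}")), "(1,2);")
  expect_identical(format(network_to_cover(from_enewick("(1,2);"))), "{1,2}")
  # all shapes with 2 leaves and 2 reticulations, plus their networks
  for (s in enumerate_lrp(2, 2, "BS")) {
    net <- decode_lrp(s)
    back <- from_enewick(to_enewick(net))
    expect_identical(format(network_to_cover(back)), format(network_to_cover(net)))
    # parse-serialise-parse stability
    expect_identical(to_enewick(back), to_enewick(from_enewick(to_enewick(back))))
  }
  # non-spinal multi-in-degree network
  hub <- cover_to_network(hub_cover_text)
  expect_identical(format(network_to_cover(from_enewick(to_enewick(hub)))),
                   hub_cover_text)
  # parallel arcs survive the round trip
  par <- decode_lrp("R1,P1", allow_parallel = TRUE)
  back <- from_enewick(to_enewick(par), allow_parallel = TRUE)
  expect_equal(nrow(back$arcs), nrow(par$arcs))
  expect_error(from_enewick("((1,2);"), "malformed")
})

test_that("edge lists round-trip and feed classification", {
  net <- decode_lrp("R1,L,P1,R2,L,P2,L")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edgelist(net, path)
  back <- read_edgelist(path)
  expect_identical(format(network_to_cover(back)), format(network_to_cover(net)))
  rep <- classify_input(path, format = "edgelist")
  expect_true(rep$classes[["tree_child"]])
  expect_identical(format(rep$lrp), "R1,L,P1,R2,L,P2,L")
})
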