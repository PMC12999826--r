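test_that("sequence construction enforces letter structure", {
  s <- parse_lrp("R1,L,P1,R2,L,P2,L")
  expect_equal(attr(s, "n"), 4)
  expect_equal(attr(s, "k"), 2)
  expect_length(s, 4 + 2 * 2 - 1)
  expect_identical(format(s), "R1,L,P1,R2,L,P2,L")
  expect_error(new_lrp(c("R1", "L")), "one R_i and one P_i")
  expect_error(new_lrp(c("R2", "P2")), "one R_i and one P_i")
  expect_error(new_lrp("Q1"), "invalid")
})

test_that("rule checking reports the printed pass/fail patterns", {
  expect_true(all(check_rules("L,R1,R2,P1,P2", "BS")$per_rule[c("R1", "R2", "R3")]))
  bad <- check_rules("L,R1,P1,R2,P2", "BS")
  expect_false(bad$per_rule[["R3"]])
  expect_length(grep("^R3", bad$violations), 2)     # fails R3 twice
  expect_true(check_rules("R1,L,P1,R2,L,P2,L", "STC")$member)
  # R4b separates stack-free from FTS and vice versa
  expect_false(check_rules("R1,R2,L,L,P2,P1", "SSF")$member)
  expect_true(check_rules("R1,R2,L,L,P2,P1", "FTS")$member)
  expect_true(check_rules("R1,L,R2,P1,L,P2", "SSF")$member)
  expect_false(check_rules("R1,L,R2,P1,L,P2", "FTS")$member)
  # R1 violation
  expect_false(check_rules(structure(c("R2", "L", "R1", "L", "P1", "P2"),
                                     n = 3L, k = 2L, class = "lrp_sequence"),
                           "BS")$per_rule[["R1"]])
})

test_that("rule sets per class match the published summary", {
  expect_identical(class_spec("bsp")$rules, c("R1", "R2"))
  expect_identical(class_spec("bs")$rules, c("R1", "R2", "R3"))
  expect_identical(class_spec("ssf")$rules, c("R1", "R2", "R3", "R4b"))
  expect_identical(class_spec("fts")$rules, c("R1", "R2", "R3", "R4c"))
  expect_identical(class_spec("STC")$rules, c("R1", "R2", "R3", "R4a", "R4b", "R4c"))
  expect_error(class_spec("XX"), "unknown class")
})

test_that("encoding reproduces the printed sequences of the worked shapes", {
  # the shapes are defined by their sequences; decode then re-encode
  for (txt in c("R1,L,P1,R2,L,P2,L",     # tree-child example
                "R1,L,R2,P1,L,P2",       # stack-free example
                "R1,R2,L,L,P2,P1")) {    # fully tree-sibling example
    expect_identical(format(encode_lrp(decode_lrp(txt))), txt)
  }
  # encoding is independent of the admissible starting leaf (cherry shapes)
  cat4 <- decode_lrp("L,L,L")
  expect_identical(format(encode_lrp(cat4)), "L,L,L")
  expect_error(encode_lrp(cover_to_network(hub_cover_text)), "not spinal|not binary")
})

test_that("decode builds the advertised structures", {
  net <- decode_lrp("R1,L,P1,R2,L,P2,L")
  expect_equal(net$n, 4)
  cl <- classify_network(net)
  expect_true(all(cl[c("binary", "spinal", "tree_child")]))
  expect_equal(sum(table(net$arcs[, "child"]) >= 2), 2)    # two reticulations
  # caterpillar from all-L
  expect_true(classify_network(decode_lrp("L,L"))[["tree_child"]])
  # one leaf, one reticulation needs parallel arcs
  expect_error(decode_lrp("R1,P1"), "violates")
  par <- decode_lrp("R1,P1", allow_parallel = TRUE)
  expect_true(classify_network(par)[["has_parallel_arcs"]])
  expect_equal(par$n, 1)
  expect_error(decode_lrp(structure(c("P1", "R1"), n = 1L, k = 1L,
                                    class = "lrp_sequence"),
                          allow_parallel = TRUE), "violates")
})

test_that("encode and decode are mutually inverse on all small shapes", {
  for (nk in small_nk_grid(8)) {
    for (spec in c("BS", "BSP")) {
      for (s in enumerate_lrp(nk[["n"]], nk[["k"]], spec)) {
        net <- decode_lrp(s, allow_parallel = spec == "BSP")
        expect_identical(as.character(encode_lrp(net)), as.character(s))
      }
    }
  }
})

test_that("rule verdicts match graph-level class predicates on decoded shapes", {
  for (nk in small_nk_grid(8)) {
    for (s in enumerate_lrp(nk[["n"]], nk[["k"]], "BSP")) {
      chk <- check_rules(s)$per_rule
      cl <- classify_network(decode_lrp(s, allow_parallel = TRUE))
      expect_equal(chk[["R3"]], !cl[["has_parallel_arcs"]])
      expect_equal(chk[["R4a"]], cl[["tree_child"]])
      expect_equal(chk[["R4b"]], cl[["stack_free"]])
      expect_equal(chk[["R4c"]], cl[["fully_tree_sibling"]])
    }
  }
})

test_that("the three bijections reproduce the printed examples", {
  expect_identical(attr(lrp_to_bessel_partition("R1,L,P1,R2,L,P2,L"), "text"),
                   "12|34|5")
  expect_identical(format(bessel_partition_to_lrp("12|34|5")), "R1,L,P1,R2,L,P2,L")
  expect_identical(attr(lrp_to_set_partition("R1,L,R2,P1,L,P2"), "text"), "124|3")
  expect_identical(format(set_partition_to_lrp("124|3")), "R1,L,R2,P1,L,P2")
  expect_identical(attr(lrp_to_permutation("R1,R2,L,L,P2,P1"), "text"), "(143)(2)")
  expect_identical(format(permutation_to_lrp("(143)(2)")), "R1,R2,L,L,P2,P1")
  # caterpillars map to all singletons / the identity permutation
  expect_identical(attr(lrp_to_bessel_partition("L,L,L"), "text"), "1|2|3")
  expect_identical(attr(lrp_to_set_partition("L,L,L"), "text"), "1|2|3")
  expect_identical(attr(lrp_to_permutation("L,L,L"), "text"), "(1)(2)(3)")
  expect_error(lrp_to_bessel_partition("R1,L,R2,P1,L,P2"), "not tree-child")
})

test_that("each bijection round-trips exhaustively with the advertised statistics", {
  for (nk in small_nk_grid(9)) {
    n <- nk[["n"]]; k <- nk[["k"]]
    if (n > 5 || k > 3) next
    for (s in enumerate_lrp(n, k, "STC")) {
      p <- lrp_to_bessel_partition(s)
      expect_equal(sum(lengths(p) == 2), k)
      expect_identical(as.character(bessel_partition_to_lrp(p)), as.character(s))
    }
    if (n > 4) next
    for (s in enumerate_lrp(n, k, "SSF")) {
      p <- lrp_to_set_partition(s)
      expect_length(p, n - 1)
      expect_identical(as.character(set_partition_to_lrp(p)), as.character(s))
    }
    for (s in enumerate_lrp(n, k, "FTS")) {
      p <- lrp_to_permutation(s)
      expect_identical(as.character(permutation_to_lrp(p)), as.character(s))
    }
  }
})
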