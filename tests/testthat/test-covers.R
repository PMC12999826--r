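test_that("parsing, serialisation and the JSON dialect round-trip", {
  cov <- parse_cover(hub_cover_text)
  expect_s3_class(cov, "expanding_cover")
  expect_equal(cov$m, 10)
  expect_equal(cov$c, 7)
  expect_equal(cov$n, 4)
  expect_identical(format(cov), hub_cover_text)
  via_json <- parse_cover("[[2,3],[1,5],[5],[4,7],[5,6],[5,7,9],[8,10]]")
  expect_identical(format(via_json), hub_cover_text)

  expect_identical(format(parse_cover("{1}")), "{1}")
  expect_equal(parse_cover("{1}")$n, 1)
  expect_error(parse_cover("{1,1}"), "duplicate element")
  # element 2 <= n appears twice across sets (here n = 2)
  expect_error(parse_cover("{1,2};{2,3}"), "more than once")
  expect_error(parse_cover("{a};{1}"), "malformed")
  expect_error(expanding_cover(list()), "empty")
})

test_that("the expanding conditions are validated with witnesses", {
  v <- validate_expanding(parse_cover(hub_cover_text))
  expect_true(v$is_expanding)
  expect_equal(v$n, 4)

  # {{1},{2}} over [2]: n = 1; both conditions hold
  expect_true(validate_expanding("{1};{2}")$is_expanding)
  # {{2},{1,3}} over [3]: n = 2
  expect_true(validate_expanding("{2};{1,3}")$is_expanding)
  # gap in the union
  bad <- validate_expanding(expanding_cover(list(c(1, 2), 4),
                                            reorder = FALSE, strict = FALSE))
  expect_false(bad$is_expanding)
  expect_match(bad$violations, "missing", all = FALSE)
  # growth condition violated: {3} alone cannot be an early subset
  bad2 <- validate_expanding(expanding_cover(list(3, c(1, 2, 3)),
                                             reorder = FALSE, strict = FALSE))
  expect_false(bad2$is_expanding)
})

test_that("labelling order is recovered from scrambled input", {
  scrambled <- expanding_cover(list(c(8, 7), c(1, 4), c(6, 2), c(5, 3), c(7, 6, 5)))
  expect_identical(format(scrambled), spinal5_cover_text)
  expect_identical(format(expanding_cover(list(c(1, 2, 3)))), "{1,2,3}")
  expect_identical(format(parse_cover(hub_cover_text)), hub_cover_text)
})

test_that("spinal covers are exactly those with i subsets of [n+i-1]", {
  expect_true(is_spinal_cover(parse_cover(spinal5_cover_text)))
  expect_false(is_spinal_cover(parse_cover(hub_cover_text)))  # 3 subsets of [5] at i = 2
  expect_true(is_spinal_cover(parse_cover("{1}")))
  expect_error(is_spinal_cover(expanding_cover(list(3, c(1, 2, 3)),
                                               reorder = FALSE, strict = FALSE)),
               "not expanding")
})

test_that("tree-child, nondegenerate and binary predicates follow the cover rules", {
  expect_false(is_tree_child_cover(parse_cover(spinal5_cover_text)))
  expect_true(is_tree_child_cover(parse_cover("{1};{2,3}")))
  expect_false(is_tree_child_cover(expanding_cover(list(c(1, 3), 3, c(3, 4)),
                                                   reorder = FALSE)))

  # hub network: vertex 5 has in-degree 4 and out-degree 2 -> degenerate
  expect_false(is_nondegenerate_cover(parse_cover(hub_cover_text)))
  # spinal 5-set cover: vertex 5 has two parents and two leaf children
  expect_false(is_nondegenerate_cover(parse_cover(spinal5_cover_text)))
  # {{1},{2}}: |C_1| = 1 but element 2 appears only once
  expect_false(is_nondegenerate_cover(parse_cover("{1};{2}")))
  expect_true(is_nondegenerate_cover(parse_cover("{1,2}")))

  expect_false(is_binary_cover(parse_cover(spinal5_cover_text)))  # a 3-set
  expect_true(is_binary_cover(parse_cover("{1,2}")))
  expect_true(is_binary_cover(network_to_cover(decode_lrp("R1,L,P1,R2,L,P2,L"))))
})

test_that("n + c = m + 1 and the spinal max rule hold on enumerated covers", {
  for (m in 3:5) for (cc in 1:m) {
    for (cov in brute_force_covers(m, cc)) {
      expect_equal(cov$n + cov$c, cov$m + 1)
      if (is_spinal_cover(cov) && cov$c > 1) {
        maxes <- vapply(cov$sets[-1], max, integer(1))
        expect_identical(maxes, cov$n + seq_len(cov$c - 1L))
      }
    }
  }
})

test_that("binary covers are nondegenerate on all small enumerated covers", {
  for (m in 3:7) {
    for (cc in 1:m) {
      for (cov in brute_force_covers(m, cc)) {
        if (is_binary_cover(cov)) expect_true(is_nondegenerate_cover(cov))
      }
    }
  }
})

test_that("tree-child category tags partition every set, with pairs matching category 3", {
  for (nk in list(c(3, 1), c(4, 2), c(5, 1))) {
    for (s in enumerate_lrp(nk[1], nk[2], "STC")) {
      cov <- network_to_cover(decode_lrp(s))
      tags <- stc_categories(cov)
      expect_true(all(!is.na(tags[-1])))          # exhaustive beyond C_1
      expect_equal(sum(tags == 1, na.rm = TRUE) %% 2, 0)
      expect_equal(sum(tags == 1, na.rm = TRUE) / 2, sum(tags == 3, na.rm = TRUE))
    }
  }
  # a caterpillar has only category-2 sets
  cat_tags <- stc_categories(network_to_cover(decode_lrp("L,L,L")))
  expect_identical(cat_tags[-1], rep(2L, 2))
  expect_error(stc_categories(parse_cover(spinal5_cover_text)), "not the cover")
})

test_that("cover files round-trip through read/write", {
  path <- withr::local_tempfile(fileext = ".cover")
  covs <- list(parse_cover(hub_cover_text), parse_cover("{1,2}"))
  write_covers(covs, path)
  writeLines(c("# a comment", readLines(path), ""), path)
  back <- read_covers(path)
  expect_identical(vapply(back, format, character(1)),
                   c(hub_cover_text, "{1,2}"))
})
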