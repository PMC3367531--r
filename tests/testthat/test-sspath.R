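test_that("element parsing recovers kinds and lengths of the endpoint folds", {
  el <- ss_elements(ss_endpoint("1PGB"))
  expect_equal(el$kind, c("E", "E", "H", "E", "E"))
  expect_equal(el$length, c(7L, 7L, 15L, 5L, 5L))

  el2 <- ss_elements(ss_endpoint("2GYC"))
  expect_equal(el2$kind, c("E", "H", "E", "H", "E"))
  expect_equal(el2$length, c(5L, 8L, 4L, 7L, 2L))

  expect_equal(nrow(ss_elements(strrep("C", 30))), 0L)
  expect_error(ss_elements("CHHX"), "position 4")
})

test_that("validator enforces element-length, separation and total-count rules", {
  expect_length(ss_validate(ss_endpoint("1PGB")), 0)
  expect_length(ss_validate(ss_endpoint("2GYC")), 0)
  expect_equal(sum(ss_elements(ss_endpoint("1PGB"))$length), 39L)

  # helix of 16 violates even when totals stay in range
  s16 <- paste0("C", strrep("H", 16), "C", strrep("E", 8), "C",
                strrep("E", 8), strrep("C", 21))
  expect_match(ss_validate(s16), "helix length 16", all = FALSE)

  # no separating coil between strand and helix
  s_touch <- paste0("C", strrep("E", 4), strrep("H", 6), "C", strrep("E", 8),
                    "C", strrep("E", 4), strrep("C", 32))
  expect_match(ss_validate(s_touch), "no separating coil", all = FALSE)
})

test_that("validator bounds are sharp at 4/15 for helices, 2/8 for strands, 20/45 overall", {
  pad_to_valid <- function(core, extra_struct) {
    # append disjoint strands to bring totals into [20, 45]
    n_e <- ceiling(extra_struct / 8)
    paste0(core, paste0(rep(paste0(strrep("E", 8), "C"), n_e), collapse = ""))
  }
  h <- function(n) pad_to_valid(paste0("C", strrep("H", n), "C"), 20 - n)
  e <- function(n) pad_to_valid(paste0("C", strrep("E", n), "C"), 20 - n)
  expect_length(ss_validate(h(15)), 0)
  expect_match(ss_validate(h(16)), "helix", all = FALSE)
  expect_length(ss_validate(h(4)), 0)
  expect_match(ss_validate(paste0(h(20 - 3), "CHHHC")), "helix", all = FALSE)
  expect_length(ss_validate(e(8)), 0)
  expect_match(ss_validate(e(9)), "strand", all = FALSE)

  total <- function(n_struct) {
    n_e <- n_struct %/% 5L; rem <- n_struct %% 5L
    paste0(paste0(rep(paste0(strrep("E", 5), "C"), n_e), collapse = ""),
           if (rem >= 2) paste0(strrep("E", rem), "C") else strrep("C", rem))
  }
  expect_length(ss_validate(total(45L)), 0)
  expect_match(ss_validate(total(50L)), "total structured", all = FALSE)
  expect_length(ss_validate(total(20L)), 0)
  expect_match(ss_validate(total(15L)), "total structured", all = FALSE)
})

test_that("move enumeration offers insertions in wide coil windows and respects bounds", {
  s <- paste0("C", strrep("E", 8), strrep("C", 12), strrep("E", 8), "C",
              strrep("E", 4), strrep("C", 10))
  mv <- ss_moves(s)
  expect_true(any(grepl("insert H", mv$move)))
  expect_true(any(grepl("insert E", mv$move)))
  # every proposed string re-validates clean
  expect_true(all(vapply(mv$ss, function(x) length(ss_validate(x)) == 0L, logical(1))))

  # at the 45-residue ceiling no lengthen or insert move is offered
  s45 <- paste0(paste0(rep(paste0(strrep("E", 8), "C"), 5), collapse = ""),
                strrep("E", 5), strrep("C", 8))
  expect_equal(sum(ss_elements(s45)$length), 45L)
  mv45 <- ss_moves(s45)
  expect_false(any(grepl("lengthen|insert", mv45$move)))

  # a minimal strand cannot be shortened, only deleted whole
  s2 <- paste0("C", strrep("E", 2), "C", strrep("E", 8), "C", strrep("E", 8),
               "C", strrep("E", 4), strrep("C", 10))
  mv2 <- ss_moves(s2)
  expect_false(any(grepl("shorten E@1 ", mv2$move)))
  expect_true(any(grepl("delete E@1", mv2$move)))
  expect_error(ss_moves("EHC"), "invalid")
})

test_that("pathway enumeration finds exactly the seven parsimonious mappings", {
  maps <- ss_pathways(ss_endpoint("1PGB"), ss_endpoint("2GYC"))
  expect_length(maps, 7L)
  desc <- sort(vapply(maps, attr, character(1), "description"))
  expected <- sort(c(
    "kept: - | lost: E1,H2,E3 | created: H1,E2,H3",
    "kept: H2>H1,E3>E2 | lost: E1 | created: H3",
    "kept: H2>H1 | lost: E1,E3 | created: E2,H3",
    "kept: E3>E2 | lost: E1,H2 | created: H1,H3",
    "kept: E1>E2,H2>H3 | lost: E3 | created: H1",
    "kept: H2>H3 | lost: E1,E3 | created: H1,E2",
    "kept: E1>E2 | lost: H2,E3 | created: H1,H3"))
  expect_equal(desc, expected)
  # reversal symmetry of the matching count
  expect_length(ss_pathways(ss_endpoint("2GYC"), ss_endpoint("1PGB")), 7L)
})

test_that("pathway enumeration handles degenerate internal element sets", {
  # internal H vs internal E: only the empty matching
  a <- paste0("C", strrep("E", 8), "C", strrep("H", 6), "C", strrep("E", 8),
              strrep("C", 10))
  b <- paste0("C", strrep("E", 8), "C", strrep("E", 4), "C", strrep("E", 8),
              strrep("C", 10))
  expect_length(ss_pathways(a, b), 1L)
  # internal H vs internal H: empty + H->H
  expect_length(ss_pathways(a, a), 2L)
  # endpoints must start and end with strands
  bad <- paste0("C", strrep("H", 8), "C", strrep("E", 8), "C", strrep("E", 8),
                strrep("C", 10))
  expect_error(ss_pathways(bad, a), "terminal strand")
})

test_that("path construction is stepwise-legal, monotone and seeded-deterministic", {
  src <- ss_endpoint("1PGB"); dst <- ss_endpoint("2GYC")
  maps <- ss_pathways(src, dst)

  p <- ss_build_path(src, dst, maps[[2]], seed = 7L)
  expect_identical(p$steps[1], src)
  expect_identical(p$steps[length(p$steps)], dst)
  expect_true(all(diff(p$distance) < 0))
  for (k in seq_along(p$moves)) {
    legal <- ss_moves(p$steps[k], target = dst)
    expect_true(p$steps[k + 1L] %in% legal$ss)
  }
  # lower bound: at most 4 positions change per move
  expect_gte(length(p$moves), ss_distance(src, dst, "hamming") / 4)
  # determinism
  p2 <- ss_build_path(src, dst, maps[[2]], seed = 7L)
  expect_identical(p$steps, p2$steps)

  expect_length(ss_build_path(src, src, seed = 1L)$moves, 0L)
  one_away <- ss_moves(src)$ss[1]
  expect_length(ss_build_path(src, one_away, seed = 1L)$moves, 1L)
})

test_that("moves with a target strictly approach it and re-validate", {
  src <- ss_endpoint("1PGB"); dst <- ss_endpoint("2GYC")
  d0 <- ss_distance(src, dst)
  mv <- ss_moves(src, target = dst)
  expect_gt(nrow(mv), 0)
  for (k in seq_len(nrow(mv))) {
    expect_lt(ss_distance(mv$ss[k], dst), d0)
    expect_length(ss_validate(mv$ss[k]), 0)
  }
})

test_that("conversion distance is a metric consistent with single-character edits", {
  expect_equal(ss_distance("CCHH", "CCHH"), 0L)
  expect_equal(ss_distance("CHHC", "CCCC"), 2L)
  expect_equal(ss_distance("EECC", "HHCC"), 4L)  # E -> C -> H costs 2 each
  expect_equal(ss_distance("EECC", "HHCC", "hamming"), 2L)
  expect_error(ss_distance("CC", "CCC"), "length")
})
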