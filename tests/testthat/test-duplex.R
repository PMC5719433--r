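test_that("pairing_map is an involution and flags unbalanced input", {
  pm <- pairing_map("((..))")
  expect_equal(pm, c(6L, 5L, NA, NA, 2L, 1L))
  expect_true(all(is.na(pairing_map("...."))))
  expect_error(pairing_map("(()"), "unmatched '\\('")
  expect_error(pairing_map("())"), "unmatched '\\)' at position 3")
  st <- fold_nussinov(random_dna(50L))
  pm2 <- pairing_map(st)
  paired <- which(!is.na(pm2))
  expect_equal(pm2[pm2[paired]], paired)
})

test_that("duplexes with ~2-nt 3' overhangs pass, blunt ends fail", {
  st <- paste0(strrep("(", 21L), strrep(".", 18L), strrep(")", 21L))
  a <- assess_duplex(list(start = 0L, end = 21L), list(start = 41L, end = 60L),
                     st)
  # blunt on one side (a 5' aligned to b 3' end): overhangs off target
  expect_false(a$passes)
  good <- assess_duplex(list(start = 2L, end = 23L),
                        list(start = 39L, end = 60L), st)
  expect_equal(c(good$overhang_a3, good$overhang_b3), c(2L, 2L))
  expect_true(good$passes)
  blunt <- assess_duplex(list(start = 0L, end = 21L),
                         list(start = 39L, end = 60L), st)
  expect_equal(c(blunt$overhang_a3, blunt$overhang_b3), c(0L, 0L))
  expect_false(blunt$passes)
})

test_that("a 1-nt stem bulge does not corrupt the overhang measurement", {
  # left arm 10 pairs, 1-nt bulge, 11 pairs; right arm contiguous
  st <- paste0(strrep("(", 10L), ".", strrep("(", 11L), strrep(".", 4L),
               strrep(")", 21L))
  a <- assess_duplex(list(start = 2L, end = 18L), list(start = 31L, end = 47L),
                     st)
  expect_equal(c(a$overhang_a3, a$overhang_b3), c(2L, 2L))
  expect_true(a$passes)
})

test_that("fully unpaired blocks fail with paired_fraction 0", {
  st <- paste0(strrep("(", 10L), strrep(".", 20L), strrep(")", 10L))
  a <- assess_duplex(list(start = 12L, end = 28L), list(start = 30L, end = 40L),
                     st)
  expect_equal(a$paired_fraction, 0)
  expect_false(a$passes)
})

test_that("assess_duplex is symmetric in its two blocks", {
  st <- paste0(strrep("(", 10L), ".", strrep("(", 11L), strrep(".", 4L),
               strrep(")", 21L))
  a <- assess_duplex(list(start = 2L, end = 18L), list(start = 31L, end = 47L),
                     st)
  b <- assess_duplex(list(start = 31L, end = 47L), list(start = 2L, end = 18L),
                     st)
  expect_equal(a$overhang_a3, b$overhang_b3)
  expect_equal(a$overhang_b3, b$overhang_a3)
  expect_equal(a$passes, b$passes)
})

test_that("fold_nussinov handles canonical small cases", {
  expect_equal(fold_nussinov("GGGAAACCC"), "(((...)))")
  expect_equal(fold_nussinov("AAAAAA"), "......")
  expect_equal(fold_nussinov(""), "")
  expect_error(fold_nussinov(random_dna(401L)), "400")
})

test_that("fold_nussinov pair counts match exhaustive enumeration", {
  set.seed(5)
  for (trial in 1:40) {
    s <- random_dna(sample(6:12, 1L))
    st <- fold_nussinov(s)
    expect_equal(n_pairs(st), enum_max_pairs(s),
                 label = paste("sequence", s))
    # the emitted structure is well formed
    expect_silent(pairing_map(st))
  }
})

test_that("fold_nussinov is maximal over supplied nested structures", {
  set.seed(9)
  cfg <- sim_config(mismatch_rate = 0.1)
  for (i in 1:3) {
    p <- make_hairpin(cfg, i)
    folded <- fold_nussinov(p$sequence)
    expect_gte(n_pairs(folded), n_pairs(p$structure))
  }
})
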