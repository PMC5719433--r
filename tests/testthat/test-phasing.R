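test_that("offset classification follows the register rules", {
  expect_equal(classify_offset(0L, 21L), "canonical")
  expect_equal(classify_offset(2L, 21L), "isomir")
  expect_equal(classify_offset(7L, 21L), "half_phased")
  expect_equal(classify_offset(21L, 21L), "phased")
  expect_equal(classify_offset(25L, 21L), "half_phased")  # residual 4
  expect_equal(classify_offset(-4L, 21L), "half_phased")
  expect_error(classify_offset(0L, 14L), ">= 15")
})

test_that("every offset gets exactly one category and residuals 0-10 are covered", {
  offsets <- -21:42
  cats <- classify_offset(offsets, 21L)
  expect_true(all(cats %in% c("canonical", "isomir", "phased", "half_phased",
                              "unphased")))
  expect_length(cats, length(offsets))
  # with defaults and P = 21 nothing is left unphased
  expect_false(any(cats == "unphased"))
  res <- phase_residual(offsets, 21L)
  expect_true(all(res >= 0L & res <= 10L))
  covered <- sort(unique(res[cats != "unphased"]))
  expect_equal(covered, 0:10)
})

test_that("classification is periodic beyond the isomiR shift", {
  # both offsets must lie outside the absolute-shift zone where the
  # canonical/isomiR special cases apply
  ds <- setdiff(-21:21, -3:3)
  ds <- ds[abs(ds + 21L) > 3L]
  for (d in ds) {
    expect_equal(classify_offset(d, 21L), classify_offset(d + 21L, 21L))
  }
})

test_that("naming runs .1, .2, .3 from the major block 5' to 3'", {
  major <- data.frame(name = "miR168", start = 30L, end = 51L,
                      is_major = TRUE)
  blocks <- rbind(block_row(30L, 51L, 500L),   # canonical
                  block_row(37L, 58L, 80L),    # offset 7: half-phased
                  block_row(58L, 79L, 60L))    # offset 28: half-phased
  calls <- call_precursor(blocks, major)
  expect_equal(calls$name, c("miR168.1", "miR168.2", "miR168.3"))
  expect_equal(calls$category,
               c("canonical", "half_phased", "half_phased"))

  single <- call_precursor(block_row(30L, 51L, 100L), major)
  expect_equal(single$name, "miR168.1")

  phased <- call_precursor(rbind(block_row(30L, 51L, 100L),
                                 block_row(51L, 72L, 40L)),
                           data.frame(name = "miR394c", start = 30L,
                                      end = 51L, is_major = TRUE))
  expect_equal(phased$name, c("miR394c.1", "miR394c.2"))
  expect_equal(phased$category[2], "phased")
})

test_that("isomiR blocks inherit the shadowed name; naming is order-stable", {
  major <- data.frame(name = "miR-t", start = 30L, end = 51L,
                      is_major = TRUE)
  blocks <- rbind(block_row(30L, 51L, 500L),
                  block_row(32L, 53L, 20L),   # isomiR of the major
                  block_row(51L, 72L, 60L))
  calls <- call_precursor(blocks, major)
  expect_equal(calls$name, c("miR-t.1", "miR-t.1", "miR-t.2"))
  expect_equal(calls$category[2], "isomir")
  perm <- blocks[c(3L, 1L, 2L), , drop = FALSE]
  expect_equal(call_precursor(perm, major), calls)
})

test_that("without a major-overlapping block numbering starts at .2", {
  major <- data.frame(name = "miR-t", start = 30L, end = 51L,
                      is_major = TRUE)
  expect_warning(calls <- call_precursor(block_row(55L, 76L, 50L), major),
                 "numbering starts at .2")
  expect_equal(calls$name, "miR-t.2")
  expect_false(any(calls$name == "miR-t.1"))
})

test_that("an offset-0 block of the wrong length is an isomiR, not canonical", {
  major <- data.frame(name = "miR-t", start = 30L, end = 51L,
                      is_major = TRUE)
  calls <- call_precursor(block_row(30L, 53L, 100L, seq = strrep("A", 23L)),
                          major)
  expect_equal(calls$category, "isomir")
})

test_that("star_partner finds the 2-nt-overhang interval on a perfect stem", {
  st <- paste0(strrep("(", 25L), strrep(".", 10L), strrep(")", 25L))
  p <- precursor_record("t", random_dna(60L),
                        data.frame(name = "m", start = 3L, end = 24L,
                                   is_major = TRUE), structure = st)
  star <- star_partner(list(start = 3L, end = 24L), p)
  expect_equal(star, list(start = 38L, end = 59L))
  a <- assess_duplex(list(start = 3L, end = 24L), star, st)
  expect_true(a$passes)
  expect_equal(c(a$overhang_a3, a$overhang_b3), c(2L, 2L))
})

test_that("star_partner returns nothing for mostly unpaired blocks", {
  st <- paste0(strrep("(", 20L), strrep(".", 14L), strrep(")", 20L),
               strrep(".", 6L))
  p <- precursor_record("t", random_dna(60L),
                        data.frame(name = "m", start = 3L, end = 24L,
                                   is_major = TRUE), structure = st)
  expect_null(star_partner(list(start = 22L, end = 36L), p))  # loop
  expect_null(star_partner(list(start = 15L, end = 35L), p))  # 30% paired
  p$structure <- NULL
  expect_error(star_partner(list(start = 3L, end = 24L), p), "fold")
})
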