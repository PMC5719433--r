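test_that("map_reads reports every exact occurrence with full counts", {
  flank5 <- random_dna(30L)
  core <- "TTGGCATTCTGTCCACCTCC"
  pre <- precursor_record(
    "pre1", paste0(flank5, core, random_dna(30L)),
    data.frame(name = "m", start = 30L, end = 50L, is_major = TRUE))
  reads <- data.frame(id = c("hit", "miss"),
                      seq = c(core, "ACGTACGTACGTACGTACGT"),
                      count = c(7L, 1L), stringsAsFactors = FALSE)
  expect_message(aln <- map_reads(reads, list(pre)), "did not map")
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$start, 30L)
  expect_equal(aln$end, 50L)
  expect_equal(aln$count, 7L)
  expect_equal(attr(aln, "n_unmapped"), 1L)
})

test_that("a tandem duplication yields one alignment per occurrence", {
  unit <- random_dna(21L)
  seq <- paste0(random_dna(10L), unit, unit, random_dna(10L))
  pre <- precursor_record(
    "pre1", seq, data.frame(name = "m", start = 10L, end = 31L,
                            is_major = TRUE))
  reads <- data.frame(id = "r", seq = unit, count = 5L,
                      stringsAsFactors = FALSE)
  aln <- map_reads(reads, list(pre))
  # brute-force substring scan as the oracle
  hits <- which(vapply(0:(nchar(seq) - 21L), function(s) {
    substring(seq, s + 1L, s + 21L) == unit
  }, logical(1L))) - 1L
  expect_gte(length(hits), 2L)
  expect_equal(sort(aln$start), sort(hits))
  expect_true(all(aln$count == 5L))
})

test_that("a read hitting several precursors carries its full count to each", {
  unit <- random_dna(21L)
  mk <- function(id) precursor_record(
    id, paste0(random_dna(20L), unit, random_dna(20L)),
    data.frame(name = paste0(id, "-m"), start = 20L, end = 41L,
               is_major = TRUE))
  aln <- map_reads(data.frame(id = "r", seq = unit, count = 9L),
                   list(mk("a"), mk("b")))
  expect_equal(nrow(aln), 2L)
  expect_setequal(aln$precursor_id, c("a", "b"))
  expect_true(all(aln$count == 9L))
})

test_that("blocks aggregate reads within the 3-nt overhang tolerance", {
  aln <- data.frame(read_id = c("a", "b"), seq = strrep("A", 21L),
                    count = c(50L, 10L), precursor_id = "p",
                    start = c(10L, 9L), end = c(31L, 30L),
                    stringsAsFactors = FALSE)
  blk <- detect_blocks(aln)
  expect_equal(nrow(blk), 1L)
  expect_equal(blk$start, 10L)
  expect_equal(blk$total_count, 60L)

  aln$start[2] <- 5L; aln$end[2] <- 26L  # 5 nt beyond: separate blocks
  blk2 <- detect_blocks(aln)
  expect_equal(nrow(blk2), 2L)
  expect_equal(sort(blk2$total_count), c(10L, 50L))
})

test_that("representative ties break by smaller start, then longer read", {
  aln <- data.frame(read_id = c("a", "b"), seq = strrep("A", 21L),
                    count = c(30L, 30L), precursor_id = "p",
                    start = c(40L, 38L), end = c(61L, 59L),
                    stringsAsFactors = FALSE)
  blk <- detect_blocks(aln)
  expect_equal(blk$start[1], 38L)
  aln2 <- data.frame(read_id = c("a", "b"), seq = c(strrep("A", 20L),
                                                    strrep("A", 24L)),
                     count = c(30L, 30L), precursor_id = "p",
                     start = c(40L, 40L), end = c(60L, 64L),
                     stringsAsFactors = FALSE)
  blk2 <- detect_blocks(aln2)
  expect_equal(blk2$end[1], 64L)
})

test_that("greedy block assignment matches the brute-force oracle", {
  set.seed(42)
  for (trial in 1:60) {
    aln <- random_alignments(sample(1:30, 1L))
    got <- detect_blocks(aln)
    want <- oracle_blocks(aln)
    expect_equal(got[c("start", "end", "total_count")], want,
                 ignore_attr = TRUE)
  }
})

test_that("block construction conserves counts and is order-invariant", {
  set.seed(7)
  for (trial in 1:20) {
    aln <- random_alignments(25L)
    blk <- detect_blocks(aln)
    expect_equal(sum(blk$total_count), sum(aln$count))
    perm <- aln[sample.int(nrow(aln)), , drop = FALSE]
    blk2 <- detect_blocks(perm)
    expect_equal(blk[c("start", "end", "total_count")],
                 blk2[c("start", "end", "total_count")])
  }
})

test_that("low-count blocks are removed at the 5-read boundary", {
  blocks <- rbind(block_row(10L, 31L, 4L), block_row(60L, 81L, 5L))
  kept <- filter_blocks(blocks)
  expect_equal(kept$start, 60L)
  expect_equal(attr(kept, "n_low_count"), 1L)
})

test_that("a block bridging two neighbours is removed, the neighbours kept", {
  a <- block_row(0L, 21L, 50L)
  b <- block_row(30L, 51L, 40L)
  bridge <- block_row(15L, 36L, 20L)  # overlaps a by 6 nt, b by 6 nt
  kept <- filter_blocks(rbind(a, bridge, b))
  expect_equal(kept$start, c(0L, 30L))
  expect_equal(attr(kept, "n_spanning"), 1L)
  # overlap within tolerance on one side does not make it spanning
  near <- block_row(18L, 39L, 20L)  # 3 nt overlap with a, deep with b only
  kept2 <- filter_blocks(rbind(a, near, b))
  expect_equal(nrow(kept2), 3L)
})

test_that("raising the count threshold never retains more blocks", {
  set.seed(11)
  for (trial in 1:10) {
    aln <- random_alignments(30L)
    blocks <- detect_blocks(aln)
    n_kept <- vapply(1:8, function(mc) {
      nrow(filter_blocks(blocks, pipeline_params(min_block_count = mc)))
    }, integer(1L))
    expect_true(all(diff(n_kept) <= 0L))
  }
})
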