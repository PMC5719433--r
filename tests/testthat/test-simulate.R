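test_that("simulated hairpins have the expected geometry and structure", {
  set.seed(1)
  cfg <- sim_config()
  p <- make_hairpin(cfg, 1L)
  expect_equal(nchar(p$sequence), 132L)  # 60 + 12 + 60
  expect_silent(pairing_map(p$structure))
  set.seed(2)
  p0 <- make_hairpin(sim_config(mismatch_rate = 0), 1L)
  maj <- major_mature(p0)
  pm <- pairing_map(p0$structure)
  expect_true(all(!is.na(pm[(maj$start + 1L):maj$end])))
  # determinism under a fixed seed
  set.seed(99); a <- make_hairpin(cfg, 1L)
  set.seed(99); b <- make_hairpin(cfg, 1L)
  expect_identical(a, b)
})

test_that("without jitter and noise reads sit only at planted positions", {
  cfg <- sim_config(noise_rate = 0, isomir_jitter_prob = 0, seed = 4L)
  bundle <- simulate_srna(cfg)
  aln <- map_reads(pool_reads(bundle), bundle$precursors)
  truth <- unique(bundle$truth[c("precursor_id", "start")])
  key <- paste(aln$precursor_id, aln$start)
  expect_true(all(key %in% paste(truth$precursor_id, truth$start)))
})

test_that("simulation output is deterministic under a fixed seed", {
  b1 <- simulate_srna(sim_config(seed = 7L))
  b2 <- simulate_srna(sim_config(seed = 7L))
  expect_identical(b1$reads, b2$reads)
  expect_identical(b1$truth, b2$truth)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_sim_bundle(b1, d1)
  write_sim_bundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("library fold changes carry into the truth table", {
  b <- simulate_srna(sim_config(seed = 2L))
  t_nc <- b$truth[b$truth$library == "NC", ]
  t_cca <- b$truth[b$truth$library == "CCA", ]
  m <- match(paste(t_nc$precursor_id, t_nc$name),
             paste(t_cca$precursor_id, t_cca$name))
  expect_equal(t_cca$expected_count[m], 4 * t_nc$expected_count)
  expect_equal(nrow(b$truth),
               length(unique(b$truth$name)) * 4L)
})

test_that("truth tables round-trip through TSV", {
  b <- simulate_srna(sim_config(seed = 3L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_truth(b$truth, f)
  back <- read_truth(f)
  rownames(b$truth) <- NULL
  expect_equal(back, b$truth)
})

test_that("the pipeline recovers all planted species on clean data", {
  for (seed in 1:5) {
    b <- simulate_srna(sim_config(seed = seed, noise_rate = 0))
    res <- suppressWarnings(mirlike_detect(pool_reads(b), b$precursors))
    ev <- evaluate_recovery(res$calls, b$truth)
    expect_equal(ev$precision, 1.0)
    expect_equal(ev$recall, 1.0)
    expect_equal(ev$category_accuracy, 1.0)
  }
})

test_that("planted stars always pass the duplex check on perfect hairpins", {
  for (seed in 1:3) {
    b <- simulate_srna(sim_config(seed = seed, mismatch_rate = 0,
                                  noise_rate = 0))
    res <- suppressWarnings(mirlike_detect(pool_reads(b), b$precursors))
    expect_gt(nrow(res$duplexes), 0L)
    expect_true(all(res$duplexes$passes))
  }
})

test_that("recall degrades monotonically as noise grows", {
  recall_at <- function(noise) {
    mean(vapply(1:6, function(seed) {
      b <- simulate_srna(sim_config(seed = seed, noise_rate = noise))
      res <- suppressWarnings(mirlike_detect(pool_reads(b), b$precursors))
      evaluate_recovery(res$calls, b$truth)$recall
    }, numeric(1L)))
  }
  r <- vapply(c(0, 1, 4), recall_at, numeric(1L))
  expect_true(all(diff(r) <= 0))
  expect_equal(r[1L], 1.0)
})

test_that("recovery metrics ignore call order and flag empty truth", {
  b <- simulate_srna(sim_config(seed = 1L, noise_rate = 0))
  res <- suppressWarnings(mirlike_detect(pool_reads(b), b$precursors))
  ev1 <- evaluate_recovery(res$calls, b$truth)
  shuffled <- res$calls[rev(seq_len(nrow(res$calls))), , drop = FALSE]
  ev2 <- evaluate_recovery(shuffled, b$truth)
  expect_equal(ev1[c("precision", "recall", "category_accuracy")],
               ev2[c("precision", "recall", "category_accuracy")])
  ev3 <- evaluate_recovery(res$calls, b$truth[0L, , drop = FALSE])
  expect_true(is.na(ev3$recall))
})
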