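# Independent oracles and tiny generators used across the suite.

# Brute-force block construction: enumerate candidate representatives in
# count order, repeatedly peeling the highest-count alignment and everything
# inside its tolerance window off the table. Deliberately structured
# differently from the package's mask-based greedy.
oracle_blocks <- function(aln, params = pipeline_params()) {
  aln <- aln[order(-aln$count, aln$start, -(aln$end - aln$start)), ,
             drop = FALSE]
  rows <- list()
  while (nrow(aln) > 0L) {
    rep_row <- aln[1L, ]
    in_win <- aln$start >= rep_row$start - params$overhang_tol &
      aln$end <= rep_row$end + params$overhang_tol
    rows[[length(rows) + 1L]] <- data.frame(
      start = rep_row$start, end = rep_row$end,
      total_count = sum(aln$count[in_win]))
    aln <- aln[!in_win, , drop = FALSE]
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_alignments <- function(n) {
  start <- sample(0:120, n, replace = TRUE)
  len <- sample(18:24, n, replace = TRUE)
  data.frame(read_id = paste0("r", seq_len(n)),
             seq = strrep("A", len),
             count = sample(1:100, n, replace = TRUE),
             precursor_id = "p", start = start, end = start + len,
             stringsAsFactors = FALSE)
}

# Exhaustive maximum base-pair count over all nested structures, by direct
# recursion on "pair position i with some k (or leave it unpaired)" -- a
# different decomposition from the package's dynamic program.
enum_max_pairs <- function(seq, min_loop = 3L) {
  b <- strsplit(chartr("Uu", "TT", toupper(seq)), "", fixed = TRUE)[[1L]]
  ok <- c("AT", "TA", "GC", "CG", "GT", "TG")
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- rec(i + 1L, j)
    for (k in seq.int(i + min_loop + 1L, j)) {
      if (paste0(b[i], b[k]) %in% ok) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    best
  }
  if (length(b) < 2L) return(0L)
  rec(1L, length(b))
}

# count pairs claimed by a dot-bracket string
n_pairs <- function(structure) {
  sum(strsplit(structure, "", fixed = TRUE)[[1L]] == "(")
}

# minimal block table row for classification tests
block_row <- function(start, end, count, pid = "pre1",
                      seq = strrep("A", end - start)) {
  data.frame(precursor_id = pid, start = start, end = end, rep_seq = seq,
             rep_count = count, total_count = count,
             n_members = 1L, stringsAsFactors = FALSE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
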