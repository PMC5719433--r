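#' Map reads to precursors without mismatches
#'
#' Every exact occurrence of every read in every precursor is reported: a read
#' found at two positions of one precursor yields two alignments, and a read
#' found on k precursors yields k alignments, each carrying the read's full
#' count (no fractional assignment). Reads are sense-strand only; pre-miRNAs
#' are single stranded so no reverse-complement mapping is attempted.
#'
#' @param reads data.frame with `id`, `seq`, `count` (see
#'   [read_collapsed_fasta()]).
#' @param precursors list of [precursor_record()] objects.
#' @return data.frame of alignments (`read_id`, `seq`, `count`,
#'   `precursor_id`, `start`, `end`; 0-based half-open), with the number of
#'   unmapped reads in attribute `"n_unmapped"`.
#' @export
map_reads <- function(reads, precursors) {
  stopifnot(is.data.frame(reads))
  if (inherits(precursors, "precursor_record")) precursors <- list(precursors)
  out <- list()
  mapped <- rep(FALSE, nrow(reads))
  lens <- unique(nchar(reads$seq))
  for (p in precursors) {
    n <- nchar(p$sequence)
    for (L in lens) {
      idx <- which(nchar(reads$seq) == L)
      if (L > n || length(idx) == 0L) next
      # index every length-L window of the precursor; overlapping
      # occurrences come out naturally
      starts0 <- 0:(n - L)
      windows <- substring(p$sequence, starts0 + 1L, starts0 + L)
      pos_by_seq <- split(starts0, windows)
      hit_pos <- pos_by_seq[reads$seq[idx]]
      for (k in seq_along(idx)) {
        pos <- hit_pos[[k]]
        if (is.null(pos)) next
        i <- idx[k]
        mapped[i] <- TRUE
        out[[length(out) + 1L]] <- data.frame(
          read_id = reads$id[i], seq = reads$seq[i], count = reads$count[i],
          precursor_id = p$id, start = pos, end = pos + L,
          stringsAsFactors = FALSE)
      }
    }
  }
  aln <- if (length(out) > 0L) do.call(rbind, out) else data.frame(
    read_id = character(0), seq = character(0), count = integer(0),
    precursor_id = character(0), start = integer(0), end = integer(0),
    stringsAsFactors = FALSE)
  aln <- aln[order(aln$precursor_id, aln$start, aln$end, aln$seq), ,
             drop = FALSE]
  rownames(aln) <- NULL
  n_unmapped <- sum(!mapped)
  if (n_unmapped > 0L) message(n_unmapped, " read(s) did not map to any precursor")
  attr(aln, "n_unmapped") <- n_unmapped
  aln
}

#' Cluster alignments on one precursor into blocks
#'
#' Greedy construction: the unassigned alignment with the highest count
#' becomes the block representative (ties: smaller start, then longer read);
#' all unassigned alignments lying within the representative's span extended
#' by `overhang_tol` nt on either end join the block. The loop repeats until
#' every alignment is assigned, so each alignment belongs to exactly one
#' block. The tolerated overhang absorbs imprecise dicing and isomiRs.
#'
#' @param alignments data.frame from [map_reads()], all on one precursor.
#' @param params [pipeline_params()].
#' @return data.frame of blocks sorted by start (`precursor_id`, `start`,
#'   `end`, `rep_seq`, `rep_count`, `total_count`, `n_members`), with a
#'   `members` list-column of per-block alignment data.frames.
#' @export
detect_blocks <- function(alignments, params = pipeline_params()) {
  stopifnot(inherits(params, "pipeline_params"))
  if (is.null(alignments) || nrow(alignments) == 0L) return(empty_blocks())
  if (length(unique(alignments$precursor_id)) != 1L) {
    stop("detect_blocks expects alignments on a single precursor; see mirlike_detect")
  }
  ord <- order(-alignments$count, alignments$start,
               -(alignments$end - alignments$start))
  aln <- alignments[ord, , drop = FALSE]
  assigned <- rep(FALSE, nrow(aln))
  blocks <- list()
  while (!all(assigned)) {
    rep_i <- which(!assigned)[1L]  # highest count among unassigned
    lo <- aln$start[rep_i] - params$overhang_tol
    hi <- aln$end[rep_i] + params$overhang_tol
    member <- !assigned & aln$start >= lo & aln$end <= hi
    members <- aln[member, , drop = FALSE]
    rownames(members) <- NULL
    blocks[[length(blocks) + 1L]] <- data.frame(
      precursor_id = aln$precursor_id[rep_i],
      start = aln$start[rep_i], end = aln$end[rep_i],
      rep_seq = aln$seq[rep_i], rep_count = aln$count[rep_i],
      total_count = sum(members$count), n_members = nrow(members),
      stringsAsFactors = FALSE)
    blocks[[length(blocks)]]$members <- I(list(members))
    assigned <- assigned | member
  }
  out <- do.call(rbind, blocks)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_blocks <- function() {
  df <- data.frame(precursor_id = character(0), start = integer(0),
                   end = integer(0), rep_seq = character(0),
                   rep_count = integer(0), total_count = integer(0),
                   n_members = integer(0), stringsAsFactors = FALSE)
  df$members <- I(list())
  df
}

#' Filter blocks by the spanning and minimum-count rules
#'
#' Two rules are applied in order. First, a block that bridges two distinct
#' neighbouring blocks - overlapping one at-least-as-abundant block on its 5'
#' side and another on its 3' side, each by more than `overhang_tol` nt - is
#' discarded as a spanning artifact. Second, blocks with fewer than
#' `min_block_count` total reads are discarded as likely sequencing error. The numbers removed by
#' each rule are attached as attributes `"n_spanning"` and `"n_low_count"`.
#'
#' @param blocks data.frame from [detect_blocks()].
#' @param params [pipeline_params()].
#' @return filtered block data.frame (same columns).
#' @export
filter_blocks <- function(blocks, params = pipeline_params()) {
  stopifnot(inherits(params, "pipeline_params"))
  if (nrow(blocks) == 0L) {
    attr(blocks, "n_spanning") <- 0L
    attr(blocks, "n_low_count") <- 0L
    return(blocks)
  }
  n <- nrow(blocks)
  spanning <- vapply(seq_len(n), function(i) {
    ov <- interval_overlap(blocks$start[i], blocks$end[i],
                           blocks$start, blocks$end)
    # a bridge artifact is weaker than the blocks it spans: neighbours must
    # be at least as abundant, so stray low-count blocks never turn a
    # genuine species into a "spanning" block
    deep <- ov > params$overhang_tol & seq_len(n) != i &
      blocks$total_count >= blocks$total_count[i]
    left <- which(deep & blocks$start < blocks$start[i])
    right <- which(deep & blocks$end > blocks$end[i])
    # needs two distinct neighbours, one on each side (a single containing
    # block is not "spanning two neighbouring blocks")
    length(left) >= 1L && length(right) >= 1L &&
      length(union(left, right)) >= 2L
  }, logical(1L))
  kept <- blocks[!spanning, , drop = FALSE]
  low <- kept$total_count < params$min_block_count
  out <- kept[!low, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_spanning") <- sum(spanning)
  attr(out, "n_low_count") <- sum(low)
  out
}

#' Export blocks as a plain table
#'
#' @param blocks data.frame from [detect_blocks()] or [filter_blocks()].
#' @param path output TSV (1-based inclusive coordinates).
#' @return the path, invisibly.
#' @export
write_blocks_tsv <- function(blocks, path) {
  tab <- data.frame(precursor_id = blocks$precursor_id,
                    start_1based = blocks$start + 1L,
                    end_1based = blocks$end,
                    representative_seq = blocks$rep_seq,
                    total_count = blocks$total_count,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
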