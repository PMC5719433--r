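#' Discover miRNA-like species on miRNA precursors
#'
#' The full discovery pipeline: reads are mapped to the precursors without
#' mismatches, clustered into blocks around their most abundant
#' representative, filtered by the spanning and minimum-count rules, and each
#' retained block is classified by its 5' offset from the major miRNA and
#' named. Where a precursor carries a secondary structure (or
#' `fold_fallback = TRUE`), each non-canonical species is additionally
#' checked for a miRNA/miRNA*-like duplex with ~2-nt 3' overhangs.
#'
#' @param reads collapsed read data.frame (`id`, `seq`, `count`), e.g. from
#'   [read_collapsed_fasta()] or [pool_reads()].
#' @param precursors list of [precursor_record()] objects.
#' @param params [pipeline_params()].
#' @param fold_fallback fold structure-less precursors with
#'   [fold_nussinov()] (sequences <= 400 nt) instead of skipping their duplex
#'   assessment.
#' @return object of class `mirlike_result`: list with `calls` (one row per
#'   retained block), `blocks` (per-precursor filtered block tables),
#'   `duplexes` (duplex assessments of non-canonical species) and `stats`
#'   (reads mapped/unmapped, blocks removed by each rule).
#' @examples
#' bundle <- simulate_srna(sim_config(n_precursors = 2, noise_rate = 0))
#' res <- mirlike_detect(pool_reads(bundle), bundle$precursors)
#' res
#' @export
mirlike_detect <- function(reads, precursors, params = pipeline_params(),
                           fold_fallback = FALSE) {
  stopifnot(inherits(params, "pipeline_params"))
  if (inherits(precursors, "precursor_record")) precursors <- list(precursors)
  aln <- map_reads(reads, precursors)
  calls <- list()
  blocks_by_pre <- list()
  duplexes <- list()
  stats <- list(n_reads = nrow(reads), n_alignments = nrow(aln),
                n_unmapped = attr(aln, "n_unmapped"),
                n_spanning_removed = 0L, n_low_count_removed = 0L)
  for (p in precursors) {
    sub <- aln[aln$precursor_id == p$id, , drop = FALSE]
    blocks <- detect_blocks(sub, params)
    kept <- filter_blocks(blocks, params)
    stats$n_spanning_removed <- stats$n_spanning_removed +
      attr(kept, "n_spanning")
    stats$n_low_count_removed <- stats$n_low_count_removed +
      attr(kept, "n_low_count")
    blocks_by_pre[[p$id]] <- kept
    if (nrow(kept) == 0L) next
    pcalls <- call_precursor(kept, major_mature(p), params)
    calls[[p$id]] <- pcalls
    struct <- p$structure
    if (is.null(struct) && fold_fallback && nchar(p$sequence) <= 400L) {
      struct <- fold_nussinov(p$sequence)
    }
    if (!is.null(struct)) {
      for (i in which(pcalls$category %in% c("phased", "half_phased"))) {
        block <- list(start = pcalls$start[i], end = pcalls$end[i])
        star <- star_partner(block, within_structure(p, struct), params)
        if (is.null(star)) next
        a <- assess_duplex(block, star, struct, params)
        duplexes[[length(duplexes) + 1L]] <- data.frame(
          precursor_id = p$id, name = pcalls$name[i],
          star_start = star$start, star_end = star$end,
          paired_fraction = a$paired_fraction,
          overhang_a3 = a$overhang_a3, overhang_b3 = a$overhang_b3,
          passes = a$passes, stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (length(calls) > 0L) do.call(rbind, calls) else empty_calls()
  rownames(calls) <- NULL
  duplexes <- if (length(duplexes) > 0L) do.call(rbind, duplexes) else
    data.frame()
  structure(list(calls = calls, blocks = blocks_by_pre, duplexes = duplexes,
                 stats = stats, params = params),
            class = "mirlike_result")
}

# a copy of the precursor carrying the (possibly folded) structure
within_structure <- function(p, struct) {
  p$structure <- struct
  p
}

#' @export
print.mirlike_result <- function(x, ...) {
  cat("<mirlike_result>\n")
  cat(sprintf("  %d reads, %d alignments (%d unmapped reads)\n",
              x$stats$n_reads, x$stats$n_alignments, x$stats$n_unmapped))
  cat(sprintf("  blocks removed: %d spanning, %d below %d reads\n",
              x$stats$n_spanning_removed, x$stats$n_low_count_removed,
              x$params$min_block_count))
  if (nrow(x$calls) == 0L) {
    cat("  no species called\n")
    return(invisible(x))
  }
  tab <- table(x$calls$category)
  cat("  calls:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (nrow(x$duplexes) > 0L) {
    cat(sprintf("  duplexes: %d/%d pass the ~2-nt 3'-overhang check\n",
                sum(x$duplexes$passes), nrow(x$duplexes)))
  }
  invisible(x)
}

#' @export
summary.mirlike_result <- function(object, ...) {
  print(object)
  if (nrow(object$calls) > 0L) {
    cat("\nCalls:\n")
    print(object$calls[c("precursor_id", "name", "category", "offset_d",
                         "residual", "start", "end", "total_count")],
          row.names = FALSE)
  }
  invisible(object)
}

#' Run the discovery pipeline on files
#'
#' File-level wrapper over [mirlike_detect()]: reads one collapsed FASTA per
#' library, pools them for detection, and writes the phasing calls (TSV and
#' GFF3), duplex assessments and per-library species counts to `out_dir`.
#' Per-library counts sum the counts of each library's alignments lying
#' within a call's span extended by `overhang_tol`.
#'
#' @param reads named character vector of collapsed FASTA paths (names are
#'   library ids; unnamed paths use the file name).
#' @param precursor_fasta,annotations,structures input paths (see
#'   [read_precursor_annotations()]); `structures` may be `NULL`.
#' @param out_dir output directory (created if needed).
#' @param params [pipeline_params()].
#' @param fold_fallback see [mirlike_detect()].
#' @return the `mirlike_result`, invisibly; the per-library count table in
#'   its `library_counts` element.
#' @export
run_detect <- function(reads, precursor_fasta, annotations,
                       structures = NULL, out_dir = ".",
                       params = pipeline_params(), fold_fallback = FALSE) {
  nm <- names(reads) %||% rep("", length(reads))
  nm[!nzchar(nm)] <- basename(reads[!nzchar(nm)])
  names(reads) <- nm
  precursors <- read_precursor_annotations(precursor_fasta, annotations,
                                           structures)
  by_lib <- lapply(reads, read_collapsed_fasta)
  pooled <- pool_reads(by_lib)
  res <- mirlike_detect(pooled, precursors, params, fold_fallback)
  lib_counts <- per_library_counts(res$calls, by_lib, precursors, params)
  res$library_counts <- lib_counts
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$calls, file.path(out_dir, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_results_gff(res$calls, file.path(out_dir, "calls.gff3"))
  utils::write.table(res$duplexes, file.path(out_dir, "duplexes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(lib_counts, file.path(out_dir, "library_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf(
    "detect: %d reads -> %d calls; removed %d spanning, %d low-count blocks",
    res$stats$n_reads, nrow(res$calls), res$stats$n_spanning_removed,
    res$stats$n_low_count_removed))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

per_library_counts <- function(calls, reads_by_lib, precursors, params) {
  if (nrow(calls) == 0L) {
    return(data.frame(precursor_id = character(0), name = character(0),
                      library = character(0), count = integer(0)))
  }
  out <- list()
  for (lib in names(reads_by_lib)) {
    aln <- map_reads(reads_by_lib[[lib]], precursors)
    for (i in seq_len(nrow(calls))) {
      in_span <- aln$precursor_id == calls$precursor_id[i] &
        aln$start >= calls$start[i] - params$overhang_tol &
        aln$end <= calls$end[i] + params$overhang_tol
      out[[length(out) + 1L]] <- data.frame(
        precursor_id = calls$precursor_id[i], name = calls$name[i],
        library = lib, count = as.integer(sum(aln$count[in_span])),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
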