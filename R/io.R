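#' Read collapsed small-RNA reads from FASTA
#'
#' Collapsed FASTA carries one record per unique read with its copy number in
#' the header. Two header dialects are accepted: `>{id}_x{count}` (the common
#' collapsed-read convention) and `>{id} count={count}`. Records with the same
#' sequence are merged by summing counts; reads outside the accepted 15-34 nt
#' small-RNA length range are dropped with a message.
#'
#' @param path FASTA file of collapsed reads.
#' @return data.frame with columns `id`, `seq`, `count` (one row per unique
#'   sequence). An empty file yields an empty data.frame with a warning.
#' @export
read_collapsed_fasta <- function(path) {
  set <- read_fasta_or_empty(path)
  if (length(set) == 0L) {
    warning("no reads in '", path, "'")
    return(empty_reads())
  }
  headers <- names(set)
  counts <- parse_collapsed_counts(headers)
  bad <- is.na(counts)
  if (any(bad)) {
    stop("collapsed FASTA header without a parsable count at record ",
         which(bad)[1L], ": '>", headers[which(bad)[1L]], "'")
  }
  ids <- sub("_x[0-9]+$", "", sub("[ \t].*$", "", headers))
  small_reads(ids, as.character(set), counts)
}

parse_collapsed_counts <- function(headers) {
  vapply(headers, function(h) {
    if (grepl("_x[0-9]+$", h)) {
      as.integer(sub(".*_x([0-9]+)$", "\\1", h))
    } else if (grepl("(^|[ \t])count=[0-9]+", h)) {
      as.integer(sub(".*count=([0-9]+).*", "\\1", h))
    } else {
      NA_integer_
    }
  }, integer(1L), USE.NAMES = FALSE)
}

#' Collapse raw FASTQ reads
#'
#' Unique sequences are counted and qualities discarded. Reads outside the
#' 15-34 nt small-RNA length range are excluded and their number reported.
#'
#' @param path FASTQ file.
#' @return data.frame with columns `id`, `seq`, `count`.
#' @export
collapse_fastq <- function(path) {
  set <- tryCatch(
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path)),
    error = function(e) {
      if (file.exists(path) && file.size(path) == 0L) return(NULL)
      stop("malformed FASTQ '", path, "': ", conditionMessage(e))
    })
  if (is.null(set) || length(set) == 0L) return(empty_reads())
  quals <- tryCatch(as.character(Biostrings::quality(set)),
                    error = function(e) NULL)
  if (is.null(quals) || any(nchar(quals) != BiocGenerics::width(set))) {
    stop("malformed FASTQ '", path,
         "': sequence and quality lengths differ")
  }
  seqs <- normalize_seq(as.character(set))
  len <- nchar(seqs)
  keep <- len >= 15L & len <= 34L
  if (any(!keep)) {
    message(sum(!keep), " read(s) outside 15-34 nt excluded")
  }
  seqs <- seqs[keep]
  if (length(seqs) == 0L) return(empty_reads())
  tab <- table(seqs)
  small_reads(paste0("r", seq_along(tab)), names(tab), as.integer(tab))
}

small_reads <- function(id, seq, count) {
  seq <- normalize_seq(seq)
  stopifnot(all(count >= 1L))
  len <- nchar(seq)
  keep <- len >= 15L & len <= 34L
  if (any(!keep)) message(sum(!keep), " read(s) outside 15-34 nt excluded")
  df <- data.frame(id = id[keep], seq = seq[keep],
                   count = as.integer(count[keep]),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$seq)) {
    agg <- stats::aggregate(count ~ seq, df, sum)
    df <- data.frame(id = df$id[match(agg$seq, df$seq)], seq = agg$seq,
                     count = as.integer(agg$count), stringsAsFactors = FALSE)
  }
  df <- df[order(df$seq), , drop = FALSE]
  rownames(df) <- NULL
  df
}

empty_reads <- function() {
  data.frame(id = character(0), seq = character(0), count = integer(0),
             stringsAsFactors = FALSE)
}

read_fasta_or_empty <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) return(Biostrings::BStringSet())
  Biostrings::readBStringSet(path)
}

#' Read precursors with their mature annotations
#'
#' @param fasta_path FASTA of precursor sequences (RNA or DNA alphabet).
#' @param annot_path tab-separated annotation table with header columns
#'   `precursor_id`, `name`, `start_1based`, `end_1based` (1-based inclusive),
#'   `is_major`; lines starting with `#` are skipped.
#' @param structure_path optional dot-bracket structure file (RNAfold layout:
#'   header, sequence, structure per record).
#' @return named list of [precursor_record()] objects.
#' @export
read_precursor_annotations <- function(fasta_path, annot_path,
                                       structure_path = NULL) {
  set <- Biostrings::readBStringSet(fasta_path)
  seqs <- stats::setNames(as.character(set), sub("[ \t].*$", "", names(set)))
  ann <- read_tsv_hash(annot_path)
  req <- c("precursor_id", "name", "start_1based", "end_1based", "is_major")
  if (!all(req %in% names(ann))) {
    stop("annotation table must have columns ", paste(req, collapse = ", "))
  }
  missing <- setdiff(unique(ann$precursor_id), names(seqs))
  if (length(missing) > 0L) {
    stop("annotation refers to precursor(s) absent from FASTA: ",
         paste(missing, collapse = ", "))
  }
  structures <- if (is.null(structure_path)) NULL else
    read_structure_file(structure_path)
  out <- lapply(unique(ann$precursor_id), function(pid) {
    rows <- ann[ann$precursor_id == pid, , drop = FALSE]
    precursor_record(
      id = pid, sequence = seqs[[pid]],
      matures = data.frame(name = rows$name,
                           start = rows$start_1based - 1L,
                           end = rows$end_1based,
                           is_major = as.logical(rows$is_major)),
      structure = if (!is.null(structures) && pid %in% names(structures))
        structures[[pid]] else NULL)
  })
  stats::setNames(out, unique(ann$precursor_id))
}

#' Read a dot-bracket structure file
#'
#' Expects the RNAfold output layout per record: a `>` header line, the
#' sequence line, then the structure line (a trailing free-energy field in
#' parentheses after whitespace is stripped).
#'
#' @param path structure file.
#' @return named character vector of dot-bracket strings.
#' @export
read_structure_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no records in structure file '", path, "'")
  out <- character(0)
  for (s in starts) {
    if (s + 2L > length(lines)) stop("truncated structure record at line ", s)
    id <- sub("[ \t].*$", "", sub("^>", "", lines[s]))
    struct <- sub("[ \t].*$", "", lines[s + 2L])
    if (grepl("[^().]", struct)) {
      stop("invalid dot-bracket characters for '", id, "'")
    }
    out[id] <- struct
  }
  out
}

#' Write phasing calls as GFF3
#'
#' Internal 0-based half-open coordinates are emitted as standard 1-based
#' inclusive GFF3 columns; category, total count, offset and name become
#' attributes. An empty call set yields a header-only file.
#'
#' @param calls data.frame of phasing calls (see [call_precursor()]).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_results_gff <- function(calls, path) {
  if (is.null(calls) || nrow(calls) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = calls$precursor_id,
      ranges = IRanges::IRanges(start = calls$start + 1L, end = calls$end),
      strand = "+")
    gr$source <- "mirphase"
    gr$type <- "small_RNA"
    gr$ID <- calls$name
    gr$category <- calls$category
    gr$count <- calls$total_count
    gr$offset <- calls$offset_d
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write collapsed reads as FASTA
#'
#' @param reads data.frame with `id`, `seq`, `count`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_collapsed_fasta <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads) > 0L) {
    writeLines(paste0(">", reads$id, "_x", reads$count, "\n", reads$seq), con)
  }
  invisible(path)
}

#' Write precursor sequences, annotations and structures
#'
#' Inverse of [read_precursor_annotations()]: `write_annotations` emits the
#' 1-based inclusive TSV dialect that the reader expects.
#'
#' @param precursors list of `precursor_record` objects.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_precursor_fasta <- function(precursors, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in precursors) writeLines(paste0(">", p$id, "\n", p$sequence), con)
  invisible(path)
}

#' @rdname write_precursor_fasta
#' @export
write_annotations <- function(precursors, path) {
  rows <- do.call(rbind, lapply(precursors, function(p) {
    data.frame(precursor_id = p$id, name = p$matures$name,
               start_1based = p$matures$start + 1L,
               end_1based = p$matures$end,
               is_major = p$matures$is_major, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_precursor_fasta
#' @export
write_structures <- function(precursors, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in precursors) {
    if (!is.null(p$structure)) {
      writeLines(paste0(">", p$id, "\n", p$sequence, "\n", p$structure), con)
    }
  }
  invisible(path)
}
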