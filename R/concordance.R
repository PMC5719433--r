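#' Classify a PCR-cloned amplicon against its expected sequence
#'
#' Verdict semantics follow amplicon re-sequencing practice: an empty
#' observed sequence (no clone recovered) is `no_match`; identity with the
#' expected sequence or with its reverse complement (cloning orientation is
#' arbitrary) is `match`; otherwise a shared contiguous run of at least
#' `near_min_len` nt against the expected sequence or its reverse complement
#' is `near`; anything else is `no_match`.
#'
#' @param expected sequence determined by RNA-seq (non-empty).
#' @param observed sequence recovered by PCR cloning; may be `""` or `NA`.
#' @param near_min_len minimum shared contiguous run for a `near` verdict
#'   (default 13 nt).
#' @return one of `"match"`, `"near"`, `"no_match"`.
#' @examples
#' classify_amplicon("TGTGTTCTCAGGTCGCCCCTG", "CAGGGGCGACCTGAGAACACA")
#' @export
classify_amplicon <- function(expected, observed, near_min_len = 13L) {
  stopifnot(length(expected) == 1L, nzchar(expected))
  expected <- normalize_seq(expected)
  if (is.na(observed) || !nzchar(observed)) return("no_match")
  observed <- normalize_seq(observed)
  rc <- revcomp(expected)
  if (observed == expected || observed == rc) return("match")
  run <- max(lcs_substring(observed, expected), lcs_substring(observed, rc))
  if (run >= near_min_len) "near" else "no_match"
}

#' Score a table of amplicon pairs
#'
#' A species is counted as confirmed when its cloned product is the same
#' (`match`) or nearly the same (`near`) as the RNA-seq-determined sequence.
#'
#' @param pairs data.frame with columns `name`, `expected`, `observed`
#'   (observed may be empty).
#' @param near_min_len passed to [classify_amplicon()].
#' @return object of class `amplicon_summary`: list with counts `n_match`,
#'   `n_near`, `n_no_match`, `n_confirmed`, `n_total` and the per-pair
#'   `verdicts` data.frame.
#' @export
score_table <- function(pairs, near_min_len = 13L) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(structure(list(n_match = 0L, n_near = 0L, n_no_match = 0L,
                          n_confirmed = 0L, n_total = 0L,
                          verdicts = data.frame()),
                     class = "amplicon_summary"))
  }
  verdict <- vapply(seq_len(nrow(pairs)), function(i) {
    classify_amplicon(pairs$expected[i], pairs$observed[i], near_min_len)
  }, character(1L))
  verdicts <- cbind(pairs, verdict = verdict, stringsAsFactors = FALSE)
  structure(list(n_match = sum(verdict == "match"),
                 n_near = sum(verdict == "near"),
                 n_no_match = sum(verdict == "no_match"),
                 n_confirmed = sum(verdict != "no_match"),
                 n_total = length(verdict), verdicts = verdicts),
            class = "amplicon_summary")
}

#' @export
print.amplicon_summary <- function(x, ...) {
  cat(sprintf(
    "<amplicon_summary> %d pairs: %d match, %d near, %d no_match (confirmed %d/%d)\n",
    x$n_total, x$n_match, x$n_near, x$n_no_match, x$n_confirmed, x$n_total))
  invisible(x)
}

#' Packaged amplicon sequence-validation pairs
#'
#' The 13 qRT-PCR amplicons (known, novel, phased and half-phased species)
#' whose cloned products were compared against their RNA-seq-determined
#' sequences. The published table concatenates the two sequence columns for
#' some rows; the splits used here are documented in the fixture file.
#'
#' @return data.frame with `type`, `name`, `expected`, `observed`.
#' @export
amplicon_fixture <- function() {
  path <- system.file("extdata", "amplicon_validation.tsv",
                      package = "mirphase", mustWork = TRUE)
  tab <- read_tsv_hash(path)
  tab$observed[is.na(tab$observed)] <- ""
  tab
}

#' Packaged qRT-PCR detection outcomes
#'
#' Detection (confirmed / not confirmed) of the 24 assayed species by type:
#' 10 canonical miRNAs, 6 phased and 8 half-phased miRNA-like RNAs.
#'
#' @return data.frame with `type`, `name`, `confirmed` (logical).
#' @export
detection_fixture <- function() {
  path <- system.file("extdata", "qpcr_detection.tsv",
                      package = "mirphase", mustWork = TRUE)
  tab <- read_tsv_hash(path)
  tab$confirmed <- as.logical(tab$confirmed)
  tab
}

#' qRT-PCR detection ratios by species type
#'
#' @param detection data.frame as returned by [detection_fixture()].
#' @return data.frame with one row per type plus a `total` row: `n_confirmed`,
#'   `n_assayed`, `percent`.
#' @export
detection_ratios <- function(detection = detection_fixture()) {
  by_type <- lapply(split(detection, detection$type), function(d) {
    data.frame(type = d$type[1L], n_confirmed = sum(d$confirmed),
               n_assayed = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, by_type)
  out <- rbind(out, data.frame(type = "total",
                               n_confirmed = sum(detection$confirmed),
                               n_assayed = nrow(detection)))
  out$percent <- 100 * out$n_confirmed / out$n_assayed
  rownames(out) <- NULL
  out
}

#' Classify 5' RACE cleavage positions against the binding region
#'
#' Each cloned 5' end is placed relative to the miRNA:target base-pairing
#' region on the transcript: `within` if it falls inside the (half-open)
#' binding interval, `upstream` if before its start, `downstream` otherwise.
#'
#' @param clones data.frame with `target_id`, `position` (0-based on the
#'   transcript), `count` (number of clones, >= 1).
#' @param binding_start,binding_end binding region, 0-based half-open.
#' @return the clones data.frame with a `region` column; per-region clone
#'   totals in attribute `"region_counts"`.
#' @export
classify_cleavage <- function(clones, binding_start, binding_end) {
  binding_start <- as.integer(binding_start)
  binding_end <- as.integer(binding_end)
  if (binding_start >= binding_end) stop("binding_start must be < binding_end")
  stopifnot(all(clones$count >= 1L))
  pos <- as.integer(clones$position)
  region <- ifelse(pos < binding_start, "upstream",
            ifelse(pos < binding_end, "within", "downstream"))
  out <- cbind(clones, region = region, stringsAsFactors = FALSE)
  counts <- vapply(c("upstream", "within", "downstream"), function(r) {
    as.integer(sum(out$count[out$region == r]))
  }, integer(1L))
  attr(out, "region_counts") <- counts
  out
}
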