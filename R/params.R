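#' Pipeline parameters
#'
#' Bundles the thresholds used throughout block detection and phasing
#' classification. Defaults encode the discovery rules: reads may extend at
#' most 3 nt beyond a block representative on either end, blocks with fewer
#' than 5 total reads are discarded as likely sequencing error, 5' shifts of
#' 1-3 nt are isomiRs, deviations of 4-11 nt from the phase grid are
#' half-phased, and miRNA/miRNA* duplexes carry ~2-nt 3' overhangs.
#'
#' @param overhang_tol integer nt a member read may extend beyond the block
#'   representative on either end (default 3).
#' @param min_block_count minimum total read count for a block to be kept
#'   (default 5).
#' @param isomir_max_shift maximum 5' shift (nt) still treated as an isomiR
#'   of an existing species (default 3).
#' @param halfphase_min,halfphase_max residual band (nt) from the phase grid
#'   that defines half-phased species (defaults 4 and 11).
#' @param duplex_overhang expected 3' overhang (nt) of a Dicer duplex
#'   (default 2).
#' @param duplex_overhang_tol tolerated deviation from `duplex_overhang`
#'   (default 1, i.e. 1-3 nt passes).
#' @return an object of class `pipeline_params` (a validated list).
#' @examples
#' pipeline_params()
#' pipeline_params(min_block_count = 10)
#' @export
pipeline_params <- function(overhang_tol = 3L,
                            min_block_count = 5L,
                            isomir_max_shift = 3L,
                            halfphase_min = 4L,
                            halfphase_max = 11L,
                            duplex_overhang = 2L,
                            duplex_overhang_tol = 1L) {
  p <- list(
    overhang_tol = as.integer(overhang_tol),
    min_block_count = as.integer(min_block_count),
    isomir_max_shift = as.integer(isomir_max_shift),
    halfphase_min = as.integer(halfphase_min),
    halfphase_max = as.integer(halfphase_max),
    duplex_overhang = as.integer(duplex_overhang),
    duplex_overhang_tol = as.integer(duplex_overhang_tol)
  )
  if (any(vapply(p, function(v) length(v) != 1L || is.na(v), logical(1L)))) {
    stop("all pipeline parameters must be single non-missing integers")
  }
  if (p$min_block_count < 1L) stop("min_block_count must be >= 1")
  if (p$overhang_tol < 0L) stop("overhang_tol must be >= 0")
  if (!(0L <= p$isomir_max_shift && p$isomir_max_shift < p$halfphase_min &&
        p$halfphase_min <= p$halfphase_max)) {
    stop("need 0 <= isomir_max_shift < halfphase_min <= halfphase_max")
  }
  if (p$duplex_overhang < 0L || p$duplex_overhang_tol < 0L) {
    stop("duplex overhang parameters must be >= 0")
  }
  structure(p, class = "pipeline_params")
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat("Pipeline parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %d\n", nm, x[[nm]]))
  invisible(x)
}
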