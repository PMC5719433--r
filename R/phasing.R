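#' Classify a block by its 5' offset from the major miRNA
#'
#' The phase grid is anchored at the major miRNA's 5' end with period equal
#' to the major miRNA length (typically 21 nt). An offset of 0 is the
#' canonical species; shifts of 1 to `isomir_max_shift` nt are isomiRs of the
#' major; otherwise the symmetric register residual
#' `min(d mod P, P - d mod P)` decides: residuals within the isomiR shift are
#' phased (on-grid), residuals in the `halfphase_min`-`halfphase_max` band
#' are half-phased (mid-register), anything else is unphased.
#'
#' @param offset_d signed 5' offset(s) in nt (block start minus major start).
#' @param period_P phase period in nt, the major miRNA length; must be >= 15.
#' @param params [pipeline_params()].
#' @return character vector of categories among `"canonical"`, `"isomir"`,
#'   `"phased"`, `"half_phased"`, `"unphased"`.
#' @examples
#' classify_offset(c(0, 2, 7, 21, 25), 21)
#' @export
classify_offset <- function(offset_d, period_P, params = pipeline_params()) {
  stopifnot(inherits(params, "pipeline_params"))
  period_P <- as.integer(period_P)
  if (length(period_P) != 1L || is.na(period_P) || period_P < 15L) {
    stop("period_P must be a single integer >= 15")
  }
  offset_d <- as.integer(offset_d)
  m <- offset_d %% period_P            # R: non-negative for negative offsets
  residual <- pmin(m, period_P - m)
  ifelse(offset_d == 0L, "canonical",
  ifelse(abs(offset_d) <= params$isomir_max_shift, "isomir",
  ifelse(residual <= params$isomir_max_shift, "phased",
  ifelse(residual >= params$halfphase_min & residual <= params$halfphase_max,
         "half_phased", "unphased"))))
}

#' Register residual of an offset on the phase grid
#'
#' @inheritParams classify_offset
#' @return integer residual(s) in `[0, floor(period_P/2)]`.
#' @export
phase_residual <- function(offset_d, period_P) {
  m <- as.integer(offset_d) %% as.integer(period_P)
  as.integer(pmin(m, period_P - m))
}

#' Call and name the species on one precursor
#'
#' Each retained block receives exactly one category and name. The block
#' covering the major mature annotation is the canonical species
#' `{major}.1`; phased and half-phased blocks are numbered `.2`, `.3`, ...
#' in 5' to 3' order; a block whose 5' end lies within the isomiR shift of an
#' already named species is an isomiR and inherits that species' name;
#' unphased blocks are named `{major}.u1`, `{major}.u2`, ...
#'
#' @param blocks filtered block data.frame (one precursor; see
#'   [filter_blocks()]).
#' @param major one-row data.frame (`name`, `start`, `end`) for the major
#'   mature miRNA, e.g. from [major_mature()].
#' @param params [pipeline_params()].
#' @return data.frame of phasing calls: `precursor_id`, `name`, `category`,
#'   `offset_d`, `period`, `residual`, `start`, `end`, `total_count`,
#'   `rep_seq`.
#' @export
call_precursor <- function(blocks, major, params = pipeline_params()) {
  stopifnot(inherits(params, "pipeline_params"))
  major <- as.data.frame(major)[1L, , drop = FALSE]
  period <- as.integer(major$end - major$start)
  if (nrow(blocks) == 0L) return(empty_calls())
  offset <- as.integer(blocks$start - major$start)
  category <- classify_offset(offset, period, params)
  # canonical requires matching length, else it is a 3' isoform
  len_ok <- (blocks$end - blocks$start) == period
  category[category == "canonical" & !len_ok] <- "isomir"
  residual <- phase_residual(offset, period)

  ov <- interval_overlap(blocks$start, blocks$end, major$start, major$end)
  has_major_block <- any(ov > 0L)
  major_idx <- NA_integer_
  if (has_major_block) {
    cand <- which(ov == max(ov))
    major_idx <- cand[order(-blocks$total_count[cand], blocks$start[cand])][1L]
  } else {
    warning("no block overlaps the major miRNA annotation on '",
            blocks$precursor_id[1L], "'; numbering starts at .2")
  }

  name <- rep(NA_character_, nrow(blocks))
  if (!is.na(major_idx)) name[major_idx] <- paste0(major$name, ".1")

  # isomiRs of the major inherit the canonical name
  shadow_major <- category == "isomir" & is.na(name)
  name[shadow_major] <- paste0(major$name, ".1")

  # new species 5' -> 3'; an on-grid block starting within the isomiR shift
  # of the previously named species is merged into that species' call
  suffix <- 2L
  last_named_start <- if (!is.na(major_idx)) blocks$start[major_idx] else NULL
  last_named_name <- if (!is.na(major_idx)) name[major_idx] else NULL
  for (i in order(blocks$start)) {
    if (!is.na(name[i]) || !category[i] %in% c("phased", "half_phased")) next
    if (!is.null(last_named_start) &&
        abs(blocks$start[i] - last_named_start) <= params$isomir_max_shift) {
      name[i] <- last_named_name
      category[i] <- "isomir"
      next
    }
    name[i] <- paste0(major$name, ".", suffix)
    suffix <- suffix + 1L
    last_named_start <- blocks$start[i]
    last_named_name <- name[i]
  }

  u <- which(is.na(name) & category == "unphased")
  if (length(u) > 0L) {
    u <- u[order(blocks$start[u])]
    name[u] <- paste0(major$name, ".u", seq_along(u))
  }
  # leftover isomiRs with no species to shadow keep the canonical name
  name[is.na(name)] <- paste0(major$name, ".1")

  out <- data.frame(precursor_id = blocks$precursor_id, name = name,
                    category = category, offset_d = offset, period = period,
                    residual = residual, start = blocks$start,
                    end = blocks$end, total_count = blocks$total_count,
                    rep_seq = blocks$rep_seq, stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_calls <- function() {
  data.frame(precursor_id = character(0), name = character(0),
             category = character(0), offset_d = integer(0),
             period = integer(0), residual = integer(0), start = integer(0),
             end = integer(0), total_count = integer(0),
             rep_seq = character(0), stringsAsFactors = FALSE)
}

#' Locate the miRNA* partner interval of a block
#'
#' Uses the precursor's dot-bracket structure to find the interval on the
#' opposite arm pairing with the block, extended so that each strand's 3' end
#' overhangs its partner's paired 5' end by `duplex_overhang` nt (the Dicer
#' signature). The pairing register is the median of `i + partner(i)` over
#' the block's paired positions, which tolerates small bulges.
#'
#' @param block list or one-row data.frame with `start`, `end` (0-based
#'   half-open).
#' @param precursor a [precursor_record()] carrying a structure.
#' @param params [pipeline_params()].
#' @return list with `start` and `end` of the partner interval, or `NULL`
#'   when fewer than half of the block's positions are paired.
#' @export
star_partner <- function(block, precursor, params = pipeline_params()) {
  if (is.null(precursor$structure)) {
    stop("precursor '", precursor$id, "' has no structure; fold one first ",
         "(see fold_nussinov) or supply a dot-bracket file")
  }
  pm <- pairing_map(precursor$structure)
  s <- as.integer(block$start); e <- as.integer(block$end)
  pos <- seq.int(s, e - 1L)
  partner <- pm[pos + 1L] - 1L  # back to 0-based
  paired <- !is.na(partner)
  if (mean(paired) < 0.5) return(NULL)
  reg <- stats::median(pos[paired] + partner[paired])
  o <- params$duplex_overhang
  n <- nchar(precursor$structure)
  list(start = max(0L, as.integer(round(reg - e + 1L + o))),
       end = min(n, as.integer(round(reg - s + 1L + o))))
}
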