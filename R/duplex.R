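#' Base-pair partner map of a dot-bracket structure
#'
#' @param structure dot-bracket string (characters `(`, `)`, `.`).
#' @return integer vector, one element per position (1-based): the partner
#'   position of each paired base, `NA` for unpaired. The map is an
#'   involution: `pm[pm[i]] == i` for paired `i`.
#' @examples
#' pairing_map("((..))")
#' @export
pairing_map <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad) > 0L) {
    stop("invalid dot-bracket character at position ", bad[1L])
  }
  pm <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) {
        stop("unbalanced structure: unmatched ')' at position ", i)
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pm[i] <- j
      pm[j] <- i
    }
  }
  if (length(stack) > 0L) {
    stop("unbalanced structure: unmatched '(' at position ", stack[1L])
  }
  pm
}

#' Assess a candidate miRNA/miRNA* duplex
#'
#' Checks whether two blocks form a Dicer-like duplex on the precursor
#' hairpin: at least half of the positions must pair into the other block and
#' both 3' overhangs must be within `duplex_overhang_tol` of
#' `duplex_overhang` (~2 nt). Overhangs are measured on the median pairing
#' register (the median of `i + partner(i)` over the inter-block pairs), so
#' single-nucleotide bulges in the stem do not corrupt the measurement.
#'
#' @param block_a,block_b lists or one-row data.frames with `start`, `end`
#'   (0-based half-open intervals on the precursor).
#' @param structure dot-bracket string of the precursor.
#' @param params [pipeline_params()].
#' @return object of class `duplex_assessment`: a list with `paired_fraction`
#'   (fraction of `block_a` positions paired into `block_b`), signed 3'
#'   overhangs `overhang_a3` and `overhang_b3`, and `passes`.
#' @export
assess_duplex <- function(block_a, block_b, structure,
                          params = pipeline_params()) {
  stopifnot(inherits(params, "pipeline_params"))
  n <- nchar(structure)
  sa <- as.integer(block_a$start); ea <- as.integer(block_a$end)
  sb <- as.integer(block_b$start); eb <- as.integer(block_b$end)
  if (sa < 0L || sb < 0L || ea > n || eb > n || sa >= ea || sb >= eb) {
    stop("block intervals must lie within the structure")
  }
  pm <- pairing_map(structure)
  pos_a <- seq.int(sa, ea - 1L)
  partner <- pm[pos_a + 1L] - 1L
  into_b <- !is.na(partner) & partner >= sb & partner < eb
  len_a <- ea - sa; len_b <- eb - sb
  if (!any(into_b)) {
    return(structure(list(strand_a = c(sa, ea), strand_b = c(sb, eb),
                          paired_fraction = 0, overhang_a3 = NA_integer_,
                          overhang_b3 = NA_integer_, passes = FALSE),
                     class = "duplex_assessment"))
  }
  reg <- stats::median(pos_a[into_b] + partner[into_b])
  overhang_a3 <- as.integer(round((ea - 1L) - (reg - sb)))
  overhang_b3 <- as.integer(round((eb - 1L) - (reg - sa)))
  n_pairs <- sum(into_b)
  passes <- (n_pairs / max(len_a, len_b)) >= 0.5 &&
    abs(overhang_a3 - params$duplex_overhang) <= params$duplex_overhang_tol &&
    abs(overhang_b3 - params$duplex_overhang) <= params$duplex_overhang_tol
  structure(list(strand_a = c(sa, ea), strand_b = c(sb, eb),
                 paired_fraction = n_pairs / len_a,
                 overhang_a3 = overhang_a3, overhang_b3 = overhang_b3,
                 passes = passes),
            class = "duplex_assessment")
}

#' @export
print.duplex_assessment <- function(x, ...) {
  cat(sprintf(
    "<duplex_assessment> a=[%d,%d) b=[%d,%d) paired=%.2f overhangs=(%s,%s) %s\n",
    x$strand_a[1L], x$strand_a[2L], x$strand_b[1L], x$strand_b[2L],
    x$paired_fraction, x$overhang_a3, x$overhang_b3,
    if (isTRUE(x$passes)) "PASS" else "fail"))
  invisible(x)
}

#' Base-pair-maximizing secondary structure (Nussinov)
#'
#' Deterministic fallback folder for precursors supplied without a structure.
#' Maximizes the number of nested Watson-Crick plus GU wobble pairs with a
#' minimum hairpin loop, and resolves ties in the traceback by always pairing
#' the leftmost available partner. This is a combinatorial folder, not a
#' thermodynamic one; externally computed minimum-free-energy structures are
#' preferred when available.
#'
#' @param sequence nucleotide string (<= 400 nt; the dynamic program is
#'   cubic).
#' @param min_loop minimum number of unpaired bases enclosed by a pair
#'   (default 3).
#' @return dot-bracket string of the same length.
#' @examples
#' fold_nussinov("GGGAAACCC")
#' @export
fold_nussinov <- function(sequence, min_loop = 3L) {
  sequence <- normalize_seq(sequence)
  n <- nchar(sequence)
  if (n > 400L) {
    stop("sequence longer than 400 nt; supply an externally folded structure")
  }
  if (n == 0L) return("")
  min_loop <- as.integer(min_loop)
  b <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  alpha <- c("A", "C", "G", "T", "N")
  pairable <- matrix(FALSE, 5L, 5L, dimnames = list(alpha, alpha))
  pairable["A", "T"] <- pairable["T", "A"] <- TRUE
  pairable["G", "C"] <- pairable["C", "G"] <- TRUE
  pairable["G", "T"] <- pairable["T", "G"] <- TRUE
  pairmat <- pairable[b, b, drop = FALSE]  # position-by-position lookup
  # D is 1-padded on both axes so that zero-width subproblems index cleanly:
  # D[i + 1, j + 1] = max pairs on sequence[i..j] (1-based i, j)
  D <- matrix(0L, n + 2L, n + 2L)
  if (n >= min_loop + 2L) {
    for (span in seq.int(min_loop + 1L, n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- D[i + 1L, j]  # j unpaired
        ks <- seq.int(i, j - min_loop - 1L)
        ks <- ks[pairmat[ks, j]]
        if (length(ks) > 0L) {
          cand <- D[i + 1L, ks] + 1L + D[cbind(ks + 2L, j)]
          best <- max(best, cand)
        }
        D[i + 1L, j + 1L] <- best
      }
    }
  }
  out <- rep(".", n)
  trace <- function(i, j) {
    while (j - i > min_loop) {
      target <- D[i + 1L, j + 1L]
      if (target == 0L) return(invisible())
      paired <- FALSE
      for (k in seq.int(i, j - min_loop - 1L)) {
        if (pairmat[k, j] &&
            D[i + 1L, k] + 1L + D[k + 2L, j] == target) {
          out[k] <<- "("
          out[j] <<- ")"
          trace(k + 1L, j - 1L)
          j <- k - 1L  # continue on the left remainder [i, k-1]
          paired <- TRUE
          break
        }
      }
      if (!paired) j <- j - 1L
    }
    invisible()
  }
  trace(1L, n)
  paste(out, collapse = "")
}
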