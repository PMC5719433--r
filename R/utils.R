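#' Normalize a nucleotide string
#'
#' Uppercases and converts U to T so that RNA precursors and cDNA-sequenced
#' reads live in one alphabet. Only ACGTUN (and case variants) are accepted.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector over the DNA alphabet (ACGTN).
#' @export
normalize_seq <- function(x) {
  x <- chartr("u", "U", toupper(as.character(x)))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("non-nucleotide characters in sequence(s): ",
         paste(utils::head(which(bad), 3L), collapse = ", "))
  }
  x
}

#' Reverse complement
#'
#' @param x character vector of DNA strings (U tolerated, normalized first).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  x <- normalize_seq(x)
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Length of the longest common contiguous substring of two strings.
# Classic rolling DP; sequences here are ~20 nt so quadratic cost is nil.
lcs_substring <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  na <- length(av); nb <- length(bv)
  if (na == 0L || nb == 0L) return(0L)
  best <- 0L
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    hit <- av[i] == bv
    cur[hit] <- c(0L, prev)[seq_len(nb)][hit] + 1L
    best <- max(best, cur)
    prev <- cur
  }
  as.integer(best)
}

# interval overlap length for 0-based half-open intervals
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# TSV reader skipping lines that START with '#' (field values may contain '#',
# e.g. novel species named "#40", so read.delim's comment.char is unusable)
read_tsv_hash <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) == 0L) stop("no data rows in '", path, "'")
  utils::read.delim(text = paste(lines, collapse = "\n"), comment.char = "",
                    stringsAsFactors = FALSE)
}
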