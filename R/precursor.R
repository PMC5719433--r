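#' Construct a precursor record
#'
#' A miRNA precursor is the coordinate frame for everything downstream: a
#' stem-loop sequence, an optional dot-bracket secondary structure, and the
#' annotated mature species, exactly one of which is flagged as the major
#' miRNA. Internal coordinates are 0-based half-open.
#'
#' Plant pre-miRNA fold-backs span roughly 50-900 nt; sequences outside
#' [40, 1000] nt are rejected.
#'
#' @param id precursor identifier.
#' @param sequence nucleotide string (U is normalized to T).
#' @param matures data.frame with columns `name`, `start` (0-based,
#'   inclusive), `end` (exclusive), `is_major` (logical); exactly one row
#'   with `is_major = TRUE`.
#' @param structure optional dot-bracket string, same length as `sequence`.
#' @return an object of class `precursor_record`.
#' @examples
#' seq <- paste(rep("ACGT", 30), collapse = "")
#' precursor_record("p1", seq,
#'   data.frame(name = "miR-1", start = 20, end = 41, is_major = TRUE))
#' @export
precursor_record <- function(id, sequence, matures, structure = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- normalize_seq(sequence)
  n <- nchar(sequence)
  if (n < 40L || n > 1000L) {
    stop("precursor '", id, "' length ", n, " outside the accepted 40-1000 nt")
  }
  if (!is.null(structure)) {
    structure <- as.character(structure)
    if (nchar(structure) != n) {
      stop("structure length (", nchar(structure),
           ") differs from sequence length (", n, ") for '", id, "'")
    }
    pairing_map(structure)  # validates balance
  }
  matures <- validate_matures(matures, n, id)
  structure(list(id = id, sequence = sequence, structure = structure,
                 matures = matures),
            class = "precursor_record")
}

validate_matures <- function(matures, precursor_len, id) {
  req <- c("name", "start", "end", "is_major")
  if (!is.data.frame(matures) || !all(req %in% names(matures))) {
    stop("matures must be a data.frame with columns ",
         paste(req, collapse = ", "))
  }
  matures <- matures[req]
  matures$name <- as.character(matures$name)
  matures$start <- as.integer(matures$start)
  matures$end <- as.integer(matures$end)
  matures$is_major <- as.logical(matures$is_major)
  if (nrow(matures) < 1L) stop("precursor '", id, "' has no mature annotation")
  bad <- matures$start < 0L | matures$start >= matures$end |
    matures$end > precursor_len
  if (any(bad)) {
    stop("mature annotation out of bounds on '", id, "': ",
         paste(matures$name[bad], collapse = ", "))
  }
  len <- matures$end - matures$start
  if (any(len < 15L | len > 30L)) {
    stop("mature length outside 15-30 nt on '", id, "'")
  }
  if (sum(matures$is_major) != 1L) {
    stop("precursor '", id, "' must have exactly one major mature annotation (has ",
         sum(matures$is_major), ")")
  }
  rownames(matures) <- NULL
  matures
}

#' @export
print.precursor_record <- function(x, ...) {
  cat(sprintf("<precursor_record> %s (%d nt%s)\n", x$id, nchar(x$sequence),
              if (is.null(x$structure)) "" else ", with structure"))
  maj <- x$matures[x$matures$is_major, , drop = FALSE]
  cat(sprintf("  major: %s [%d, %d)\n", maj$name, maj$start, maj$end))
  if (nrow(x$matures) > 1L) {
    cat("  other matures:", paste(x$matures$name[!x$matures$is_major],
                                  collapse = ", "), "\n")
  }
  invisible(x)
}

#' The major mature annotation of a precursor
#'
#' @param precursor a `precursor_record`.
#' @return one-row data.frame (name, start, end, is_major).
#' @export
major_mature <- function(precursor) {
  stopifnot(inherits(precursor, "precursor_record"))
  precursor$matures[precursor$matures$is_major, , drop = FALSE]
}
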