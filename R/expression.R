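#' Per-library species counts
#'
#' @param library_id library label, e.g. one of the four chilling conditions
#'   `NC` (normal), `CA` (acclimation, 14 C), `CCA` (4 C after acclimation),
#'   `CS` (cold shock 24 C to 4 C).
#' @param counts named integer vector of read counts per species name.
#' @param total_mapped total mapped reads; defaults to `sum(counts)`.
#' @return object of class `library_counts`.
#' @export
library_counts <- function(library_id, counts, total_mapped = sum(counts)) {
  stopifnot(length(library_id) == 1L, !is.null(names(counts)))
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (any(counts < 0L)) stop("counts must be non-negative")
  total_mapped <- as.integer(total_mapped)
  if (total_mapped != sum(counts)) {
    stop("total_mapped must equal the sum of counts")
  }
  structure(list(library_id = as.character(library_id), counts = counts,
                 total_mapped = total_mapped),
            class = "library_counts")
}

#' Reads-per-million normalization
#'
#' @param lib a [library_counts()] object.
#' @return named numeric vector: `count * 1e6 / total_mapped`.
#' @export
rpm_normalize <- function(lib) {
  stopifnot(inherits(lib, "library_counts"))
  if (lib$total_mapped == 0L) stop("total_mapped is zero; cannot normalize")
  lib$counts * 1e6 / lib$total_mapped
}

#' Cross-condition log2 fold changes from sequencing counts
#'
#' RPM values with a pseudocount are compared against the control library:
#' `log2(RPM_treatment + c) - log2(RPM_control + c)`.
#'
#' @param libs list of [library_counts()] objects.
#' @param control_id library id of the control condition (default `"NC"`).
#' @param pseudocount RPM pseudocount `c` guarding zeros (default 1).
#' @return data.frame with `name`, `library`, `log2fc` (treatments only).
#' @export
condition_fold_changes <- function(libs, control_id = "NC", pseudocount = 1) {
  ids <- vapply(libs, function(l) l$library_id, character(1L))
  if (!control_id %in% ids) stop("control library '", control_id, "' missing")
  names(libs) <- ids
  all_names <- unique(unlist(lapply(libs, function(l) names(l$counts))))
  rpm <- vapply(libs, function(l) {
    v <- rpm_normalize(l)
    stats::setNames(ifelse(all_names %in% names(v), v[all_names], 0), all_names)
  }, numeric(length(all_names)))
  ctrl <- rpm[, control_id]
  treatments <- setdiff(ids, control_id)
  out <- do.call(rbind, lapply(treatments, function(id) {
    data.frame(name = all_names, library = id,
               log2fc = log2(rpm[, id] + pseudocount) -
                 log2(ctrl + pseudocount),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' A qRT-PCR CT measurement
#'
#' Technical replicates may be supplied as vectors; they are summarized by
#' their mean before any delta-CT arithmetic. U6 is the customary reference
#' gene for plant miRNA assays.
#'
#' @param sample_id sample label.
#' @param target_ct CT value(s) of the target species.
#' @param reference_ct CT value(s) of the reference gene (U6).
#' @param ntc_ct CT of the no-template control for this primer set, or `NA`.
#' @return object of class `ct_measurement`.
#' @export
ct_measurement <- function(sample_id, target_ct, reference_ct, ntc_ct = NA) {
  chk <- function(x, what, allow_na = FALSE) {
    x <- as.numeric(x)
    if (allow_na && all(is.na(x))) return(NA_real_)
    if (any(is.na(x)) || any(x <= 0 | x > 50)) {
      stop(what, " CT values must lie in (0, 50]")
    }
    mean(x)
  }
  if (missing(reference_ct) || is.null(reference_ct)) {
    stop("a reference (U6) CT is required")
  }
  structure(list(sample_id = as.character(sample_id),
                 target_ct = chk(target_ct, "target"),
                 reference_ct = chk(reference_ct, "reference"),
                 ntc_ct = chk(ntc_ct, "NTC", allow_na = TRUE)),
            class = "ct_measurement")
}

#' Relative expression by the 2^-ddCT method
#'
#' `dCT = CT(target) - CT(reference)` within each sample,
#' `ddCT = dCT(sample) - dCT(control)`, and the relative concentration is
#' `2^-ddCT`. A target CT above the no-template control CT means the species
#' is considered not expressed (`detected = FALSE`), whatever the fold
#' change.
#'
#' @param sample,control [ct_measurement()] objects.
#' @return object of class `relative_expression`: list with `sample_id`,
#'   `delta_ct`, `delta_delta_ct`, `fold_change`, `detected`.
#' @examples
#' s <- ct_measurement("CS", 24, 18)
#' nc <- ct_measurement("NC", 26, 18)
#' ddct(s, nc)$fold_change  # 4
#' @export
ddct <- function(sample, control) {
  stopifnot(inherits(sample, "ct_measurement"),
            inherits(control, "ct_measurement"))
  delta_ct <- sample$target_ct - sample$reference_ct
  delta_delta_ct <- delta_ct - (control$target_ct - control$reference_ct)
  detected <- !(is.finite(sample$ntc_ct) && sample$target_ct > sample$ntc_ct)
  structure(list(sample_id = sample$sample_id, delta_ct = delta_ct,
                 delta_delta_ct = delta_delta_ct,
                 fold_change = 2^(-delta_delta_ct), detected = detected),
            class = "relative_expression")
}

#' @export
print.relative_expression <- function(x, ...) {
  cat(sprintf("<relative_expression> %s: ddCT %.3f, fold %.3g%s\n",
              x$sample_id, x$delta_delta_ct, x$fold_change,
              if (x$detected) "" else " (not detected: CT above NTC)"))
  invisible(x)
}

#' Read a CT table and compute relative expression
#'
#' Input TSV columns: `sample_id`, `target`, `target_ct`, `reference_ct`,
#' `ntc_ct` (may be empty). Replicate rows per (sample, target) are averaged.
#' The control sample's own row yields fold change 1.
#'
#' @param path CT table TSV.
#' @param control_id sample id of the control (default `"NC"`).
#' @return data.frame mirroring the `relative_expression` fields, one row per
#'   (target, sample).
#' @export
ddct_table <- function(path, control_id = "NC") {
  tab <- read_tsv_hash(path)
  req <- c("sample_id", "target", "target_ct", "reference_ct")
  if (!all(req %in% names(tab))) {
    stop("CT table must have columns ", paste(req, collapse = ", "))
  }
  if (!"ntc_ct" %in% names(tab)) tab$ntc_ct <- NA
  out <- list()
  for (target in unique(tab$target)) {
    rows <- tab[tab$target == target, , drop = FALSE]
    if (!control_id %in% rows$sample_id) {
      stop("no control sample '", control_id, "' for target '", target, "'")
    }
    meas <- lapply(split(rows, rows$sample_id), function(r) {
      ct_measurement(r$sample_id[1L], r$target_ct, r$reference_ct,
                     r$ntc_ct[1L])
    })
    for (m in meas) {
      r <- ddct(m, meas[[control_id]])
      out[[length(out) + 1L]] <- data.frame(
        target = target, sample_id = r$sample_id, delta_ct = r$delta_ct,
        delta_delta_ct = r$delta_delta_ct, fold_change = r$fold_change,
        detected = r$detected, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Expected qRT-PCR amplicon length
#'
#' The assay amplicon comprises the miRNA-specific primer region (the mature
#' length, 21-25 nt in practice) plus the fixed adaptor bases, giving the
#' characteristic ~55-nt product for a 25-nt species with 30-nt adaptors.
#'
#' @param mature_len mature miRNA length in nt (15-30).
#' @param adaptor_len total adaptor length in nt (default 30).
#' @return integer amplicon length.
#' @examples
#' amplicon_length(25)  # 55
#' @export
amplicon_length <- function(mature_len, adaptor_len = 30L) {
  mature_len <- as.integer(mature_len)
  if (any(is.na(mature_len)) || any(mature_len < 15L | mature_len > 30L)) {
    stop("mature_len must be within 15-30 nt")
  }
  mature_len + as.integer(adaptor_len)
}
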