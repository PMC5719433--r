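#' Configuration for the hairpin read simulator
#'
#' The simulator emulates the read stacks seen on real miRNA precursors:
#' one dominant mature species on the 5' arm of a hairpin, optional extra
#' species planted in register (phased) or mid-register (half-phased), its
#' miRNA* on the 3' arm with 2-nt 3' overhangs, 1-3-nt isomiR jitter, and
#' low-level positional noise, across several libraries with
#' condition-dependent fold changes.
#'
#' Defaults mirror the discovery setting: 60-nt arms around a 12-nt loop
#' (132-nt precursors), a 21-nt major miRNA with mean 100 reads, odd-numbered
#' precursors carrying one phased species at +21 nt (mean 50), even-numbered
#' ones two half-phased species at +7 and +28 nt (means 30 and 20), a major
#' star species (mean 30), 10% isomiR jitter, 0.02 noise reads per nt, and
#' libraries NC/CA/CCA/CS with fold changes 1, 2, 4 and 0.5.
#'
#' @param n_precursors number of hairpins to simulate.
#' @param arm_len,loop_len,major_len hairpin geometry in nt.
#' @param major_start 0-based start of the major miRNA on the 5' arm.
#' @param major_mean,star_mean mean read counts (at fold change 1) of the
#'   major species and its star.
#' @param planted function(precursor index) returning a data.frame with
#'   `category` (`"phased"`/`"half_phased"`), `offset` (nt from the major 5'
#'   end) and `mean_count`; or such a data.frame applied to every precursor;
#'   or `NULL` for the alternating default described above.
#' @param mismatch_rate per-position probability of breaking a stem pair.
#' @param isomir_jitter_prob per-read probability of a 1-3-nt 5' shift.
#' @param noise_rate expected background reads per precursor position.
#' @param libraries named numeric vector of per-library fold changes applied
#'   to all planted species (control first).
#' @param nb_size negative-binomial dispersion (size) of species counts.
#' @param seed integer seed driving all randomness.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_precursors = 3L, arm_len = 60L, loop_len = 12L,
                       major_len = 21L, major_start = 5L, major_mean = 100,
                       star_mean = 30, planted = NULL, mismatch_rate = 0.05,
                       isomir_jitter_prob = 0.1, noise_rate = 0.02,
                       libraries = c(NC = 1, CA = 2, CCA = 4, CS = 0.5),
                       nb_size = 5, seed = 1L) {
  stopifnot(arm_len >= major_len + 12L, loop_len >= 3L,
            major_len >= 15L, major_len <= 30L,
            isomir_jitter_prob >= 0, isomir_jitter_prob <= 1,
            mismatch_rate >= 0, mismatch_rate <= 1, noise_rate >= 0,
            !is.null(names(libraries)), length(libraries) >= 1L)
  if (is.null(planted)) {
    planted <- function(i) {
      if (i %% 2L == 1L) {
        data.frame(category = "phased", offset = major_len, mean_count = 50)
      } else {
        data.frame(category = c("half_phased", "half_phased"),
                   offset = c(7L, major_len + 7L), mean_count = c(30, 20))
      }
    }
  }
  if (is.data.frame(planted)) {
    planted_df <- planted
    planted <- function(i) planted_df
  }
  structure(list(n_precursors = as.integer(n_precursors),
                 arm_len = as.integer(arm_len), loop_len = as.integer(loop_len),
                 major_len = as.integer(major_len),
                 major_start = as.integer(major_start),
                 major_mean = major_mean, star_mean = star_mean,
                 planted = planted, mismatch_rate = mismatch_rate,
                 isomir_jitter_prob = isomir_jitter_prob,
                 noise_rate = noise_rate, libraries = libraries,
                 nb_size = nb_size, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate one hairpin precursor
#'
#' The sequence is a random 5' arm, a random loop, and the reverse complement
#' of the arm with pairs broken at `mismatch_rate`; the dot-bracket structure
#' is emitted from the known pairing (broken pairs become unpaired on both
#' sides). The major miRNA is annotated on the 5' arm. Uses the current RNG
#' state; [simulate_srna()] seeds it from the config.
#'
#' @param config [sim_config()].
#' @param index precursor number (used for the id and the planted layout).
#' @return a [precursor_record()] with structure.
#' @export
make_hairpin <- function(config, index = 1L) {
  nt <- c("A", "C", "G", "T")
  arm <- sample(nt, config$arm_len, replace = TRUE)
  loop <- sample(nt, config$loop_len, replace = TRUE)
  arm3 <- strsplit(chartr("ACGT", "TGCA", paste(rev(arm), collapse = "")),
                   "", fixed = TRUE)[[1L]]
  broken <- stats::runif(config$arm_len) < config$mismatch_rate
  if (any(broken)) {
    # substitute the 3' side so the pair no longer forms
    for (k in which(broken)) {
      comp <- chartr("ACGT", "TGCA", arm[k])
      arm3[config$arm_len - k + 1L] <- sample(setdiff(nt, comp), 1L)
    }
  }
  n <- 2L * config$arm_len + config$loop_len
  struct <- rep(".", n)
  paired5 <- which(!broken)
  struct[paired5] <- "("
  struct[n - paired5 + 1L] <- ")"
  major <- data.frame(name = sprintf("syn-miR%03d", index),
                      start = config$major_start,
                      end = config$major_start + config$major_len,
                      is_major = TRUE)
  precursor_record(sprintf("syn-pre%03d", index),
                   paste(c(arm, loop, arm3), collapse = ""),
                   matures = major, structure = paste(struct, collapse = ""))
}

# star interval of [s, e) on a synthetic hairpin of length n: pairing
# register is i + partner(i) = n - 1, plus the 2-nt 3' overhangs
synthetic_star_interval <- function(s, e, n, overhang = 2L) {
  list(start = n - e + 1L + overhang, end = n - s + 1L + overhang)
}

#' Simulate reads for one precursor across all libraries
#'
#' For the major species, its star, and each planted species, per-library
#' counts are drawn from a negative binomial with mean
#' `mean_count * fold_change`; each read copy is independently shifted by
#' 1-3 nt with probability `isomir_jitter_prob`; background noise reads of
#' 18-26 nt are placed uniformly at `noise_rate` per position. Reads are
#' exact substrings of the precursor (mismatched reads would not map and are
#' deliberately not simulated).
#'
#' @param precursor a hairpin from [make_hairpin()].
#' @param config [sim_config()].
#' @param index precursor number (selects the planted layout).
#' @return list with `reads` (named list per library of collapsed read
#'   data.frames) and `truth` (data.frame: `precursor_id`, `name`,
#'   `category`, `start`, `end`, `library`, `expected_count`).
#' @export
plant_reads <- function(precursor, config, index = 1L) {
  n <- nchar(precursor$sequence)
  maj <- major_mature(precursor)
  star <- synthetic_star_interval(maj$start, maj$end, n,
                                  overhang = 2L)
  planted <- config$planted(index)
  species <- data.frame(
    name = c(paste0(maj$name, ".1"),
             if (nrow(planted) > 0L) paste0(maj$name, ".", 1L + seq_len(nrow(planted))),
             paste0(maj$name, ".star")),
    category = c("canonical", planted$category,
                 classify_offset(star$start - maj$start, config$major_len)),
    start = as.integer(c(maj$start, maj$start + planted$offset, star$start)),
    mean_count = c(config$major_mean, planted$mean_count, config$star_mean),
    stringsAsFactors = FALSE)
  species$end <- species$start + config$major_len
  if (any(species$start < 0L | species$end > n)) {
    stop("planted species out of precursor bounds")
  }
  reads <- list()
  truth <- list()
  for (lib in names(config$libraries)) {
    fold <- config$libraries[[lib]]
    seqs <- character(0)
    for (si in seq_len(nrow(species))) {
      count <- stats::rnbinom(1L, size = config$nb_size,
                              mu = species$mean_count[si] * fold)
      if (count == 0L) next
      shift <- integer(count)
      jit <- stats::runif(count) < config$isomir_jitter_prob
      shift[jit] <- sample(c(-3:-1, 1:3), sum(jit), replace = TRUE)
      s <- pmin(pmax(species$start[si] + shift, 0L), n - config$major_len)
      seqs <- c(seqs, substring(precursor$sequence, s + 1L,
                                s + config$major_len))
    }
    n_noise <- stats::rpois(1L, config$noise_rate * n)
    if (n_noise > 0L) {
      len <- sample(18:26, n_noise, replace = TRUE)
      s <- vapply(len, function(l) sample.int(n - l + 1L, 1L) - 1L, integer(1L))
      seqs <- c(seqs, substring(precursor$sequence, s + 1L, s + len))
    }
    tab <- table(seqs)
    reads[[lib]] <- if (length(tab) == 0L) empty_reads() else
      small_reads(paste0(precursor$id, "_", lib, "_r", seq_along(tab)),
                  names(tab), as.integer(tab))
    truth[[lib]] <- data.frame(
      precursor_id = precursor$id, name = species$name,
      category = species$category, start = species$start, end = species$end,
      library = lib, expected_count = species$mean_count * fold,
      stringsAsFactors = FALSE)
  }
  list(reads = reads, truth = do.call(rbind, truth))
}

#' Run the full simulation
#'
#' @param config [sim_config()].
#' @return object of class `sim_bundle`: list with `precursors` (named list
#'   of [precursor_record()]), `reads` (named list per library of collapsed
#'   read data.frames, pooled over precursors), `truth` (data.frame) and the
#'   `config`.
#' @export
simulate_srna <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  precursors <- list()
  reads <- stats::setNames(vector("list", length(config$libraries)),
                           names(config$libraries))
  truth <- list()
  for (i in seq_len(config$n_precursors)) {
    pre <- make_hairpin(config, i)
    precursors[[pre$id]] <- pre
    planted <- plant_reads(pre, config, i)
    for (lib in names(config$libraries)) {
      reads[[lib]] <- rbind(reads[[lib]], planted$reads[[lib]])
    }
    truth[[i]] <- planted$truth
  }
  reads <- lapply(reads, function(r) {
    if (is.null(r) || nrow(r) == 0L) empty_reads() else
      small_reads(r$id, r$seq, r$count)
  })
  structure(list(precursors = precursors, reads = reads,
                 truth = do.call(rbind, truth), config = config),
            class = "sim_bundle")
}

#' Pool collapsed reads over libraries
#'
#' @param bundle a `sim_bundle` from [simulate_srna()], or a named list of
#'   read data.frames.
#' @return one collapsed read data.frame with summed counts.
#' @export
pool_reads <- function(bundle) {
  reads <- if (inherits(bundle, "sim_bundle")) bundle$reads else bundle
  all <- do.call(rbind, reads)
  if (is.null(all) || nrow(all) == 0L) return(empty_reads())
  small_reads(all$id, all$seq, all$count)
}

#' Write the simulation truth table
#'
#' @param truth truth data.frame from [simulate_srna()].
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a truth table written by [write_truth()]
#'
#' @param path truth TSV.
#' @return data.frame.
#' @export
read_truth <- function(path) {
  read_tsv_hash(path)
}

#' Write a complete simulated bundle to a directory
#'
#' Emits one collapsed FASTA per library plus precursor FASTA, annotation
#' TSV, structure file and truth TSV.
#'
#' @param bundle a `sim_bundle`.
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_sim_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    precursors = file.path(dir, "precursors.fa"),
    annotations = file.path(dir, "annotations.tsv"),
    structures = file.path(dir, "structures.db"),
    truth = file.path(dir, "truth.tsv"))
  write_precursor_fasta(bundle$precursors, paths$precursors)
  write_annotations(bundle$precursors, paths$annotations)
  write_structures(bundle$precursors, paths$structures)
  write_truth(bundle$truth, paths$truth)
  for (lib in names(bundle$reads)) {
    p <- file.path(dir, paste0("reads_", lib, ".fa"))
    write_collapsed_fasta(bundle$reads[[lib]], p)
    paths[[paste0("reads_", lib)]] <- p
  }
  invisible(paths)
}

#' Compare phasing calls with the simulation truth
#'
#' A call matches a truth record when precursor ids agree, 5' starts differ
#' by at most `isomir_max_shift`, and categories agree. Precision and recall
#' are computed over species calls (categories canonical/phased/half-phased;
#' isomiR and unphased calls count against precision only via their absence
#' from truth), and `category_accuracy` over position-matched pairs.
#'
#' @param calls phasing-call data.frame (see [call_precursor()] /
#'   [mirlike_detect()]).
#' @param truth truth data.frame from [simulate_srna()].
#' @param params [pipeline_params()].
#' @return list with `precision`, `recall`, `category_accuracy`, `n_truth`,
#'   `n_calls`. `recall` is `NA` when the truth is empty.
#' @export
evaluate_recovery <- function(calls, truth, params = pipeline_params()) {
  truth <- unique(truth[c("precursor_id", "name", "category", "start", "end")])
  species_cats <- c("canonical", "phased", "half_phased")
  calls <- calls[calls$category %in% species_cats, , drop = FALSE]
  n_truth <- nrow(truth)
  n_calls <- nrow(calls)
  pos_match <- function(t, c) {
    t$precursor_id == c$precursor_id &
      abs(t$start - c$start) <= params$isomir_max_shift
  }
  matched_truth <- logical(n_truth)
  matched_call <- logical(n_calls)
  cat_ok <- logical(0)
  for (i in seq_len(n_truth)) {
    for (j in seq_len(n_calls)) {
      if (truth$precursor_id[i] == calls$precursor_id[j] &&
          abs(truth$start[i] - calls$start[j]) <= params$isomir_max_shift) {
        cat_ok <- c(cat_ok, truth$category[i] == calls$category[j])
        if (truth$category[i] == calls$category[j] && !matched_call[j]) {
          matched_truth[i] <- TRUE
          matched_call[j] <- TRUE
        }
      }
    }
  }
  list(precision = if (n_calls == 0L) NA_real_ else
         sum(matched_call) / n_calls,
       recall = if (n_truth == 0L) NA_real_ else sum(matched_truth) / n_truth,
       category_accuracy = if (length(cat_ok) == 0L) NA_real_ else
         mean(cat_ok),
       n_truth = n_truth, n_calls = n_calls)
}
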