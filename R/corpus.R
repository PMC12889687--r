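# Training-window construction: fixed-length case-preserving windows with
# chromosome-based splits, repeat-run annotation and stochastic augmentation.
#
# A corpus is a tibble with one row per window: chrom, start, end (0-based
# half-open), seq, split, and repeat_runs (list column of integer matrices
# with columns start, end, offsets within seq).

#' Chromosome-based split specification
#'
#' Published splits hold out chromosomes 6 and 21 for validation and 5, 10,
#' 14, 18, 20, and 22 for testing; every other chromosome is training.
#' Matching ignores an optional `chr` prefix.
#'
#' @param val_chroms,test_chroms Character vectors of chromosome names; the
#'   two sets must be disjoint.
#' @return A `split_spec` list.
#' @export
split_spec <- function(val_chroms = c("chr6", "chr21"),
                       test_chroms = c("chr5", "chr10", "chr14", "chr18", "chr20", "chr22")) {
  v <- norm_chrom(val_chroms)
  t <- norm_chrom(test_chroms)
  if (length(intersect(v, t)) > 0) {
    rlang::abort(sprintf(
      "chromosome(s) %s appear in both validation and test sets",
      paste(intersect(v, t), collapse = ", ")
    ))
  }
  structure(list(val_chroms = v, test_chroms = t), class = "split_spec")
}

norm_chrom <- function(x) sub("^chr", "", x)

#' Assign a chromosome to a split
#'
#' @param chrom Character vector of chromosome names.
#' @param spec A [split_spec()].
#' @return Character vector over `train`, `val`, `test`.
#' @examples
#' assign_split(c("chr6", "chr5", "chr1"), split_spec())
#' @export
assign_split <- function(chrom, spec = split_spec()) {
  if (any(!nzchar(chrom))) rlang::abort("empty chromosome name")
  nc <- norm_chrom(chrom)
  dplyr::case_when(
    nc %in% spec$val_chroms ~ "val",
    nc %in% spec$test_chroms ~ "test",
    .default = "train"
  )
}

#' Annotate soft-masked repeat runs
#'
#' Maximal runs of lowercase characters of length at least `min_run`, as
#' 0-based half-open offsets within the sequence. Runs shorter than
#' `min_run` are not reported.
#'
#' @param seq DNA string over `ACGTNacgtn`.
#' @param min_run Minimum run length (default 30, the loss-exclusion
#'   threshold for contiguous repeat stretches).
#' @return Integer matrix with columns `start`, `end`; zero rows if none.
#' @examples
#' annotate_repeat_runs(paste0("ACGT", strrep("acgt", 10), "ACGT"), min_run = 30)
#' @export
annotate_repeat_runs <- function(seq, min_run = 30L) {
  validate_dna(seq)
  lower <- grepl("[acgtn]", seq_chars(seq))
  r <- rle(lower)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_run
  m <- cbind(start = starts[keep], end = ends[keep])
  storage.mode(m) <- "integer"
  m
}

# Center an interval [start, end) into a window of fixed length; the extra
# base goes 3' when the deficit/overhang is odd. Works for expansion and
# center-cropping alike.
center_window <- function(start, end, window) {
  new_start <- floor((start + end - window + 1) / 2)
  c(new_start, new_start + window)
}

#' Load fixed-length training windows from BED intervals
#'
#' Intervals shorter than `window` are expanded symmetrically about their
#' midpoint (extra base 3'); longer intervals are center-cropped. Windows
#' that would cross a chromosome edge are slid back inside the bounds when
#' the chromosome is long enough, otherwise skipped; both cases emit a
#' warning.
#'
#' @param bed BED path or tibble from [read_bed()].
#' @param genome A [genome_source()].
#' @param window Window length in bp (default 350).
#' @param spec A [split_spec()] used to label each window.
#' @param min_run Repeat-run annotation threshold.
#' @return Corpus tibble: `chrom`, `start`, `end`, `seq`, `split`,
#'   `repeat_runs` (list column).
#' @export
load_windows <- function(bed, genome, window = 350L, spec = split_spec(),
                         min_run = 30L) {
  stopifnot(window > 0)
  if (is.character(bed)) bed <- read_bed(bed)
  n_skip <- 0L
  n_clamp <- 0L
  rows <- vector("list", nrow(bed))
  for (i in seq_len(nrow(bed))) {
    chrom <- bed$chrom[i]
    if (!chrom %in% names(genome$seqs)) {
      rlang::abort(sprintf("BED interval %d references unknown chromosome '%s'", i, chrom))
    }
    clen <- genome$lengths[[chrom]]
    if (clen < window) {
      n_skip <- n_skip + 1L
      next
    }
    w <- center_window(bed$start[i], bed$end[i], window)
    if (w[1] < 0 || w[2] > clen) {
      w <- pmin(pmax(w[1], 0L), clen - window)
      w <- c(w, w + window)
      n_clamp <- n_clamp + 1L
    }
    seq <- get_sequence(genome, chrom, w[1], w[2])
    rows[[i]] <- tibble(
      chrom = chrom, start = as.integer(w[1]), end = as.integer(w[2]), seq = seq
    )
  }
  if (n_skip > 0) {
    rlang::warn(sprintf("%d interval(s) skipped: chromosome shorter than the window", n_skip))
  }
  if (n_clamp > 0) {
    rlang::warn(sprintf("%d window(s) clamped at a chromosome edge", n_clamp))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(), seq = character(),
      split = character(), repeat_runs = list()
    ))
  }
  out$split <- assign_split(out$chrom, spec)
  out$repeat_runs <- lapply(out$seq, annotate_repeat_runs, min_run = min_run)
  out
}

#' Augmentation policy
#'
#' Reverse-complement with probability `rc_prob` and an integer shift drawn
#' uniformly from `shift_range` (closed). Defaults follow the published
#' training scheme: rc probability 0.5, shifts between -50 and +50 bp.
#'
#' @param rc_prob Probability of reverse complement.
#' @param shift_range Length-2 integer vector `c(-S, S)`.
#' @return An `augmentation_policy` list.
#' @export
augmentation_policy <- function(rc_prob = 0.5, shift_range = c(-50L, 50L)) {
  stopifnot(rc_prob >= 0, rc_prob <= 1, length(shift_range) == 2,
            shift_range[1] <= shift_range[2])
  structure(list(rc_prob = rc_prob, shift_range = as.integer(shift_range)),
            class = "augmentation_policy")
}

# Reverse-complement a corpus row, remapping repeat-run offsets.
rc_record <- function(seq, runs) {
  L <- nchar(seq)
  new_runs <- runs
  if (nrow(runs) > 0) {
    new_runs <- cbind(start = L - runs[, "end"], end = L - runs[, "start"])
    new_runs <- new_runs[order(new_runs[, "start"]), , drop = FALSE]
    storage.mode(new_runs) <- "integer"
  }
  list(seq = reverse_complement(seq), runs = new_runs)
}

#' Augment a corpus of windows
#'
#' Shift is applied first (re-extracting the displaced window from the
#' genome; offsets that would cross a chromosome edge are clamped to the
#' largest legal displacement), then reverse complement with probability
#' `rc_prob`. Without a genome (e.g. standalone synthetic sequences) shifts
#' are clamped to zero and only reverse complement applies. Draws come from
#' R's RNG; seed upstream for reproducibility.
#'
#' @param corpus Corpus tibble.
#' @param policy An [augmentation_policy()].
#' @param genome Optional [genome_source()] backing the windows.
#' @param min_run Repeat-run threshold used when re-annotating shifted windows.
#' @return Corpus tibble of the same shape.
#' @export
augment_corpus <- function(corpus, policy = augmentation_policy(),
                           genome = NULL, min_run = 30L) {
  n <- nrow(corpus)
  if (n == 0) return(corpus)
  shifts <- policy$shift_range[1] +
    sample.int(policy$shift_range[2] - policy$shift_range[1] + 1L, n, replace = TRUE) - 1L
  rc <- runif(n) < policy$rc_prob
  for (i in seq_len(n)) {
    if (shifts[i] != 0 && !is.null(genome)) {
      clen <- genome$lengths[[corpus$chrom[i]]]
      window <- corpus$end[i] - corpus$start[i]
      s <- corpus$start[i] + shifts[i]
      s <- min(max(s, 0L), clen - window) # clamp at chromosome edges
      corpus$start[i] <- as.integer(s)
      corpus$end[i] <- as.integer(s + window)
      corpus$seq[i] <- get_sequence(genome, corpus$chrom[i], s, s + window)
      corpus$repeat_runs[[i]] <- annotate_repeat_runs(corpus$seq[i], min_run)
    }
    if (rc[i]) {
      r <- rc_record(corpus$seq[i], corpus$repeat_runs[[i]])
      corpus$seq[i] <- r$seq
      corpus$repeat_runs[[i]] <- r$runs
    }
  }
  corpus
}

#' Write / read a corpus
#'
#' Sequences go to case-preserving FASTA (record ids `chrom:start-end`), the
#' window manifest to TSV (`chrom`, `start`, `end`, `split`).
#'
#' @param corpus Corpus tibble.
#' @param fasta,manifest Output paths.
#' @export
write_corpus <- function(corpus, fasta, manifest) {
  ids <- sprintf("%s:%d-%d", corpus$chrom, corpus$start, corpus$end)
  write_fasta(setNames(corpus$seq, ids), fasta)
  readr::write_tsv(
    dplyr::select(corpus, "chrom", "start", "end", "split"), manifest
  )
  invisible(corpus)
}

#' @rdname write_corpus
#' @param min_run Repeat-run threshold used on re-read.
#' @export
read_corpus <- function(fasta, manifest, min_run = 30L) {
  seqs <- Biostrings::readBStringSet(fasta)
  man <- readr::read_tsv(manifest, show_col_types = FALSE)
  out <- tibble(
    chrom = man$chrom, start = as.integer(man$start), end = as.integer(man$end),
    seq = unname(as.character(seqs)), split = man$split
  )
  out$repeat_runs <- lapply(out$seq, annotate_repeat_runs, min_run = min_run)
  out
}
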