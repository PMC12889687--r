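# Case-preserving genome access and plain-format IO.
#
# Soft-masked genomes mark repeats as lowercase; tokenization folds case, but
# repeat annotation depends on it, so sequences are held as raw character
# strings (Biostrings BString on disk IO) and case is never folded on read.

#' Create a genome source
#'
#' A case-preserving, bounds-checked accessor over per-chromosome sequences.
#' Accepts a FASTA path (read via `Biostrings::readBStringSet`, which keeps
#' soft-masking case) or a named character vector of sequences.
#'
#' @param x FASTA file path or named character vector.
#' @return A `genome_source` object.
#' @examples
#' g <- genome_source(c(chr1 = "ACGTacgtNNN"))
#' get_sequence(g, "chr1", 0, 4)
#' @export
genome_source <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    ss <- Biostrings::readBStringSet(x)
    seqs <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else if (is.character(x) && !is.null(names(x))) {
    seqs <- x
  } else {
    rlang::abort("genome_source() expects a FASTA path or a named character vector")
  }
  for (nm in names(seqs)) validate_dna(seqs[[nm]], sprintf("sequence '%s'", nm))
  structure(
    list(seqs = seqs, lengths = setNames(nchar(seqs), names(seqs))),
    class = "genome_source"
  )
}

#' @export
print.genome_source <- function(x, ...) {
  cat(sprintf(
    "<genome_source> %d sequences, %s bp total\n",
    length(x$seqs), format(sum(x$lengths), big.mark = ",")
  ))
  invisible(x)
}

#' @rdname genome_source
#' @param genome A `genome_source`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open coordinates.
#' @export
get_sequence <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome$seqs)) {
    rlang::abort(sprintf("unknown chromosome '%s'", chrom))
  }
  len <- genome$lengths[[chrom]]
  if (start < 0 || end > len || start >= end) {
    rlang::abort(sprintf(
      "coordinates [%d, %d) outside bounds of %s (length %d)",
      start, end, chrom, len
    ))
  }
  substr(genome$seqs[[chrom]], start + 1L, end)
}

#' Read a BED3+ file
#'
#' BED is 0-based half-open; those coordinates are kept internally. Malformed
#' lines raise a parse error naming the line number. `track`/`browser` lines
#' and `#` comments are skipped.
#'
#' @param path BED file path.
#' @return Tibble with `chrom`, `start`, `end` (and `name` when present).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) return(tibble(chrom = character(), start = integer(), end = integer()))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  out <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    f <- fields[[i]]
    if (length(f) < 3) {
      rlang::abort(sprintf("BED parse error at line %d: fewer than 3 fields", idx[i]))
    }
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e) || s < 0 || e <= s) {
      rlang::abort(sprintf(
        "BED parse error at line %d: invalid interval [%s, %s)", idx[i], f[2], f[3]
      ))
    }
    out[[i]] <- list(chrom = f[1], start = s, end = e,
                     name = if (length(f) >= 4) f[4] else NA_character_)
  }
  dplyr::bind_rows(out)
}

#' Write sequences to FASTA, preserving case
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
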