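# Single-nucleotide token alphabet shared by every model surface.
# Integer ids are fixed so that the first four match the probability
# matrix column order (A, C, G, T); N and MASK never appear in output.

TOKENS <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L, MASK = 6L)
BASES <- c("A", "C", "G", "T")
MASK_ID <- 6L
N_ID <- 5L

#' Encode a DNA sequence into token ids
#'
#' Case is folded to uppercase at tokenization; soft-masking case lives only
#' in sequence records, never in the model input. Valid input characters are
#' `ACGTNacgtn`.
#'
#' @param seq A single character string over `ACGTNacgtn`.
#' @return Integer vector of token ids (A=1, C=2, G=3, T=4, N=5).
#' @examples
#' encode_tokens("ACGTn")
#' @export
encode_tokens <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  ids <- TOKENS[chars]
  if (anyNA(ids)) {
    bad <- which(is.na(ids))[1]
    rlang::abort(sprintf(
      "invalid character '%s' at position %d; expected one of ACGTNacgtn",
      chars[bad], bad
    ))
  }
  unname(ids)
}

#' Decode token ids into a DNA sequence
#'
#' The MASK token is an input-side symbol only and never decodes into
#' sequence output.
#'
#' @param ids Integer vector of token ids in 1..5.
#' @return Uppercase character string.
#' @export
decode_tokens <- function(ids) {
  ids <- as.integer(ids)
  if (any(ids == MASK_ID)) {
    rlang::abort("MASK tokens cannot be decoded into sequence output")
  }
  if (any(ids < 1L | ids > 5L)) {
    rlang::abort("token ids must lie in 1..5")
  }
  paste(names(TOKENS)[ids], collapse = "")
}

#' Reverse complement preserving case
#'
#' Maps A<->T and C<->G on both cases, keeps N/n, and reverses the sequence.
#'
#' @param seq Character string over `ACGTNacgtn`.
#' @return The reverse complement, case preserved.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  flipped <- chartr("ACGTacgtNn", "TGCAtgcaNn", seq)
  paste(rev(strsplit(flipped, "", fixed = TRUE)[[1]]), collapse = "")
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

validate_dna <- function(seq, what = "sequence") {
  if (grepl("[^ACGTNacgtn]", seq)) {
    bad <- regmatches(seq, regexpr("[^ACGTNacgtn]", seq))
    rlang::abort(sprintf("%s contains invalid character '%s'", what, bad))
  }
  invisible(seq)
}
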