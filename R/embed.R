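# Per-base embeddings: averaged late-layer hidden states, and the chunked
# tiling scheme for sequences longer than the model context.

#' Extract per-base embeddings for a short sequence
#'
#' Element-wise mean of the last `min(6, n_blocks)` transformer block
#' outputs (no masking applied). For the 8-block configuration this averages
#' blocks 3..8; the tiny 2-block preset averages both.
#'
#' @param model A `dna_lm`.
#' @param seq DNA string with `1 <= nchar(seq) <= context_length`.
#' @return length x embed_dim numeric matrix.
#' @export
extract_embeddings <- function(model, seq) {
  if (!nzchar(seq)) rlang::abort("empty sequence")
  ids <- encode_tokens(seq)
  out <- model_forward(model, matrix(ids, nrow = 1), return_hidden = TRUE)
  nb <- model$config$n_blocks
  n_avg <- min(6L, nb)
  layers <- (nb - n_avg + 1L):nb
  h <- out$hidden[1, , , , drop = FALSE] # 1 x nb x L x d
  emb <- matrix(0, length(ids), model$config$embed_dim)
  for (b in layers) emb <- emb + matrix(h[1, b, , ], nrow = length(ids))
  emb / n_avg
}

#' Source-window map for chunked embedding of a long sequence
#'
#' For a length-M input (`M >= context`): when M is an exact multiple of the
#' context the chunks tile `[0, M)` directly. Otherwise a central chunk is
#' placed symmetrically about the sequence midpoint (`[floor(M/2) -
#' context/2, ...)`, deficit ties resolved 5'), full chunks tile outward
#' from it, and the uncovered ends take their rows from embeddings of the
#' first/last `context` bases. Every output position is covered exactly
#' once.
#'
#' @param M Total sequence length.
#' @param context Model context length.
#' @return Tibble with one row per emitted window: `window_start`,
#'   `window_end` (the subsequence run through the model), `use_start`,
#'   `use_end` (rows of that window's embedding that are kept, 0-based
#'   within the window), `out_start`, `out_end` (destination rows), and
#'   `role` (`"chunk"` or `"edge"`).
#' @examples
#' chunk_map(2114, 350)
#' @export
chunk_map <- function(M, context = 350L) {
  M <- as.integer(M)
  context <- as.integer(context)
  if (M < context) rlang::abort("M < context: use extract_embeddings() directly")
  if (M == context) {
    return(tibble(window_start = 0L, window_end = context,
                  use_start = 0L, use_end = context,
                  out_start = 0L, out_end = context, role = "chunk"))
  }
  # (coordinates below are built from integer arithmetic on M and context)
  if (M %% context == 0) {
    starts <- seq(0L, M - context, by = context)
    return(tibble(
      window_start = starts, window_end = starts + context,
      use_start = 0L, use_end = context,
      out_start = starts, out_end = starts + context, role = "chunk"
    ))
  }
  center_start <- floor(M / 2) - context %/% 2L
  k_left <- center_start %/% context
  k_right <- (M - (center_start + context)) %/% context
  starts <- center_start + context * seq(-k_left, k_right)
  chunks <- tibble(
    window_start = as.integer(starts), window_end = as.integer(starts + context),
    use_start = 0L, use_end = as.integer(context),
    out_start = as.integer(starts), out_end = as.integer(starts + context),
    role = "chunk"
  )
  lo <- min(starts)
  hi <- max(starts) + context
  edges <- list()
  if (lo > 0) {
    edges$left <- tibble(window_start = 0L, window_end = as.integer(context),
                         use_start = 0L, use_end = as.integer(lo),
                         out_start = 0L, out_end = as.integer(lo), role = "edge")
  }
  if (hi < M) {
    ws <- M - context
    edges$right <- tibble(window_start = as.integer(ws), window_end = as.integer(M),
                          use_start = as.integer(hi - ws), use_end = as.integer(context),
                          out_start = as.integer(hi), out_end = as.integer(M),
                          role = "edge")
  }
  dplyr::bind_rows(c(list(chunks), edges))
}

#' Embed a sequence longer than the model context
#'
#' Runs each window from [chunk_map()] through the model and assembles a
#' full-length embedding matrix; every position's row comes from exactly one
#' window.
#'
#' @param model A `dna_lm`.
#' @param seq DNA string with `nchar(seq) >= context_length`.
#' @return M x embed_dim numeric matrix.
#' @export
embed_long_sequence <- function(model, seq) {
  M <- nchar(seq)
  context <- model$config$context_length
  map <- chunk_map(M, context)
  emb <- matrix(NA_real_, M, model$config$embed_dim)
  for (i in seq_len(nrow(map))) {
    sub <- substr(seq, map$window_start[i] + 1L, map$window_end[i])
    e <- extract_embeddings(model, sub)
    rows <- (map$use_start[i] + 1L):map$use_end[i]
    emb[(map$out_start[i] + 1L):map$out_end[i], ] <- e[rows, , drop = FALSE]
  }
  emb
}

#' Write embeddings as TSV
#'
#' One row per position, one column per embedding dimension, with a leading
#' `position` column (0-based). Float32-precision values.
#'
#' @param emb Embedding matrix.
#' @param path Output path.
#' @export
write_embeddings_tsv <- function(emb, path) {
  df <- as.data.frame(signif(emb, 8))
  names(df) <- sprintf("e%03d", seq_len(ncol(emb)) - 1L)
  df <- cbind(position = seq_len(nrow(emb)) - 1L, df)
  readr::write_tsv(tibble::as_tibble(df), path)
  invisible(path)
}
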