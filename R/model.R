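# Model configuration, parameter initialization, and the forward surface.

#' Transformer encoder configuration
#'
#' The full-scale preset matches the published architecture: 8 pre-LayerNorm
#' transformer blocks with embedding size 768, 8 heads, feed-forward dimension
#' 3072, rotary positions in every attention layer, and a 350 bp context. The
#' `tiny` preset (2 blocks, embedding 64, 4 heads, feed-forward 128) is a
#' desk-scale configuration used throughout the tests and examples.
#'
#' @param preset `"full"` or `"tiny"`, or `NULL` to specify fields directly.
#' @param embed_dim,n_blocks,n_heads,ff_dim Architecture dimensions.
#' @param context_length Maximum input length in bp (default 350).
#' @param rope_base Rotary embedding base (default 10000).
#' @return A `model_config` list.
#' @examples
#' model_config("tiny")
#' @export
model_config <- function(preset = c("tiny", "full"), embed_dim = NULL,
                         n_blocks = NULL, n_heads = NULL, ff_dim = NULL,
                         context_length = 350L, rope_base = 10000) {
  defaults <- switch(match.arg(preset),
    full = list(embed_dim = 768L, n_blocks = 8L, n_heads = 8L, ff_dim = 3072L),
    tiny = list(embed_dim = 64L, n_blocks = 2L, n_heads = 4L, ff_dim = 128L)
  )
  cfg <- list(
    embed_dim = as.integer(embed_dim %||% defaults$embed_dim),
    n_blocks = as.integer(n_blocks %||% defaults$n_blocks),
    n_heads = as.integer(n_heads %||% defaults$n_heads),
    ff_dim = as.integer(ff_dim %||% defaults$ff_dim),
    context_length = as.integer(context_length),
    rope_base = rope_base
  )
  if (cfg$embed_dim %% cfg$n_heads != 0) {
    rlang::abort("embed_dim must be divisible by n_heads")
  }
  if ((cfg$embed_dim / cfg$n_heads) %% 2 != 0) {
    rlang::abort("head dimension must be even for rotary positions")
  }
  if (cfg$context_length < 1) rlang::abort("context_length must be >= 1")
  structure(cfg, class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(
    "model_config: %d blocks, d=%d, %d heads, ff=%d, context=%d\n",
    x$n_blocks, x$embed_dim, x$n_heads, x$ff_dim, x$context_length
  ))
  invisible(x)
}

# Fresh parameter list. Linear weights ~ N(0, 1/embed_dim) (the 1/sqrt(d)
# scaling keeps attention logits and residual updates O(1) across model
# sizes); LayerNorm gains 1, shifts 0; the N-token embedding row is zero and
# never updated.
init_params <- function(config, seed = 1L) {
  set.seed(seed)
  d <- config$embed_dim
  ff <- config$ff_dim
  sd0 <- 1 / sqrt(d)
  rmat <- function(nr, nc) matrix(rnorm(nr * nc, sd = sd0), nr, nc)
  p <- list(embed = rmat(6, d))
  p$embed[N_ID, ] <- 0
  for (b in seq_len(config$n_blocks) - 1L) {
    pre <- sprintf("b%d_", b)
    p[[paste0(pre, "ln1_g")]] <- rep(1, d)
    p[[paste0(pre, "ln1_b")]] <- rep(0, d)
    p[[paste0(pre, "w_qkv")]] <- rmat(d, 3 * d)
    p[[paste0(pre, "b_qkv")]] <- rep(0, 3 * d)
    p[[paste0(pre, "w_o")]] <- rmat(d, d)
    p[[paste0(pre, "b_o")]] <- rep(0, d)
    p[[paste0(pre, "ln2_g")]] <- rep(1, d)
    p[[paste0(pre, "ln2_b")]] <- rep(0, d)
    p[[paste0(pre, "w_ff1")]] <- rmat(d, ff)
    p[[paste0(pre, "b_ff1")]] <- rep(0, ff)
    p[[paste0(pre, "w_ff2")]] <- rmat(ff, d)
    p[[paste0(pre, "b_ff2")]] <- rep(0, d)
  }
  p$lnf_g <- rep(1, d)
  p$lnf_b <- rep(0, d)
  p$head_w1 <- rmat(d, d)
  p$head_b1 <- rep(0, d)
  p$head_ln_g <- rep(1, d)
  p$head_ln_b <- rep(0, d)
  p$head_w2 <- rmat(d, 4)
  p$head_b2 <- rep(0, 4)
  p
}

#' Construct a DNA language model object
#'
#' Usually produced by [train_model()]; `dna_lm()` wraps a parameter list and
#' a configuration (e.g. a fresh, untrained model for smoke testing).
#'
#' @param config A [model_config()].
#' @param params Optional parameter list; fresh random parameters when `NULL`.
#' @param seed Seed used for fresh initialization.
#' @return A `dna_lm` object.
#' @export
dna_lm <- function(config = model_config("tiny"), params = NULL, seed = 1L) {
  structure(
    list(
      config = config,
      params = params %||% init_params(config, seed),
      log = NULL,
      prior_config = NULL,
      training_config = NULL,
      seed = seed
    ),
    class = "dna_lm"
  )
}

#' @export
print.dna_lm <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<dna_lm> %d blocks, d=%d, %d heads, context=%d, %s parameters%s\n",
    x$config$n_blocks, x$config$embed_dim, x$config$n_heads,
    x$config$context_length, format(np, big.mark = ","),
    if (is.null(x$log)) " (untrained)" else sprintf(", %d epochs trained", max(x$log$epoch))
  ))
  invisible(x)
}

#' Number of parameters of a model
#'
#' @param model A `dna_lm`.
#' @return Integer parameter count (the pinned N-embedding row included).
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Model forward pass
#'
#' Generic over model implementations so that analysis code (likelihood
#' reconstruction, dependency maps, variant scoring, generation) can run
#' against trained models and hand-built test doubles alike. Implementations
#' take a batch of token id rows and return per-position distributions over
#' A, C, G, T.
#'
#' @param model A model object.
#' @param tokens Integer matrix, batch x length, of token ids (1..6).
#' @param return_hidden Also return the per-block hidden states.
#' @param return_logits Also return pre-softmax logits.
#' @param ... Passed to methods.
#' @return List with `probs` (batch x length x 4 array; rows sum to 1) and
#'   optionally `logits` and `hidden` (batch x n_blocks x length x embed_dim).
#' @export
model_forward <- function(model, tokens, return_hidden = FALSE,
                          return_logits = FALSE, ...) {
  UseMethod("model_forward")
}

#' @export
model_forward.dna_lm <- function(model, tokens, return_hidden = FALSE,
                                 return_logits = FALSE, ...) {
  if (is.vector(tokens)) tokens <- matrix(as.integer(tokens), nrow = 1)
  storage.mode(tokens) <- "integer"
  if (ncol(tokens) > model$config$context_length) {
    rlang::abort(sprintf(
      "input length %d exceeds context_length %d (chunking is the caller's job)",
      ncol(tokens), model$config$context_length
    ))
  }
  if (ncol(tokens) < 1) rlang::abort("empty sequence")
  cpp_forward(model$params, model$config, tokens, return_hidden, return_logits)
}

context_length <- function(model) UseMethod("context_length")

#' @export
context_length.dna_lm <- function(model) model$config$context_length

#' @export
context_length.default <- function(model) {
  attr(model, "context_length") %||% 350L
}

#' Predict per-position base probabilities for a sequence
#'
#' Convenience wrapper around [model_forward()] for a single sequence.
#'
#' @param model A model object.
#' @param seq DNA string (length <= context).
#' @return length x 4 probability matrix (columns A, C, G, T).
#' @export
predict_probs <- function(model, seq) {
  ids <- if (is.character(seq)) encode_tokens(seq) else as.integer(seq)
  out <- model_forward(model, matrix(ids, nrow = 1))
  pm <- matrix(out$probs[1, , ], ncol = 4)
  colnames(pm) <- BASES
  pm
}

#' Save or load a model checkpoint
#'
#' A checkpoint is a directory holding the serialized weight list
#' (`weights.rds`) and a JSON sidecar (`config.json`) recording the
#' architecture, token alphabet order, training seed, and a hash of the
#' configuration; loading verifies the hash.
#'
#' @param model A `dna_lm`.
#' @param path Checkpoint directory.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns the restored `dna_lm`.
#' @export
save_checkpoint <- function(model, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(model$config)
  sidecar <- list(
    alphabet = names(TOKENS),
    config = cfg,
    seed = model$seed,
    config_hash = rlang::hash(cfg),
    package_version = as.character(utils::packageVersion("motiflm"))
  )
  jsonlite::write_json(sidecar, file.path(path, "config.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  saveRDS(model[c("params", "log", "prior_config", "training_config")],
    file.path(path, "weights.rds")
  )
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  sidecar <- jsonlite::read_json(file.path(path, "config.json"),
    simplifyVector = TRUE
  )
  cfg <- sidecar$config
  cfg$rope_base <- as.numeric(cfg$rope_base)
  for (f in c("embed_dim", "n_blocks", "n_heads", "ff_dim", "context_length")) {
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  if (rlang::hash(cfg) != sidecar$config_hash) {
    rlang::abort("checkpoint config hash mismatch; file corrupted or edited")
  }
  blob <- readRDS(file.path(path, "weights.rds"))
  m <- dna_lm(structure(cfg, class = "model_config"),
    params = blob$params,
    seed = as.integer(sidecar$seed)
  )
  m$log <- blob$log
  m$prior_config <- blob$prior_config
  m$training_config <- blob$training_config
  m
}
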