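# Hand-built model doubles implementing the model_forward() contract, used to
# test analysis code against known conditional structure.

# A double whose probabilities come from `fun(ids)` (ids: integer vector of
# one sequence; returns L x 4 row-stochastic matrix). May inspect MASK/N.
fn_model <- function(fun, context = 350L) {
  structure(list(fun = fun), context_length = context, class = "fn_model")
}

model_forward.fn_model <- function(model, tokens, return_hidden = FALSE,
                                   return_logits = FALSE, ...) {
  if (is.vector(tokens)) tokens <- matrix(as.integer(tokens), nrow = 1)
  B <- nrow(tokens)
  L <- ncol(tokens)
  probs <- array(NA_real_, c(B, L, 4))
  logits <- array(NA_real_, c(B, L, 4))
  for (s in seq_len(B)) {
    pm <- model$fun(tokens[s, ])
    probs[s, , ] <- pm
    logits[s, , ] <- log(pmax(pm, 1e-12))
  }
  out <- list(probs = probs)
  if (return_logits) out$logits <- logits
  out
}

registerS3method("model_forward", "fn_model", model_forward.fn_model,
                 envir = asNamespace("motiflm"))

# Uniform 0.25 everywhere.
uniform_model <- function(context = 350L) {
  fn_model(function(ids) matrix(0.25, length(ids), 4), context)
}

# Position-wise fixed distributions: output never depends on the input
# (independence case for dependency maps).
fixed_model <- function(prob_matrix, context = 350L) {
  fn_model(function(ids) prob_matrix[seq_along(ids), , drop = FALSE], context)
}

# The base at position `j_dep` deterministically copies the base observed at
# position `i_src`; everything else uniform.
copy_model <- function(i_src, j_dep, p_hi = 0.97, context = 350L) {
  fn_model(function(ids) {
    pm <- matrix(0.25, length(ids), 4)
    src <- ids[i_src]
    if (src >= 1 && src <= 4) {
      pm[j_dep, ] <- (1 - p_hi) / 3
      pm[j_dep, src] <- p_hi
    }
    pm
  }, context)
}

# Motif-aware double: inside `span` (0-based half-open), if every *visible*
# (non-masked) span position matches `consensus_ids`, predict the consensus
# base confidently; elsewhere uniform. Context-sensitive, so shuffling the
# span destroys the signal.
motif_context_model <- function(span, consensus_ids, p_hi = 0.9, context = 350L) {
  fn_model(function(ids) {
    pm <- matrix(0.25, length(ids), 4)
    idx <- (span[1] + 1L):span[2]
    vis <- ids[idx] != 6L
    if (all(ids[idx][vis] == consensus_ids[vis])) {
      for (k in seq_along(idx)) {
        pm[idx[k], ] <- (1 - p_hi) / 3
        pm[idx[k], consensus_ids[k]] <- p_hi
      }
    }
    pm
  }, context)
}

# Small random corpora used across files.
make_tiny_corpus <- function(n = 20, L = 60, seed = 42) {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    }, character(1))
  })
  tibble::tibble(
    chrom = sprintf("s%03d", seq_len(n)), start = 0L, end = L, seq = seqs,
    split = rep(c("train", "val"), c(n - max(2, n %/% 5), max(2, n %/% 5))),
    repeat_runs = lapply(seqs, annotate_repeat_runs)
  )
}
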