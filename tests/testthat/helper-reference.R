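# Independent double-precision R reimplementation of the encoder forward
# pass, kept deliberately separate from the compiled path it cross-checks.

ref_layernorm <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  v <- rowMeans((X - mu)^2)
  xhat <- (X - mu) / sqrt(v + eps)
  sweep(sweep(xhat, 2, g, "*"), 2, b, "+")
}

ref_gelu <- function(Z) {
  c0 <- sqrt(2 / pi)
  0.5 * Z * (1 + tanh(c0 * (Z + 0.044715 * Z^3)))
}

ref_rope <- function(M, dh, base = 10000) {
  L <- nrow(M)
  H <- ncol(M) / dh
  half <- dh / 2
  t0 <- 0:(L - 1)
  for (h in seq_len(H) - 1) {
    for (m in seq_len(half) - 1) {
      th <- t0 * base^(-2 * m / dh)
      i0 <- h * dh + 2 * m + 1
      q0 <- M[, i0]
      q1 <- M[, i0 + 1]
      M[, i0] <- q0 * cos(th) - q1 * sin(th)
      M[, i0 + 1] <- q0 * sin(th) + q1 * cos(th)
    }
  }
  M
}

ref_softmax_rows <- function(S) {
  S <- exp(S - apply(S, 1, max))
  S / rowSums(S)
}

# Forward pass for one token id vector; returns the L x 4 probability matrix.
# use_rope = FALSE disables the rotary rotation (diagnostic variant).
ref_forward <- function(params, cfg, ids, use_rope = TRUE) {
  d <- cfg$embed_dim
  H <- cfg$n_heads
  dh <- d / H
  X <- params$embed[ids, , drop = FALSE]
  for (b in seq_len(cfg$n_blocks) - 1L) {
    p <- function(nm) params[[sprintf("b%d_%s", b, nm)]]
    U <- ref_layernorm(X, p("ln1_g"), p("ln1_b"))
    QKV <- sweep(U %*% p("w_qkv"), 2, p("b_qkv"), "+")
    Q <- QKV[, 1:d, drop = FALSE]
    K <- QKV[, (d + 1):(2 * d), drop = FALSE]
    if (use_rope) {
      Q <- ref_rope(Q, dh, cfg$rope_base)
      K <- ref_rope(K, dh, cfg$rope_base)
    }
    V <- QKV[, (2 * d + 1):(3 * d), drop = FALSE]
    O <- matrix(0, nrow(X), d)
    for (h in seq_len(H) - 1) {
      cols <- (h * dh + 1):((h + 1) * dh)
      P <- ref_softmax_rows(Q[, cols] %*% t(K[, cols]) / sqrt(dh))
      O[, cols] <- P %*% V[, cols]
    }
    X <- X + sweep(O %*% p("w_o"), 2, p("b_o"), "+")
    U2 <- ref_layernorm(X, p("ln2_g"), p("ln2_b"))
    Z <- sweep(U2 %*% p("w_ff1"), 2, p("b_ff1"), "+")
    X <- X + sweep(ref_gelu(Z) %*% p("w_ff2"), 2, p("b_ff2"), "+")
  }
  Hf <- ref_layernorm(X, params$lnf_g, params$lnf_b)
  Z1 <- sweep(Hf %*% params$head_w1, 2, params$head_b1, "+")
  N1 <- ref_layernorm(ref_gelu(Z1), params$head_ln_g, params$head_ln_b)
  logits <- sweep(N1 %*% params$head_w2, 2, params$head_b2, "+")
  ref_softmax_rows(logits)
}
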