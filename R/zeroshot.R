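# Zero-shot interrogation of a trained model: per-position likelihood
# reconstruction by iterated masking, profile normalization, contribution
# tracks for seqlet-based motif discovery, motif-vs-shuffle likelihood
# comparison, and nucleotide dependency maps.

#' Normalize a reconstructed probability matrix
#'
#' For each base k, `p_bar_k` is the mean predicted probability of k over all
#' non-N positions; the normalized likelihood of the observed base is
#' `p_norm[i] = probs[i, b_i] / p_bar_{b_i}`. N positions are `NA` and
#' excluded from the means.
#'
#' @param probs length x 4 probability matrix (rows normalized).
#' @param seq The sequence the matrix describes.
#' @return List with `p_norm` (length-L vector, `NA` at N) and `p_bar`
#'   (named length-4 vector).
#' @export
normalize_profile <- function(probs, seq) {
  ids <- encode_tokens(seq)
  if (nrow(probs) != length(ids)) rlang::abort("probs/seq length mismatch")
  if (any(abs(rowSums(probs) - 1) > 1e-4)) {
    rlang::abort("probability rows must sum to 1")
  }
  non_n <- ids <= 4L
  p_bar <- colMeans(probs[non_n, , drop = FALSE])
  names(p_bar) <- BASES
  if (any(p_bar < 1e-12)) rlang::abort("degenerate model: a base has ~zero mean probability")
  p_norm <- rep(NA_real_, length(ids))
  p_norm[non_n] <- probs[cbind(which(non_n), ids[non_n])] / unname(p_bar[ids[non_n]])
  list(p_norm = p_norm, p_bar = p_bar)
}

#' Reconstruct per-position likelihoods by iterated masking
#'
#' Row i of the result comes from a forward pass in which only position i is
#' replaced by MASK and the rest of the sequence serves as context: L forward
#' passes, batched internally (results are invariant to `batch_size`).
#'
#' @param model A model object (evaluation mode; deterministic).
#' @param seq DNA string, `nchar(seq) <= context_length`.
#' @param batch_size Masked copies per internal forward batch.
#' @return A `likelihood_profile`: tibble with `position` (0-based), `base`,
#'   `p_a`..`p_t`, `p_norm`; attributes `probs` (L x 4), `p_bar`, `seq`.
#' @export
reconstruct_likelihoods <- function(model, seq, batch_size = 64L) {
  ids <- encode_tokens(seq)
  L <- length(ids)
  probs <- matrix(NA_real_, L, 4, dimnames = list(NULL, BASES))
  chunks <- split(seq_len(L), ceiling(seq_len(L) / batch_size))
  for (ch in chunks) {
    toks <- matrix(rep(ids, each = length(ch)), nrow = length(ch))
    toks[cbind(seq_along(ch), ch)] <- MASK_ID
    out <- model_forward(model, toks)
    for (j in seq_along(ch)) probs[ch[j], ] <- out$probs[j, ch[j], ]
  }
  norm <- normalize_profile(probs, seq)
  tbl <- tibble(
    position = seq_len(L) - 1L,
    base = seq_chars(toupper(seq)),
    p_a = probs[, 1], p_c = probs[, 2], p_g = probs[, 3], p_t = probs[, 4],
    p_norm = norm$p_norm
  )
  structure(tbl, probs = probs, p_bar = norm$p_bar, seq = seq,
            class = c("likelihood_profile", class(tbl)))
}

#' Contribution track of a likelihood profile
#'
#' Per-base signed importance in the layout consumed by seqlet-based motif
#' discovery: at each position the observed base's channel carries
#' `log(p_norm)` (natural log) and other channels are 0. Missing `p_norm`
#' entries (N positions) become 0 with a logged count. Optionally also
#' returns the hypothetical all-base track `log(probs / p_bar)`.
#'
#' @param profile A [reconstruct_likelihoods()] result.
#' @param hypothetical Also compute the all-base track.
#' @return L x 4 signed matrix (attribute `hypothetical` when requested).
#' @export
contribution_track <- function(profile, hypothetical = FALSE) {
  probs <- attr(profile, "probs")
  p_bar <- attr(profile, "p_bar")
  L <- nrow(probs)
  track <- matrix(0, L, 4, dimnames = list(NULL, BASES))
  obs <- match(profile$base, BASES)
  ok <- !is.na(obs) & !is.na(profile$p_norm)
  if (any(!ok)) {
    rlang::inform(sprintf("%d position(s) without p_norm written as zeros", sum(!ok)))
  }
  track[cbind(which(ok), obs[ok])] <- unname(log(profile$p_norm[ok]))
  if (hypothetical) {
    attr(track, "hypothetical") <- log(sweep(probs, 2, p_bar, "/"))
  }
  track
}

#' Write a contribution track (and one-hot sequence) as TSV
#'
#' Layout: `position`, one-hot `seq_a..seq_t`, contribution `contrib_a..t`.
#'
#' @param track Matrix from [contribution_track()].
#' @param seq The underlying sequence.
#' @param path Output path.
#' @export
write_contribution_tsv <- function(track, seq, path) {
  ids <- encode_tokens(seq)
  onehot <- matrix(0L, length(ids), 4)
  ok <- ids <= 4L
  onehot[cbind(which(ok), ids[ok])] <- 1L
  df <- tibble(
    position = seq_along(ids) - 1L,
    seq_a = onehot[, 1], seq_c = onehot[, 2], seq_g = onehot[, 3], seq_t = onehot[, 4],
    contrib_a = track[, 1], contrib_c = track[, 2],
    contrib_g = track[, 3], contrib_t = track[, 4]
  )
  readr::write_tsv(df, path)
  invisible(path)
}

#' Dinucleotide-preserving shuffle
#'
#' Altschul-Erickson shuffle via a uniformly random Eulerian path: preserves
#' exact dinucleotide counts (and therefore mononucleotide counts and the
#' first/last base). Draws use R's RNG.
#'
#' @param seq Uppercase DNA string (length >= 2).
#' @return Shuffled string with identical dinucleotide composition.
#' @export
dinuc_shuffle <- function(seq) {
  chars <- seq_chars(toupper(seq))
  n <- length(chars)
  if (n < 2) return(seq)
  verts <- unique(chars)
  if (length(verts) == 1) return(seq) # homopolymer: single possible sequence
  edges <- lapply(setNames(verts, verts), function(v) chars[which(chars[-n] == v) + 1L])
  last <- chars[n]
  repeat {
    # choose a random final outgoing edge for every vertex except the last
    last_edge <- list()
    for (v in setdiff(verts, last)) {
      outs <- edges[[v]]
      if (length(outs) == 0) next
      last_edge[[v]] <- outs[sample.int(length(outs), 1)]
    }
    # the chosen last edges must form a tree pointing at `last`
    ok <- TRUE
    for (v in names(last_edge)) {
      cur <- v
      seen <- character(0)
      while (cur != last) {
        if (cur %in% seen || is.null(last_edge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  shuffled <- lapply(setNames(verts, verts), function(v) {
    outs <- edges[[v]]
    le <- last_edge[[v]]
    if (!is.null(le)) {
      drop_idx <- which(outs == le)[1]
      outs <- outs[-drop_idx]
    }
    out <- if (length(outs) > 1) outs[sample.int(length(outs))] else outs
    c(out, le)
  })
  used <- setNames(rep(1L, length(verts)), verts)
  res <- character(n)
  res[1] <- chars[1]
  cur <- chars[1]
  for (i in 2:n) {
    nxt <- shuffled[[cur]][used[[cur]]]
    used[[cur]] <- used[[cur]] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  paste(res, collapse = "")
}

#' Motif-vs-shuffle likelihood comparison
#'
#' Scores a motif span by its mean `log(p_norm)` under iterated-masking
#' reconstruction, then dinucleotide-shuffles *only the span* (context
#' fixed), recomputes the profile and rescores the same span, `n_shuffles`
#' times. The exceedance fraction is the share of replicates the observed
#' span strictly beats.
#'
#' @param model A model object.
#' @param seq Context sequence.
#' @param span Length-2 vector `[start, end)` (0-based) of the motif span;
#'   span length >= 2.
#' @param n_shuffles Number of shuffle replicates.
#' @param batch_size Passed to [reconstruct_likelihoods()].
#' @return A `motif_shuffle_result` list: `span`, `observed`, `replicates`,
#'   `exceedance` (fraction in \[0,1\], `NA` when `n_shuffles = 0`).
#' @export
motif_vs_shuffle_score <- function(model, seq, span, n_shuffles = 20L,
                                   batch_size = 64L) {
  stopifnot(length(span) == 2, span[1] >= 0, span[2] <= nchar(seq),
            span[2] - span[1] >= 2)
  idx <- (span[1] + 1L):span[2]
  span_score <- function(s) {
    prof <- reconstruct_likelihoods(model, s, batch_size = batch_size)
    mean(log(prof$p_norm[idx]), na.rm = TRUE)
  }
  observed <- span_score(seq)
  reps <- numeric(0)
  if (n_shuffles > 0) {
    sub <- substr(seq, span[1] + 1L, span[2])
    if (length(unique(seq_chars(toupper(sub)))) == 1) {
      rlang::inform("homopolymer span: shuffles are identical to the observed span")
    }
    reps <- vapply(seq_len(n_shuffles), function(r) {
      shuf <- dinuc_shuffle(sub)
      span_score(paste0(substr(seq, 1, span[1]), shuf,
                        substr(seq, span[2] + 1L, nchar(seq))))
    }, numeric(1))
  }
  structure(
    list(span = span, observed = observed, replicates = reps,
         exceedance = if (n_shuffles > 0) mean(observed > reps) else NA_real_),
    class = "motif_shuffle_result"
  )
}

#' Nucleotide dependency map
#'
#' With *no* masking, one reference forward pass and, for each position i,
#' three passes substituting each alternate base at i (1 + 3L passes total).
#' For target position j and base k the dependency contribution is
#' `log2(odds(P_alt[j,k]) / odds(P_ref[j,k]))` with `odds(p) = p/(1-p)`;
#' `e[i, j]` keeps the signed value of largest magnitude over the 3
#' alternates x 4 bases. Probabilities are clamped to `[1e-6, 1 - 1e-6]`
#' before odds; the diagonal is fixed at 0.
#'
#' @param model A model object.
#' @param seq DNA string (no N handling beyond the model's own).
#' @param batch_size Substituted copies per internal forward batch.
#' @return A `dependency_map`: L x L matrix `e` with attributes `seq`.
#' @export
dependency_map <- function(model, seq, batch_size = 64L) {
  ids <- encode_tokens(seq)
  L <- length(ids)
  clamp <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)
  ref <- clamp(matrix(model_forward(model, matrix(ids, nrow = 1))$probs[1, , ], ncol = 4))
  ref_odds <- log2(ref / (1 - ref))
  # enumerate all substitutions (positions x 3 alternates)
  subs <- list()
  for (i in seq_len(L)) {
    if (ids[i] > 4L) next # no defined alternates at N positions
    for (alt in setdiff(1:4, ids[i])) subs[[length(subs) + 1]] <- c(i, alt)
  }
  e <- matrix(0, L, L)
  chunks <- split(seq_along(subs), ceiling(seq_along(subs) / batch_size))
  for (ch in chunks) {
    toks <- matrix(rep(ids, each = length(ch)), nrow = length(ch))
    for (j in seq_along(ch)) toks[j, subs[[ch[j]]][1]] <- subs[[ch[j]]][2]
    out <- model_forward(model, toks)
    for (j in seq_along(ch)) {
      i <- subs[[ch[j]]][1]
      alt_p <- clamp(matrix(out$probs[j, , ], ncol = 4))
      delta <- log2(alt_p / (1 - alt_p)) - ref_odds # L x 4 signed log-odds shifts
      mag <- apply(abs(delta), 1, max)
      sgn <- delta[cbind(seq_len(L), apply(abs(delta), 1, which.max))]
      upd <- abs(sgn) > abs(e[i, ])
      e[i, upd] <- sgn[upd]
    }
  }
  diag(e) <- 0
  structure(e, seq = seq, class = c("dependency_map", "matrix", "array"))
}

#' Mean absolute dependency within vs between spans
#'
#' Diagnostic summary: mean `|e[i, j]|` over position pairs that fall inside
#' one span versus pairs drawn from outside all spans.
#'
#' @param map A [dependency_map()].
#' @param spans Tibble with `start`, `end` (0-based half-open).
#' @param n_background Number of background pairs sampled.
#' @return Tibble with `within_motif` and `background` means.
#' @export
dependency_contrast <- function(map, spans, n_background = 2000L) {
  e <- unclass(map)
  L <- nrow(e)
  within <- c()
  in_span <- rep(FALSE, L)
  for (r in seq_len(nrow(spans))) {
    idx <- (spans$start[r] + 1L):spans$end[r]
    in_span[idx] <- TRUE
    pr <- expand.grid(i = idx, j = idx)
    pr <- pr[pr$i != pr$j, ]
    within <- c(within, abs(e[cbind(pr$i, pr$j)]))
  }
  bg_idx <- which(!in_span)
  bi <- sample(bg_idx, n_background, replace = TRUE)
  bj <- sample(bg_idx, n_background, replace = TRUE)
  keep <- bi != bj
  tibble(
    within_motif = mean(within),
    background = mean(abs(e[cbind(bi[keep], bj[keep])]))
  )
}
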