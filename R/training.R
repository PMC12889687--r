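# Masked-LM objective with repeat-aware loss masking, the combined loss, and
# the training loop. Heavy lifting (forward/backward) happens in the compiled
# core; all stochastic choices are made here under R's RNG.

#' Training configuration
#'
#' Published-scale defaults: learning rate 1e-4 and 150 epochs. Small-corpus
#' demonstrations use fewer epochs and a larger rate (see the `tiny`
#' workflows). With `no_prior = TRUE` the Fourier weight is forced to zero
#' and *every* soft-masked (lowercase) base is excluded from the loss, not
#' just long runs.
#'
#' @param learning_rate Adam learning rate.
#' @param epochs Number of epochs.
#' @param batch_size Sequences per step.
#' @param mask_rate Fraction of eligible tokens selected for prediction.
#' @param patience Early-stopping patience on validation MLM loss (epochs).
#' @param no_prior Disable the Fourier prior (ablation variant).
#' @param rc_prob Reverse-complement augmentation probability per epoch.
#' @param clip_norm Global gradient-norm clip.
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 1e-4, epochs = 150L,
                            batch_size = 32L, mask_rate = 0.15,
                            patience = 10L, no_prior = FALSE,
                            rc_prob = 0.5, clip_norm = 5) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1,
            mask_rate > 0, mask_rate <= 1)
  structure(
    list(
      learning_rate = learning_rate, epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), mask_rate = mask_rate,
      patience = as.integer(patience), no_prior = isTRUE(no_prior),
      rc_prob = rc_prob, clip_norm = clip_norm
    ),
    class = "training_config"
  )
}

# Positions eligible for the loss: everything except N and (interiors of)
# lowercase repeat runs of >= min_run; with exclude_all_repeats, every
# lowercase base is dropped.
eligible_positions <- function(seq, repeat_runs, exclude_all_repeats = FALSE) {
  chars <- seq_chars(seq)
  elig <- !(toupper(chars) == "N")
  if (exclude_all_repeats) {
    elig <- elig & !grepl("[acgtn]", chars)
  } else if (nrow(repeat_runs) > 0) {
    for (r in seq_len(nrow(repeat_runs))) {
      elig[(repeat_runs[r, "start"] + 1L):repeat_runs[r, "end"]] <- FALSE
    }
  }
  which(elig)
}

#' Build a masking plan for one sequence
#'
#' Each eligible position (non-N, outside repeat runs of at least `min_run`
#' lowercase bases) is selected independently with probability `rate`;
#' selected positions are assigned masked / mutated / unchanged with
#' probabilities 0.8 / 0.1 / 0.1. "Mutated" substitutes a uniformly chosen
#' different base. Draws use R's RNG; seed upstream.
#'
#' @param seq Sequence string.
#' @param repeat_runs Integer run matrix from [annotate_repeat_runs()].
#' @param rate Selection probability (default 0.15).
#' @param exclude_all_repeats Drop every lowercase base from eligibility
#'   (the no-prior ablation convention).
#' @return A `masking_plan`: list with `input_ids` (model input tokens),
#'   `orig_ids`, `loss_positions` (1-based), `action` per selected position.
#'   A sequence with no selected positions yields an empty plan.
#' @export
build_masking_plan <- function(seq, repeat_runs = annotate_repeat_runs(seq),
                               rate = 0.15, exclude_all_repeats = FALSE) {
  orig <- encode_tokens(seq)
  elig <- eligible_positions(seq, repeat_runs, exclude_all_repeats)
  sel <- elig[runif(length(elig)) < rate]
  input <- orig
  action <- character(0)
  if (length(sel) > 0) {
    action <- sample(c("masked", "mutated", "unchanged"), length(sel),
                     replace = TRUE, prob = c(0.8, 0.1, 0.1))
    for (i in seq_along(sel)) {
      p <- sel[i]
      if (action[i] == "masked") {
        input[p] <- MASK_ID
      } else if (action[i] == "mutated") {
        input[p] <- sample(setdiff(1:4, orig[p]), 1)
      }
    }
  }
  structure(
    list(input_ids = input, orig_ids = orig, loss_positions = sel, action = action),
    class = "masking_plan"
  )
}

#' Probability of the original base at every position
#'
#' Length-L profile feeding the Fourier prior: entry i is the probability the
#' model assigns to the original base at position i; N positions take the
#' mean of the non-N entries (neutral fill).
#'
#' @param probs length x 4 probability matrix.
#' @param orig_ids Original token ids (1..5).
#' @return Numeric length-L vector.
#' @export
reference_probability_profile <- function(probs, orig_ids) {
  if (nrow(probs) != length(orig_ids)) {
    rlang::abort("probability matrix and token vector lengths differ")
  }
  non_n <- orig_ids <= 4L
  prof <- rep(NA_real_, length(orig_ids))
  prof[non_n] <- probs[cbind(which(non_n), orig_ids[non_n])]
  prof[!non_n] <- mean(prof[non_n])
  prof
}

#' Masked-LM loss of a plan
#'
#' Mean negative natural-log probability of the original base over the loss
#' positions (all three action classes contribute).
#'
#' @param probs length x 4 probability matrix from the masked forward pass.
#' @param plan A [build_masking_plan()] result.
#' @return Scalar loss; an empty plan contributes 0 (with a note).
#' @export
mlm_loss <- function(probs, plan) {
  if (length(plan$loss_positions) == 0) {
    rlang::inform("empty masking plan: sequence skipped from the MLM loss")
    return(0)
  }
  p <- probs[cbind(plan$loss_positions, plan$orig_ids[plan$loss_positions])]
  mean(-log(pmax(p, 1e-12)))
}

#' Combine MLM and Fourier-prior losses
#'
#' @param l_mlm,l_att Loss components.
#' @param lambda Prior weight.
#' @return List (`loss_breakdown`) with `l_mlm`, `l_att`, `lambda`, `l_total
#'   = l_mlm + lambda * l_att`.
#' @export
combined_loss <- function(l_mlm, l_att, lambda = 0.002) {
  stopifnot(lambda >= 0)
  structure(
    list(l_mlm = l_mlm, l_att = l_att, lambda = lambda,
         l_total = l_mlm + lambda * l_att),
    class = "loss_breakdown"
  )
}

# ---- vectorized training fast path ------------------------------------------
# The per-sequence build_masking_plan() is the reference implementation; the
# training loop applies the same distributions (Bernoulli selection,
# 0.8/0.1/0.1 actions, uniform substitution) in one matrix pass per batch.

# Token matrix + eligibility for a corpus, in both orientations.
encode_corpus <- function(corpus, exclude_all_repeats = FALSE) {
  n <- nrow(corpus)
  L <- nchar(corpus$seq[1])
  toks <- matrix(0L, n, L)
  elig <- matrix(FALSE, n, L)
  for (i in seq_len(n)) {
    toks[i, ] <- encode_tokens(corpus$seq[i])
    elig[i, eligible_positions(corpus$seq[i], corpus$repeat_runs[[i]],
                               exclude_all_repeats)] <- TRUE
  }
  rc_map <- c(4L, 3L, 2L, 1L, 5L)
  list(
    toks = toks, elig = elig,
    toks_rc = matrix(rc_map[toks[, L:1]], n, L),
    elig_rc = elig[, L:1, drop = FALSE]
  )
}

# Vectorized masking over a batch of token rows (same distributions as
# build_masking_plan). Returns the cpp_loss_grad input matrices.
mask_batch <- function(toks, elig, rate = 0.15) {
  sel <- matrix(runif(length(toks)) < rate, nrow(toks)) & elig
  act <- matrix(runif(length(toks)), nrow(toks))
  toks_in <- toks
  toks_in[sel & act < 0.8] <- MASK_ID
  mut <- sel & act >= 0.8 & act < 0.9
  if (any(mut)) {
    k <- sample.int(3L, sum(mut), replace = TRUE)
    toks_in[mut] <- ((toks[mut] - 1L + k) %% 4L) + 1L
  }
  list(toks_in = toks_in, toks_orig = toks,
       loss_mask = matrix(as.integer(sel), nrow(toks)))
}

# Assemble batch matrices from masking plans.
batch_from_plans <- function(plans, L) {
  B <- length(plans)
  toks_in <- matrix(0L, B, L)
  toks_orig <- matrix(0L, B, L)
  loss_mask <- matrix(0L, B, L)
  for (i in seq_len(B)) {
    toks_in[i, ] <- plans[[i]]$input_ids
    toks_orig[i, ] <- plans[[i]]$orig_ids
    loss_mask[i, plans[[i]]$loss_positions] <- 1L
  }
  list(toks_in = toks_in, toks_orig = toks_orig, loss_mask = loss_mask)
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr, clip_norm = 1,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  scale <- if (is.finite(gnorm) && gnorm > clip_norm) clip_norm / gnorm else 1
  state$t <- state$t + 1L
  bc1 <- 1 - 0.9^state$t
  bc2 <- 1 - 0.999^state$t
  for (nm in names(params)) {
    g <- grads[[nm]] * scale
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Validation MLM loss under a deterministic per-epoch masking stream; the
# eligibility/token matrices are computed once and cached on the tconf env.
validation_mlm <- function(params, config, enc, tconf, watt, prior, seed) {
  if (is.null(enc)) return(NA_real_)
  n <- nrow(enc$toks)
  total <- 0
  withr::with_seed(seed, {
    idx <- split(seq_len(n), ceiling(seq_len(n) / 64))
    for (ch in idx) {
      b <- mask_batch(enc$toks[ch, , drop = FALSE],
                      enc$elig[ch, , drop = FALSE], tconf$mask_rate)
      r <- cpp_loss_grad(params, config, b$toks_in, b$toks_orig, b$loss_mask,
                         0, FALSE, watt, prior$eps, FALSE)
      total <- total + r$mlm * length(ch)
    }
  })
  total / n
}

#' Train a masked DNA language model
#'
#' Per step: reverse-complement augmentation, independent masking plans,
#' one forward/backward pass computing the masked-LM loss plus the Fourier
#' prior on the per-sequence original-base probability profile (mean-filled
#' at N positions, computed from the same masked pass), and an Adam update
#' with gradient-norm clipping. Validation MLM loss is computed each epoch
#' and the best-validation weights are retained. Fully reproducible for a
#' fixed seed on one device.
#'
#' @param corpus Corpus tibble with nonempty `train` split (and ideally a
#'   `val` split); all sequences must share one length.
#' @param model_config A [model_config()].
#' @param training_config A [training_config()].
#' @param prior_config A [fourier_prior_config()].
#' @param seed Integer seed governing initialization, augmentation, masking
#'   and shuffling.
#' @param genome Optional [genome_source()] enabling shift augmentation.
#' @param shift_range Shift augmentation range (used only with a genome).
#' @param quiet Suppress the per-epoch progress line.
#' @return A trained `dna_lm`; `tidy()` returns the per-epoch metric log.
#' @export
train_model <- function(corpus,
                        model_config = motiflm::model_config("tiny"),
                        training_config = motiflm::training_config(),
                        prior_config = fourier_prior_config(),
                        seed = 1L, genome = NULL, shift_range = c(-50L, 50L),
                        quiet = FALSE) {
  tconf <- training_config
  train <- corpus[corpus$split == "train", ]
  val <- corpus[corpus$split == "val", ]
  if (nrow(train) == 0) rlang::abort("corpus has no training sequences")
  L <- unique(nchar(corpus$seq))
  if (length(L) != 1) rlang::abort("all corpus sequences must share one length")
  if (L > model_config$context_length) {
    rlang::abort("sequence length exceeds the model context")
  }
  lambda <- if (tconf$no_prior) 0 else prior_config$lambda
  watt <- spectral_weights(L, prior_config)
  set.seed(seed)
  params <- init_params(model_config, seed = seed)
  state <- adam_init(params)
  best <- list(val = Inf, params = params, epoch = 0L)
  log_rows <- list()
  wait <- 0L

  enc_base <- NULL
  enc_val <- NULL
  for (epoch in seq_len(tconf$epochs)) {
    if (is.null(genome)) {
      # standalone sequences: shift augmentation has no flanks to draw on,
      # so only reverse complement applies; token/eligibility matrices are
      # precomputed once and reused
      if (is.null(enc_base)) enc_base <- encode_corpus(train, tconf$no_prior)
      enc <- enc_base
    } else {
      aug <- augment_corpus(train, augmentation_policy(0, shift_range), genome = genome)
      enc <- encode_corpus(aug, tconf$no_prior)
    }
    rc <- runif(nrow(train)) < tconf$rc_prob
    toks_ep <- enc$toks
    elig_ep <- enc$elig
    toks_ep[rc, ] <- enc$toks_rc[rc, ]
    elig_ep[rc, ] <- enc$elig_rc[rc, ]
    ord <- sample.int(nrow(train))
    batches <- split(ord, ceiling(seq_along(ord) / tconf$batch_size))
    ep_mlm <- 0
    ep_att <- 0
    for (bi in seq_along(batches)) {
      rows <- batches[[bi]]
      b <- mask_batch(toks_ep[rows, , drop = FALSE],
                      elig_ep[rows, , drop = FALSE], tconf$mask_rate)
      r <- cpp_loss_grad(params, model_config, b$toks_in, b$toks_orig,
                         b$loss_mask, lambda, lambda > 0, watt,
                         prior_config$eps, TRUE)
      if (!is.finite(r$total)) {
        rlang::abort(sprintf(
          "training diverged (non-finite loss) at epoch %d batch %d; seeds: run=%d",
          epoch, bi, seed
        ))
      }
      up <- adam_step(params, r$grads, state, tconf$learning_rate, tconf$clip_norm)
      params <- up$params
      state <- up$state
      ep_mlm <- ep_mlm + r$mlm
      ep_att <- ep_att + r$att
    }
    if (is.null(enc_val) && nrow(val) > 0) {
      enc_val <- encode_corpus(val, tconf$no_prior)
    }
    # fixed masking stream across epochs so validation losses are comparable
    val_mlm <- validation_mlm(params, model_config, enc_val, tconf, watt,
                              prior_config, seed + 104729L)
    log_rows[[epoch]] <- tibble(
      epoch = epoch,
      train_mlm = ep_mlm / length(batches),
      train_att = ep_att / length(batches),
      val_mlm = val_mlm
    )
    if (!quiet) {
      message(sprintf(
        "epoch %d/%d  train_mlm %.4f  train_att %.4f  val_mlm %s",
        epoch, tconf$epochs, ep_mlm / length(batches), ep_att / length(batches),
        ifelse(is.na(val_mlm), "NA", sprintf("%.4f", val_mlm))
      ))
    }
    track <- if (is.na(val_mlm)) ep_mlm / length(batches) else val_mlm
    if (track < best$val) {
      best <- list(val = track, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= tconf$patience) break
    }
  }

  model <- dna_lm(model_config, params = best$params, seed = seed)
  model$log <- dplyr::bind_rows(log_rows)
  model$prior_config <- prior_config
  model$training_config <- tconf
  model$best_epoch <- best$epoch
  model
}

#' @export
tidy.dna_lm <- function(x, ...) {
  if (is.null(x$log)) {
    return(tibble(epoch = integer(), train_mlm = double(),
                  train_att = double(), val_mlm = double()))
  }
  x$log
}

#' @export
glance.dna_lm <- function(x, ...) {
  tibble(
    n_blocks = x$config$n_blocks,
    embed_dim = x$config$embed_dim,
    n_heads = x$config$n_heads,
    context_length = x$config$context_length,
    n_parameters = n_parameters(x),
    epochs_trained = if (is.null(x$log)) 0L else max(x$log$epoch),
    best_epoch = x$best_epoch %||% NA_integer_,
    best_val_mlm = if (is.null(x$log)) NA_real_ else suppressWarnings(min(x$log$val_mlm, na.rm = TRUE)),
    lambda = x$prior_config$lambda %||% NA_real_,
    seed = x$seed
  )
}
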