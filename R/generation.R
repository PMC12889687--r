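# Untargeted masked-resampling generation and objective-guided beam-search
# sequence design against pluggable oracles.

#' Untargeted generation configuration
#'
#' @param n_iter Number of mask-and-resample iterations (`N_i >= 0`).
#' @param p_mask Per-token masking probability per iteration, in \[0, 1\].
#' @param temperature Softmax temperature on the model logits (> 0); small
#'   values approach greedy argmax resampling.
#' @return A `generation_config` list.
#' @export
generation_config <- function(n_iter = 10L, p_mask = 0.1, temperature = 1) {
  stopifnot(n_iter >= 0, p_mask >= 0, p_mask <= 1, temperature > 0)
  structure(list(n_iter = as.integer(n_iter), p_mask = p_mask,
                 temperature = temperature),
            class = "generation_config")
}

#' Untargeted sequence generation by iterated masked resampling
#'
#' Repeats `n_iter` times: mask each token independently with probability
#' `p_mask`, compute `P = softmax(logits / temperature)` at the masked
#' positions, and resample only those positions; unmasked tokens are kept.
#' N positions are never masked or resampled and survive verbatim. With
#' `p_mask = 0` or `n_iter = 0` the input is returned unchanged. Draws use
#' R's RNG; seed upstream.
#'
#' @param model A model object exposing logits via [model_forward()].
#' @param seq Seed sequence (`nchar <= context_length`).
#' @param config A [generation_config()].
#' @return Generated sequence (uppercase; N preserved).
#' @export
untargeted_generate <- function(model, seq, config = generation_config()) {
  ids <- encode_tokens(seq)
  maskable <- which(ids != N_ID)
  if (config$n_iter == 0 || config$p_mask == 0 || length(maskable) == 0) {
    return(decode_tokens(ids))
  }
  for (it in seq_len(config$n_iter)) {
    sel <- maskable[runif(length(maskable)) < config$p_mask]
    if (length(sel) == 0) next
    toks <- ids
    toks[sel] <- MASK_ID
    out <- model_forward(model, matrix(toks, nrow = 1), return_logits = TRUE)
    logits <- matrix(out$logits[1, , ], ncol = 4)
    for (p in sel) {
      z <- logits[p, ] / config$temperature
      z <- z - max(z)
      pr <- exp(z) / sum(exp(z))
      ids[p] <- sample.int(4L, 1, prob = pr)
    }
  }
  decode_tokens(ids)
}

#' Beam-search configuration for targeted design
#'
#' @param n_steps Outer generation-and-evaluation steps (`N_g >= 1`).
#' @param k Sequences retained after each step (`k >= 1`).
#' @param children_per_parent Candidates each pool member spawns per step.
#' @return A `design_config` list.
#' @export
design_config <- function(n_steps = 10L, k = 5L, children_per_parent = 4L) {
  stopifnot(n_steps >= 1, k >= 1, children_per_parent >= 1)
  structure(list(n_steps = as.integer(n_steps), k = as.integer(k),
                 children_per_parent = as.integer(children_per_parent)),
            class = "design_config")
}

#' Targeted sequence design by oracle-guided beam search
#'
#' Starting from a pool holding only the seed, each step spawns
#' `children_per_parent` candidates per pool member via
#' [untargeted_generate()], scores every pool member and candidate with the
#' objective `h` (higher is better), and, whenever the pool exceeds `k`,
#' retains only the top k. Parents compete with their children at
#' retention, so the best pool score is non-decreasing across steps; ties at
#' the retention boundary break by earlier insertion. Objective values are
#' cached per sequence. For seeds longer than the model context only the
#' central `context_length` bp are edited; the frozen flanks are still part
#' of every objective call.
#'
#' @param model A model object.
#' @param seq Seed sequence.
#' @param objective Function sequence -> finite scalar (higher is better);
#'   candidates on which it fails are discarded with a logged reason.
#' @param design A [design_config()].
#' @param generation A [generation_config()].
#' @return A `design_result` list: `pool` (tibble `seq`, `score`, ranked),
#'   `trajectory` (tibble `step`, `best_score`, `pool_size`), `seed_score`,
#'   configs.
#' @export
targeted_design <- function(model, seq, objective,
                            design = design_config(),
                            generation = generation_config()) {
  context <- context_length(model)
  M <- nchar(seq)
  if (M > context) {
    c0 <- floor(M / 2) - context %/% 2L
    left <- substr(seq, 1, c0)
    core <- substr(seq, c0 + 1L, c0 + context)
    right <- substr(seq, c0 + context + 1L, M)
    rebuild <- function(x) paste0(left, x, right)
  } else {
    core <- seq
    rebuild <- identity
  }
  cache <- new.env(parent = emptyenv())
  score_of <- function(x) {
    if (!is.null(cache[[x]])) return(cache[[x]])
    val <- tryCatch(objective(rebuild(x)), error = function(e) {
      rlang::warn(sprintf("objective failed on a candidate (%s); discarded",
                          conditionMessage(e)))
      NA_real_
    })
    if (!is.null(val) && length(val) == 1 && is.finite(val)) cache[[x]] <- val else val <- NA_real_
    val
  }
  pool <- tibble(seq = core, score = score_of(core), born = 0L)
  if (is.na(pool$score[1])) rlang::abort("objective failed on the seed sequence")
  seed_score <- pool$score[1]
  traj <- vector("list", design$n_steps)
  next_id <- 1L
  for (step in seq_len(design$n_steps)) {
    kids <- list()
    for (p in pool$seq) {
      for (cidx in seq_len(design$children_per_parent)) {
        child <- untargeted_generate(model, p, generation)
        sc <- score_of(child)
        if (!is.na(sc)) {
          kids[[length(kids) + 1]] <- tibble(seq = child, score = sc, born = next_id)
          next_id <- next_id + 1L
        }
      }
    }
    pool <- dplyr::bind_rows(pool, kids)
    pool <- pool[!duplicated(pool$seq), ]
    if (nrow(pool) > design$k) {
      # stable sort: ties at the boundary break by earlier insertion
      pool <- pool[order(-pool$score, pool$born), ][seq_len(design$k), ]
    }
    traj[[step]] <- tibble(step = step, best_score = max(pool$score),
                           pool_size = nrow(pool))
  }
  pool <- pool[order(-pool$score, pool$born), ]
  pool$rank <- seq_len(nrow(pool))
  pool$seq <- vapply(pool$seq, rebuild, character(1), USE.NAMES = FALSE)
  structure(
    list(pool = dplyr::select(pool, "rank", "seq", "score"),
         trajectory = dplyr::bind_rows(traj), seed_score = seed_score,
         design = design, generation = generation),
    class = "design_result"
  )
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf(
    "<design_result> %d steps, pool %d, seed score %.4f -> best %.4f\n",
    max(x$trajectory$step), nrow(x$pool), x$seed_score, max(x$pool$score)
  ))
  invisible(x)
}

#' @export
tidy.design_result <- function(x, ...) x$trajectory

#' @export
glance.design_result <- function(x, ...) {
  tibble(
    n_steps = max(x$trajectory$step),
    seed_score = x$seed_score,
    best_score = max(x$pool$score),
    improvement = max(x$pool$score) - x$seed_score,
    pool_size = nrow(x$pool)
  )
}

#' Built-in design objectives
#'
#' `objective_pwm()` maximizes the best PWM log-odds score;
#' `objective_target()` minimizes the absolute error between an oracle
#' prediction and a target value; `objective_differential()` maximizes one
#' oracle while minimizing another as a weighted difference (cell-type
#' specificity designs).
#'
#' @param motif A [motif_model()].
#' @param background Background frequencies for the PWM score.
#' @return A function sequence -> scalar (higher is better).
#' @export
objective_pwm <- function(motif, background = rep(0.25, 4)) {
  force(motif)
  function(seq) as.numeric(pwm_log_odds_score(seq, motif, background))
}

#' @rdname objective_pwm
#' @param oracle,oracle_high,oracle_low Functions sequence -> positive scalar.
#' @param target Target oracle value.
#' @export
objective_target <- function(oracle, target) {
  force(oracle); force(target)
  function(seq) -abs(oracle(seq) - target)
}

#' @rdname objective_pwm
#' @param weight Weight on the minimized oracle.
#' @export
objective_differential <- function(oracle_high, oracle_low, weight = 1) {
  force(oracle_high); force(oracle_low); force(weight)
  function(seq) oracle_high(seq) - weight * oracle_low(seq)
}
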