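# Synthetic motif-planted corpora and labelled variant sets.
#
# Desk-scale stand-in for a regulatory-element training corpus: fixed-length
# sequences of i.i.d. background with sparse, non-overlapping PWM-sampled
# motif instances, optional lowercase repeat runs, and variant sets split
# into motif-disrupting vs background classes with PWM-derived effect sizes.

#' Specification of a synthetic corpus
#'
#' @param n_sequences Number of sequences.
#' @param length Sequence length in bp (default 350, the model context).
#' @param background Background nucleotide frequencies (A, C, G, T); the
#'   default approximates human genomic composition (42% GC).
#' @param motifs Named list of [motif_model()]s to plant.
#' @param motifs_per_seq Mean number of motif instances per sequence
#'   (Poisson-distributed, capped at `max_motifs`).
#' @param max_motifs Cap on instances per sequence.
#' @param repeat_rate Fraction of sequences receiving one lowercase repeat run.
#' @param repeat_len_range Repeat run length range (uniform integer draw);
#'   minimum 30 bp so injected runs cross the loss-exclusion threshold.
#' @param val_fraction Fraction of sequences labelled `val` (rest `train`).
#' @return A `synthetic_corpus_spec` list.
#' @export
synthetic_corpus_spec <- function(n_sequences = 1000L, length = 350L,
                                  background = c(A = 0.29, C = 0.21, G = 0.21, T = 0.29),
                                  motifs = default_motifs(),
                                  motifs_per_seq = 3, max_motifs = 5L,
                                  repeat_rate = 0.1,
                                  repeat_len_range = c(30L, 60L),
                                  val_fraction = 0.1) {
  stopifnot(abs(sum(background) - 1) < 1e-6, length >= 1, n_sequences >= 1,
            repeat_rate >= 0, repeat_rate <= 1)
  widths <- vapply(motifs, function(m) m$width, integer(1))
  if (any(widths > length)) rlang::abort("motif wider than the sequence length")
  if (max_motifs * max(widths) > length) {
    rlang::abort("infeasible packing: max_motifs * max motif width exceeds the sequence length")
  }
  structure(
    list(
      n_sequences = as.integer(n_sequences), length = as.integer(length),
      background = background, motifs = motifs,
      motifs_per_seq = motifs_per_seq, max_motifs = as.integer(max_motifs),
      repeat_rate = repeat_rate, repeat_len_range = as.integer(repeat_len_range),
      val_fraction = val_fraction
    ),
    class = "synthetic_corpus_spec"
  )
}

sample_pwm_instance <- function(pwm) {
  paste(BASES[apply(pwm, 1, function(p) sample.int(4, 1, prob = p))], collapse = "")
}

#' Generate a synthetic motif-planted corpus
#'
#' Background bases are drawn i.i.d. from the stated frequencies; each motif
#' instance is sampled column-wise from its PWM, placed uniformly without
#' overlapping other instances, on a uniformly chosen strand. Repeat runs
#' are written as lowercase outside planted spans. Regeneration with the
#' same seed is byte-identical.
#'
#' @param spec A [synthetic_corpus_spec()].
#' @param seed Integer seed.
#' @return List with `corpus` (corpus tibble; `chrom` carries synthetic ids)
#'   and `annotations` (tibble `seq_id`, `motif`, `start`, `end`, `strand`;
#'   coordinates 0-based half-open within the sequence).
#' @export
generate_corpus <- function(spec, seed = 1L) {
  set.seed(seed)
  L <- spec$length
  n <- spec$n_sequences
  ids <- sprintf("synth_%05d", seq_len(n))
  seqs <- character(n)
  runs_list <- vector("list", n)
  ann <- vector("list", n)
  motif_names <- names(spec$motifs)
  for (i in seq_len(n)) {
    chars <- sample(BASES, L, replace = TRUE, prob = spec$background)
    n_m <- min(rpois(1, spec$motifs_per_seq), spec$max_motifs)
    placed <- matrix(integer(0), ncol = 2) # occupied [start, end) spans
    rows <- list()
    if (n_m > 0) {
      for (j in seq_len(n_m)) {
        mname <- sample(motif_names, 1)
        m <- spec$motifs[[mname]]
        ok <- FALSE
        for (try in 1:200) {
          s0 <- sample.int(L - m$width + 1L, 1) - 1L
          e0 <- s0 + m$width
          if (nrow(placed) == 0 || all(e0 <= placed[, 1] | s0 >= placed[, 2])) {
            ok <- TRUE
            break
          }
        }
        if (!ok) next # sequence too crowded; skip this instance
        strand <- sample(c("+", "-"), 1)
        inst <- sample_pwm_instance(m$pwm)
        if (strand == "-") inst <- reverse_complement(inst)
        chars[(s0 + 1):e0] <- seq_chars(inst)
        placed <- rbind(placed, c(s0, e0))
        rows[[length(rows) + 1]] <- tibble(
          seq_id = ids[i], motif = mname, start = s0, end = e0, strand = strand
        )
      }
    }
    # optional lowercase repeat run, kept clear of planted spans
    if (runif(1) < spec$repeat_rate) {
      rl <- spec$repeat_len_range[1] +
        sample.int(spec$repeat_len_range[2] - spec$repeat_len_range[1] + 1L, 1) - 1L
      for (try in 1:200) {
        s0 <- sample.int(L - rl + 1L, 1) - 1L
        e0 <- s0 + rl
        if (nrow(placed) == 0 || all(e0 <= placed[, 1] | s0 >= placed[, 2])) {
          chars[(s0 + 1):e0] <- tolower(chars[(s0 + 1):e0])
          break
        }
      }
    }
    seqs[i] <- paste(chars, collapse = "")
    ann[[i]] <- if (length(rows)) dplyr::bind_rows(rows) else NULL
  }
  split <- ifelse(runif(n) < spec$val_fraction, "val", "train")
  corpus <- tibble(
    chrom = ids, start = 0L, end = L, seq = seqs, split = split,
    repeat_runs = lapply(seqs, annotate_repeat_runs, min_run = 30L)
  )
  annotations <- dplyr::bind_rows(ann)
  if (nrow(annotations) == 0) {
    annotations <- tibble(seq_id = character(), motif = character(),
                          start = integer(), end = integer(), strand = character())
  }
  list(corpus = corpus, annotations = annotations)
}

#' Build a labelled synthetic variant set
#'
#' Motif-disrupting variants substitute, at a high-information PWM column
#' whose planted base matches the consensus, the column's lowest-probability
#' base; their effect size is the PWM log-odds delta
#' `log(p_alt / p_ref)` (natural log) and they are flagged significant.
#' Background variants fall outside all planted spans, substitute a random
#' different base, and carry small zero-centered noise effects, flagged
#' non-significant.
#'
#' @param corpus Corpus tibble from [generate_corpus()].
#' @param annotations Annotation tibble from [generate_corpus()].
#' @param spec The [synthetic_corpus_spec()] used (supplies the motif PWMs).
#' @param n_per_class Length-2 vector: counts of (motif_disrupting,
#'   background) variants.
#' @param seed Integer seed.
#' @param background_sd SD of background effect-size noise.
#' @return Tibble: `seq_id`, `pos` (0-based offset), `ref`, `alt`,
#'   `effect_size`, `class`, `significant`.
#' @export
make_variant_set <- function(corpus, annotations, spec,
                             n_per_class = c(50L, 50L), seed = 1L,
                             background_sd = 0.05) {
  set.seed(seed)
  n_motif <- n_per_class[1]
  n_bg <- n_per_class[2]
  if (n_motif > 0 && nrow(annotations) == 0) {
    rlang::abort("corpus contains no planted motifs but motif variants were requested")
  }
  seq_by_id <- setNames(corpus$seq, corpus$chrom)

  motif_rows <- list()
  if (n_motif > 0) {
    # candidate variants: one per planted instance, at the most informative
    # column whose planted base matches the consensus. A candidate is kept
    # only if the substitution verifiably lowers the sequence's best PWM
    # score for that motif (short motifs can have spurious background hits
    # that would otherwise absorb the max).
    cand <- list()
    for (r in seq_len(nrow(annotations))) {
      a <- annotations[r, ]
      m <- spec$motifs[[a$motif]]
      inst <- substr(seq_by_id[[a$seq_id]], a$start + 1L, a$end)
      inst_fwd <- toupper(if (a$strand == "-") reverse_complement(inst) else inst)
      chars <- seq_chars(inst_fwd)
      cons <- seq_chars(consensus_seq(m))
      match_cols <- which(chars == cons)
      if (length(match_cols) == 0) next
      # any consensus-matching column is high-information here; draw one so
      # effect sizes vary across the PWM's column strengths
      col <- match_cols[sample.int(length(match_cols), 1)]
      colp <- m$pwm[col, ]
      ref_fwd <- BASES[which.max(colp)] # consensus by construction
      alt_fwd <- BASES[which.min(colp)]
      if (a$strand == "+") {
        pos <- a$start + col - 1L
        ref <- ref_fwd
        alt <- alt_fwd
      } else {
        pos <- a$end - col # column col maps to end - col on the minus strand
        ref <- chartr("ACGT", "TGCA", ref_fwd)
        alt <- chartr("ACGT", "TGCA", alt_fwd)
      }
      before <- toupper(seq_by_id[[a$seq_id]])
      after <- before
      substr(after, pos + 1L, pos + 1L) <- alt
      if (pwm_log_odds_score(after, m) >= pwm_log_odds_score(before, m)) next
      cand[[length(cand) + 1]] <- tibble(
        seq_id = a$seq_id, pos = as.integer(pos), ref = ref, alt = alt,
        effect_size = log(colp[[alt_fwd]] / colp[[ref_fwd]]),
        class = "motif_disrupting", significant = TRUE
      )
    }
    if (length(cand) < n_motif) {
      rlang::abort(sprintf(
        "requested %d motif-disrupting variants but only %d eligible positions exist",
        n_motif, length(cand)
      ))
    }
    motif_rows <- cand[sample(length(cand), n_motif)]
  }

  bg_rows <- list()
  if (n_bg > 0) {
    spans <- split(annotations, annotations$seq_id)
    for (j in seq_len(n_bg)) {
      for (try in 1:500) {
        sid <- sample(corpus$chrom, 1)
        pos <- sample.int(nchar(seq_by_id[[sid]]), 1) - 1L
        sp <- spans[[sid]]
        inside <- !is.null(sp) && any(pos >= sp$start & pos < sp$end)
        ref <- toupper(substr(seq_by_id[[sid]], pos + 1L, pos + 1L))
        if (!inside && ref %in% BASES) break
      }
      alt <- sample(setdiff(BASES, ref), 1)
      bg_rows[[length(bg_rows) + 1]] <- tibble(
        seq_id = sid, pos = as.integer(pos), ref = ref, alt = alt,
        effect_size = rnorm(1, 0, background_sd),
        class = "background", significant = FALSE
      )
    }
  }

  out <- dplyr::bind_rows(c(motif_rows, bg_rows))
  # contract: the stored ref base equals the sequence base at the offset
  stopifnot(all(toupper(substr(seq_by_id[out$seq_id], out$pos + 1L, out$pos + 1L)) == out$ref))
  out
}

#' Write / read a variant table
#'
#' TSV dialect with 1-based positions on disk (`seq_id`, `pos_1based`,
#' `ref`, `alt`, `effect_size`, `significant`, `class`); converted to
#' 0-based offsets internally.
#'
#' @param variants Variant tibble (0-based `pos`).
#' @param path Output path.
#' @export
write_variants_tsv <- function(variants, path) {
  readr::write_tsv(
    dplyr::mutate(variants, pos_1based = .data$pos + 1L, pos = NULL)[
      , c("seq_id", "pos_1based", "ref", "alt", "effect_size", "significant", "class")
    ],
    path
  )
  invisible(path)
}

#' @rdname write_variants_tsv
#' @export
read_variants_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  dplyr::mutate(x, pos = as.integer(.data$pos_1based) - 1L, pos_1based = NULL)
}
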