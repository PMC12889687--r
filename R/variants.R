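# Variant scoring: zero-shot masked log-likelihood ratios, oracle-based
# log2 fold-change scoring, and the evaluation protocol that restricts
# correlations to variants with significant observed effects.

#' Validate a variant table against a genome
#'
#' A variant table has columns `seq_id` (or `chrom`), `pos` (0-based), `ref`,
#' `alt`, and optionally `effect_size` and `significant`. The reference base
#' must match the genome (case-folded); mismatches are flagged, not dropped.
#'
#' @param variants Variant tibble.
#' @param genome A [genome_source()].
#' @return The tibble with a logical `ref_mismatch` column.
#' @export
check_variants <- function(variants, genome) {
  if (!"seq_id" %in% names(variants) && "chrom" %in% names(variants)) {
    variants <- dplyr::rename(variants, seq_id = "chrom")
  }
  stopifnot(all(c("seq_id", "pos", "ref", "alt") %in% names(variants)))
  if (any(variants$ref == variants$alt)) rlang::abort("ref and alt alleles must differ")
  if (!all(c(variants$ref, variants$alt) %in% BASES)) {
    rlang::abort("ref/alt must be single bases in {A, C, G, T}")
  }
  obs <- vapply(seq_len(nrow(variants)), function(i) {
    toupper(get_sequence(genome, variants$seq_id[i], variants$pos[i], variants$pos[i] + 1L))
  }, character(1))
  variants$ref_mismatch <- obs != variants$ref
  if (any(variants$ref_mismatch)) {
    rlang::warn(sprintf(
      "%d variant(s) whose ref allele does not match the genome; scores withheld",
      sum(variants$ref_mismatch)
    ))
  }
  variants
}

# Extract a window of `window` bp centered on pos, sliding inside chromosome
# bounds when needed. Returns the window string and the variant offset.
variant_window <- function(genome, seq_id, pos, window) {
  clen <- genome$lengths[[seq_id]]
  if (clen < window) rlang::abort(sprintf("sequence %s shorter than the scoring window", seq_id))
  start <- pos - window %/% 2L
  start <- min(max(start, 0L), clen - window)
  list(seq = get_sequence(genome, seq_id, start, start + window),
       offset = pos - start)
}

#' Zero-shot variant scoring by masked log-likelihood ratio
#'
#' For each variant, the `window` bp sequence centered on the position is
#' extracted, the variant position is masked, and one forward pass yields
#' `s = log(p(alt) / p(ref))` (natural log; the base only rescales, and rank
#' metrics are base-invariant). Swapping ref and alt negates `s` exactly.
#'
#' @param model A model object.
#' @param genome A [genome_source()] (for standalone synthetic sequences,
#'   build one from the corpus with `genome_source(setNames(corpus$seq,
#'   corpus$chrom))`).
#' @param variants Variant tibble (see [check_variants()]).
#' @param window Scoring window (default 350).
#' @param batch_size Variants per forward batch.
#' @param on_mismatch Policy for variants whose ref allele does not match the
#'   genome: `"withhold"` (default; score stays `NA`) or `"score"` (score
#'   anyway — the masked input is identical either way; used e.g. for
#'   allele-swap diagnostics).
#' @return Score table: the input plus `score` (`NA` where the ref allele
#'   mismatched the genome, under the default policy) and `ref_mismatch`.
#' @export
zero_shot_llr <- function(model, genome, variants, window = 350L,
                          batch_size = 64L,
                          on_mismatch = c("withhold", "score")) {
  on_mismatch <- match.arg(on_mismatch)
  variants <- check_variants(variants, genome)
  n <- nrow(variants)
  score <- rep(NA_real_, n)
  todo <- if (on_mismatch == "score") seq_len(n) else which(!variants$ref_mismatch)
  chunks <- split(todo, ceiling(seq_along(todo) / batch_size))
  for (ch in chunks) {
    toks <- matrix(0L, length(ch), window)
    offs <- integer(length(ch))
    for (j in seq_along(ch)) {
      i <- ch[j]
      w <- variant_window(genome, variants$seq_id[i], variants$pos[i], window)
      ids <- encode_tokens(w$seq)
      ids[w$offset + 1L] <- MASK_ID
      toks[j, ] <- ids
      offs[j] <- w$offset + 1L
    }
    out <- model_forward(model, toks)
    for (j in seq_along(ch)) {
      i <- ch[j]
      p <- out$probs[j, offs[j], ]
      score[i] <- log(p[TOKENS[[variants$alt[i]]]] / p[TOKENS[[variants$ref[i]]]])
    }
  }
  variants$score <- score
  variants
}

#' Supervised-style variant scoring through an oracle
#'
#' Builds the reference and alternate window sequences differing only at the
#' central position and scores `log2(g(S_alt) / g(S_ref))` for a
#' strictly-positive oracle `g` (e.g. predicted accessibility counts).
#'
#' @param oracle Function mapping a sequence string to a positive scalar.
#' @param genome A [genome_source()].
#' @param variants Variant tibble.
#' @param window Oracle input length (default 2114).
#' @return Score table with an `oracle_score` column.
#' @export
oracle_log_fold_change <- function(oracle, genome, variants, window = 2114L) {
  variants <- check_variants(variants, genome)
  score <- rep(NA_real_, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    if (variants$ref_mismatch[i]) next
    w <- variant_window(genome, variants$seq_id[i], variants$pos[i], window)
    s_ref <- w$seq
    substr(s_ref, w$offset + 1L, w$offset + 1L) <- variants$ref[i]
    s_alt <- w$seq
    substr(s_alt, w$offset + 1L, w$offset + 1L) <- variants$alt[i]
    g_ref <- oracle(s_ref)
    g_alt <- oracle(s_alt)
    if (!is.finite(g_ref) || !is.finite(g_alt) || g_ref <= 0 || g_alt <= 0) {
      rlang::abort(sprintf(
        "oracle returned a non-positive value for variant %s:%d",
        variants$seq_id[i], variants$pos[i]
      ))
    }
    score[i] <- log2(g_alt / g_ref)
  }
  variants$oracle_score <- score
  variants
}

#' Evaluate variant scores against observed effects
#'
#' Pearson and Spearman correlations between scores and observed effect
#' sizes are computed on the *significant* subset only; AUROC discriminates
#' significant from non-significant variants using the score magnitude
#' `|score|` and uses all variants.
#'
#' @param scores Score table with `score` (or the column named in
#'   `score_col`), `effect_size`, `significant`.
#' @param score_col Which score column to evaluate.
#' @return One-row tibble: `pearson`, `spearman`, `auroc`, `n_significant`,
#'   `n_total`, `n_missing`; metrics are `NA` with a warning when
#'   undercounted (fewer than 3 significant variants, or a single class).
#' @export
evaluate_variant_scores <- function(scores, score_col = "score") {
  stopifnot(all(c(score_col, "effect_size", "significant") %in% names(scores)))
  s <- scores[[score_col]]
  ok <- !is.na(s)
  sig <- scores$significant & ok
  pearson <- spearman <- auroc <- NA_real_
  if (sum(sig) >= 3) {
    if (sd(s[sig]) == 0 || sd(scores$effect_size[sig]) == 0) {
      rlang::warn("zero variance among significant variants: correlations are NA")
    } else {
      pearson <- cor(s[sig], scores$effect_size[sig])
      spearman <- cor(s[sig], scores$effect_size[sig], method = "spearman")
    }
  } else {
    rlang::warn("fewer than 3 significant variants: correlations reported as NA")
  }
  if (length(unique(scores$significant[ok])) == 2) {
    roc <- pROC::roc(
      response = scores$significant[ok], predictor = abs(s[ok]),
      levels = c(FALSE, TRUE), direction = "<", quiet = TRUE
    )
    auroc <- as.numeric(pROC::auc(roc))
  } else {
    rlang::warn("both significance classes required for AUROC: reported as NA")
  }
  tibble(
    pearson = pearson, spearman = spearman, auroc = auroc,
    n_significant = sum(sig), n_total = nrow(scores), n_missing = sum(!ok)
  )
}

#' Read a minimal VCF of SNVs
#'
#' Accepts the minimal subset (CHROM, POS, REF, ALT) with optional INFO keys
#' `EFFECT` (observed effect size) and `SIG` (0/1 significance flag).
#' Positions are 1-based in the file and converted to 0-based offsets.
#'
#' @param path VCF path.
#' @return Variant tibble (`seq_id`, `pos`, `ref`, `alt`, `effect_size`,
#'   `significant`).
#' @export
read_variants_vcf <- function(path) {
  rlang::check_installed("vcfR")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info_field <- function(info, key) {
    ifelse(grepl(paste0("(^|;)", key, "="), info),
           sub(paste0(".*", key, "=([^;]*).*"), "\\1", info), NA)
  }
  tibble(
    seq_id = fix$CHROM,
    pos = as.integer(fix$POS) - 1L,
    ref = fix$REF,
    alt = fix$ALT,
    effect_size = suppressWarnings(as.numeric(info_field(fix$INFO, "EFFECT"))),
    significant = suppressWarnings(as.integer(info_field(fix$INFO, "SIG"))) == 1L
  )
}

#' Write variants as minimal VCF
#'
#' @param variants Variant tibble (0-based `pos`).
#' @param path Output path.
#' @export
write_variants_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=EFFECT,Number=1,Type=Float,Description=\"Observed effect size\">",
    "##INFO=<ID=SIG,Number=1,Type=Integer,Description=\"Significant observed effect (1=yes)\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  eff <- if ("effect_size" %in% names(variants)) variants$effect_size else NA
  sig <- if ("significant" %in% names(variants)) as.integer(variants$significant) else NA
  writeLines(sprintf(
    "%s\t%d\t.\t%s\t%s\t.\t.\tEFFECT=%s;SIG=%s",
    variants$seq_id, variants$pos + 1L, variants$ref, variants$alt,
    ifelse(is.na(eff), ".", sprintf("%.6g", eff)),
    ifelse(is.na(sig), ".", as.character(sig))
  ), con)
  invisible(path)
}
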