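llr_fixture <- function() {
  spec <- synthetic_corpus_spec(n_sequences = 60)
  gen <- generate_corpus(spec, seed = 41)
  vars <- make_variant_set(gen$corpus, gen$annotations, spec,
                           n_per_class = c(20L, 20L), seed = 6)
  genome <- genome_source(setNames(gen$corpus$seq, gen$corpus$chrom))
  list(gen = gen, vars = vars, genome = genome, spec = spec)
}

test_that("the LLR score is the printed log ratio at the masked center", {
  # double with fixed probabilities at every position
  m <- fn_model(function(ids) {
    matrix(rep(c(0.1, 0.2, 0.3, 0.4), each = length(ids)), length(ids), 4)
  }, context = 350L)
  fx <- llr_fixture()
  v <- fx$vars[fx$vars$ref == "A" & fx$vars$alt == "T", ][1, ]
  sc <- zero_shot_llr(m, fx$genome, v)
  expect_equal(sc$score, log(0.4 / 0.1), tolerance = 1e-9)
  v2 <- fx$vars[1, ]
  p <- c(A = 0.1, C = 0.2, G = 0.3, T = 0.4)
  expect_equal(zero_shot_llr(m, fx$genome, v2)$score,
               log(p[[v2$alt]] / p[[v2$ref]]), tolerance = 1e-9)
})

test_that("swapping ref and alt negates the score exactly", {
  fx <- llr_fixture()
  m <- dna_lm(model_config("tiny"), seed = 13) # untrained weights suffice
  s1 <- zero_shot_llr(m, fx$genome, fx$vars)
  swapped <- dplyr::mutate(fx$vars, tmp = ref, ref = alt, alt = tmp, tmp = NULL)
  # the masked input is identical for both allele orderings, so swapping
  # negates the log ratio exactly; score despite the genome-ref mismatch
  s2 <- suppressWarnings(zero_shot_llr(m, fx$genome, swapped, on_mismatch = "score"))
  expect_equal(s2$score, -s1$score, tolerance = 1e-12)
})

test_that("ref-mismatching variants are flagged and withheld, not dropped", {
  fx <- llr_fixture()
  bad <- fx$vars
  bad$ref[1] <- setdiff(c("A", "C", "G", "T"), c(bad$ref[1], bad$alt[1]))[1]
  m <- uniform_model()
  expect_warning(sc <- zero_shot_llr(m, fx$genome, bad), "does not match")
  expect_equal(nrow(sc), nrow(bad))
  expect_true(is.na(sc$score[1]))
  expect_true(sc$ref_mismatch[1])
  expect_false(any(is.na(sc$score[-1])))
})

test_that("oracle log fold-change follows its closed forms", {
  fx <- llr_fixture()
  v <- fx$vars[fx$vars$class == "motif_disrupting", ][1:5, ]
  expect_equal(
    oracle_log_fold_change(function(s) 3.7, fx$genome, v, window = 350L)$oracle_score,
    rep(0, 5)
  )
  # an oracle that doubles when the alt allele is present at the variant
  # position (the 350-bp window over a 350-bp sequence is the sequence itself)
  g2 <- function(s) if (substr(s, v$pos[1] + 1, v$pos[1] + 1) == v$alt[1]) 2 else 1
  one <- oracle_log_fold_change(g2, fx$genome, v[1, ], window = 350L)
  expect_equal(one$oracle_score, 1.0)
  expect_error(
    oracle_log_fold_change(function(s) 0, fx$genome, v[1, ], window = 350L),
    "non-positive"
  )
})

test_that("a PWM-sum oracle scores motif-disrupting variants negative", {
  fx <- llr_fixture()
  motifs <- fx$spec$motifs
  # summed best-hit score per motif: disrupting any planted instance lowers it
  oracle <- function(s) {
    exp(sum(vapply(motifs, function(m) {
      as.numeric(pwm_log_odds_score(s, m))
    }, numeric(1))) / 10)
  }
  v <- fx$vars[fx$vars$class == "motif_disrupting", ][1:8, ]
  sc <- oracle_log_fold_change(oracle, fx$genome, v, window = 350L)
  expect_true(all(sc$oracle_score < 0))
})

test_that("evaluation restricts correlations to significant variants", {
  withr::with_seed(14, {
    eff <- c(rnorm(40, 0, 2), rnorm(40, 0, 0.1))
    tbl <- tibble::tibble(
      score = c(eff[1:40] + rnorm(40, 0, 0.01), rnorm(40, 0, 0.1)),
      effect_size = eff,
      significant = rep(c(TRUE, FALSE), each = 40)
    )
  })
  ev <- evaluate_variant_scores(tbl)
  expect_gt(ev$pearson, 0.99)
  expect_equal(ev$n_significant, 40L)
  expect_equal(ev$n_total, 80L)
  # perfect scores give perfect correlations
  perfect <- dplyr::mutate(tbl, score = effect_size)
  ev2 <- evaluate_variant_scores(perfect)
  expect_equal(ev2$pearson, 1)
  expect_equal(ev2$spearman, 1)
})

test_that("random scores give chance-level AUROC (permutation null)", {
  withr::with_seed(15, {
    tbl <- tibble::tibble(
      score = rnorm(500),
      effect_size = rnorm(500),
      significant = rep(c(TRUE, FALSE), 250)
    )
  })
  ev <- evaluate_variant_scores(tbl)
  n1 <- 250; n2 <- 250
  null_sd <- sqrt((n1 + n2 + 1) / (12 * n1 * n2))
  expect_lt(abs(ev$auroc - 0.5), 3 * null_sd)
})

test_that("degenerate evaluation inputs yield NA metrics with warnings", {
  tbl <- tibble::tibble(score = rnorm(5), effect_size = rnorm(5),
                        significant = rep(FALSE, 5))
  expect_warning(expect_warning(ev <- evaluate_variant_scores(tbl), "significant"),
                 "AUROC")
  expect_true(is.na(ev$pearson))
  expect_true(is.na(ev$auroc))
})

test_that("variant VCF writing and reading round-trips", {
  fx <- llr_fixture()
  p <- withr::local_tempfile(fileext = ".vcf")
  write_variants_vcf(fx$vars, p)
  back <- read_variants_vcf(p)
  expect_equal(back$pos, fx$vars$pos)
  expect_equal(back$ref, fx$vars$ref)
  expect_equal(back$alt, fx$vars$alt)
  expect_equal(back$significant, fx$vars$significant)
  expect_equal(back$effect_size, fx$vars$effect_size, tolerance = 1e-5)
})
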