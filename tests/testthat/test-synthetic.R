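test_that("a motif-free spec yields no annotations", {
  spec <- synthetic_corpus_spec(n_sequences = 20, motifs_per_seq = 0)
  gen <- generate_corpus(spec, seed = 1)
  expect_equal(nrow(gen$annotations), 0L)
  expect_true(all(nchar(gen$corpus$seq) == 350L))
})

test_that("planted counts and composition match the sampling distributions", {
  spec <- synthetic_corpus_spec(
    n_sequences = 1000, motifs_per_seq = 2,
    background = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
    repeat_rate = 0
  )
  gen <- generate_corpus(spec, seed = 3)
  # instances per sequence ~ min(Poisson(2), 5); oracle moments from the pmf
  # (placement rejection can drop instances only in pathologically crowded
  # sequences, which do not occur at this density)
  k <- 0:5
  pk <- dpois(k, 2)
  pk[6] <- 1 - sum(pk[1:5])
  mu <- sum(k * pk)
  v <- sum(k^2 * pk) - mu^2
  total <- nrow(gen$annotations)
  expect_lt(abs(total - 1000 * mu), 3 * sqrt(1000 * v))
  # background composition: multinomial oracle on motif-free positions
  spec0 <- synthetic_corpus_spec(
    n_sequences = 1000, motifs_per_seq = 0,
    background = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3), repeat_rate = 0
  )
  gen0 <- generate_corpus(spec0, seed = 4)
  chars <- unlist(strsplit(gen0$corpus$seq, ""))
  n <- length(chars)
  for (b in c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
    base <- names(which(c(A = 0.3, C = 0.2, G = 0.2, T = 0.3) == b))[1]
  }
  freq <- table(factor(chars, levels = c("A", "C", "G", "T"))) / n
  for (i in 1:4) {
    p <- c(0.3, 0.2, 0.2, 0.3)[i]
    expect_lt(abs(freq[[i]] - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("annotations exactly describe planted spans", {
  spec <- synthetic_corpus_spec(n_sequences = 50)
  gen <- generate_corpus(spec, seed = 7)
  seq_by_id <- setNames(gen$corpus$seq, gen$corpus$chrom)
  for (r in seq_len(nrow(gen$annotations))) {
    a <- gen$annotations[r, ]
    m <- spec$motifs[[a$motif]]
    expect_equal(a$end - a$start, m$width)
    inst <- toupper(substr(seq_by_id[[a$seq_id]], a$start + 1, a$end))
    if (a$strand == "-") inst <- reverse_complement(inst)
    # sampled from a 0.94-dominant PWM: most planted bases match consensus
    cons <- consensus_seq(m)
    matches <- sum(strsplit(inst, "")[[1]] == strsplit(cons, "")[[1]])
    expect_gte(matches, ceiling(m$width / 2))
  }
  # spans never overlap within one sequence
  by_seq <- split(gen$annotations, gen$annotations$seq_id)
  for (sp in by_seq) {
    sp <- sp[order(sp$start), ]
    if (nrow(sp) > 1) expect_true(all(sp$start[-1] >= sp$end[-nrow(sp)]))
  }
})

test_that("regeneration with the same seed is byte-identical", {
  spec <- synthetic_corpus_spec(n_sequences = 30)
  g1 <- generate_corpus(spec, seed = 9)
  g2 <- generate_corpus(spec, seed = 9)
  expect_identical(g1, g2)
  g3 <- generate_corpus(spec, seed = 10)
  expect_false(identical(g1$corpus$seq, g3$corpus$seq))
})

test_that("lowercase fraction tracks the repeat-injection rate", {
  spec <- synthetic_corpus_spec(n_sequences = 400, motifs_per_seq = 0,
                                repeat_rate = 0.5, repeat_len_range = c(40L, 40L))
  gen <- generate_corpus(spec, seed = 5)
  has_run <- vapply(gen$corpus$repeat_runs, nrow, integer(1)) > 0
  expect_lt(abs(mean(has_run) - 0.5), 3 * sqrt(0.25 / 400))
  lower <- mean(grepl("[acgt]", unlist(strsplit(gen$corpus$seq, ""))))
  expect_equal(lower, mean(has_run) * 40 / 350, tolerance = 0.01)
})

test_that("PWM scoring matches a brute-force scan and its closed forms", {
  unif <- motif_model("unif", matrix(0.25, 6, 4))
  expect_equal(as.numeric(pwm_log_odds_score("ACGTACGTACGT", unif)), 0)
  m <- default_motifs()$ap1_like
  cons <- consensus_seq(m)
  max_score <- sum(log(apply(m$pwm, 1, max) / 0.25))
  expect_equal(as.numeric(pwm_log_odds_score(cons, m)), max_score)
  # brute-force oracle over all placements and strands of a 20-bp sequence
  withr::with_seed(2, {
    seq <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  })
  brute <- -Inf
  for (s in list(seq, reverse_complement(seq))) {
    chars <- strsplit(s, "")[[1]]
    for (o in 1:(20 - m$width + 1)) {
      sc <- 0
      for (j in 1:m$width) {
        sc <- sc + log(m$pwm[j, chars[o + j - 1]] / 0.25)
      }
      brute <- max(brute, sc)
    }
  }
  expect_equal(as.numeric(pwm_log_odds_score(seq, m)), brute, tolerance = 1e-12)
  # reverse-complementing the sequence leaves the two-strand score unchanged
  expect_equal(as.numeric(pwm_log_odds_score(reverse_complement(seq), m)),
               as.numeric(pwm_log_odds_score(seq, m)))
})

test_that("variant sets honor their class contracts", {
  spec <- synthetic_corpus_spec(n_sequences = 150)
  gen <- generate_corpus(spec, seed = 21)
  vars <- make_variant_set(gen$corpus, gen$annotations, spec,
                           n_per_class = c(40L, 40L), seed = 2)
  expect_equal(nrow(vars), 80L)
  expect_equal(sum(vars$class == "motif_disrupting"), 40L)
  expect_true(all(vars$significant == (vars$class == "motif_disrupting")))
  seq_by_id <- setNames(gen$corpus$seq, gen$corpus$chrom)
  # stored ref equals the sequence base; motif variants sit inside spans
  for (r in seq_len(nrow(vars))) {
    v <- vars[r, ]
    expect_equal(toupper(substr(seq_by_id[[v$seq_id]], v$pos + 1, v$pos + 1)), v$ref)
    sp <- gen$annotations[gen$annotations$seq_id == v$seq_id, ]
    inside <- nrow(sp) > 0 && any(v$pos >= sp$start & v$pos < sp$end)
    expect_equal(inside, v$class == "motif_disrupting")
  }
  expect_true(all(abs(vars$effect_size[vars$class == "background"]) < 0.5))
  expect_true(all(vars$effect_size[vars$class == "motif_disrupting"] < -1))
})

test_that("motif-disrupting variants strictly lower the PWM score", {
  spec <- synthetic_corpus_spec(n_sequences = 100)
  gen <- generate_corpus(spec, seed = 31)
  ann <- gen$annotations
  vars <- make_variant_set(gen$corpus, ann, spec, n_per_class = c(30L, 0L), seed = 3)
  seq_by_id <- setNames(toupper(gen$corpus$seq), gen$corpus$chrom)
  for (r in seq_len(nrow(vars))) {
    v <- vars[r, ]
    sp <- ann[ann$seq_id == v$seq_id & ann$start <= v$pos & ann$end > v$pos, ]
    m <- spec$motifs[[sp$motif[1]]]
    before <- seq_by_id[[v$seq_id]]
    after <- before
    substr(after, v$pos + 1, v$pos + 1) <- v$alt
    expect_lt(as.numeric(pwm_log_odds_score(after, m)),
              as.numeric(pwm_log_odds_score(before, m)))
  }
})

test_that("PWM log-odds effect sizes come straight from the column", {
  # 0.97-dominant columns with a distinctive consensus (TGACTC)
  pwm <- matrix(0.01, 6, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(6)) pwm[i, c("T", "G", "A", "C", "T", "C")[i]] <- 0.97
  m <- motif_model("toy", pwm, floor = 0.01)
  spec <- synthetic_corpus_spec(n_sequences = 40, motifs = list(toy = m),
                                motifs_per_seq = 1, repeat_rate = 0)
  gen <- generate_corpus(spec, seed = 8)
  vars <- make_variant_set(gen$corpus, gen$annotations, spec,
                           n_per_class = c(10L, 0L), seed = 4)
  expect_true(all(abs(vars$effect_size - log(0.01 / 0.97)) < 1e-12))
  expect_equal(log(0.01 / 0.97), -4.575, tolerance = 1e-4)
})

test_that("MEME minimal format round-trips", {
  motifs <- default_motifs()
  p <- withr::local_tempfile(fileext = ".meme")
  write_meme(motifs, p)
  back <- read_meme(p)
  expect_equal(names(back), names(motifs))
  for (nm in names(motifs)) {
    expect_equal(back[[nm]]$pwm, motifs[[nm]]$pwm, tolerance = 1e-5)
  }
})

test_that("variant TSV round trip preserves coordinates and flags", {
  spec <- synthetic_corpus_spec(n_sequences = 50)
  gen <- generate_corpus(spec, seed = 12)
  vars <- make_variant_set(gen$corpus, gen$annotations, spec,
                           n_per_class = c(15L, 15L), seed = 5)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_variants_tsv(vars, p)
  back <- read_variants_tsv(p)
  expect_equal(back$pos, vars$pos)
  expect_equal(back$ref, vars$ref)
  expect_equal(back$significant, vars$significant)
  expect_equal(back$effect_size, vars$effect_size, tolerance = 1e-9)
})
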