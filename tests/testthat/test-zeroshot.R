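test_that("a uniform model reconstructs to p_norm = 1 and zero contributions", {
  m <- uniform_model(context = 60L)
  withr::with_seed(1, {
    seq <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  })
  prof <- reconstruct_likelihoods(m, seq)
  expect_equal(unname(attr(prof, "p_bar")), rep(0.25, 4))
  expect_equal(prof$p_norm, rep(1, 40))
  rows <- attr(prof, "probs")
  expect_true(max(abs(rowSums(rows) - 1)) < 1e-6)
  expect_true(all(contribution_track(prof) == 0))
})

test_that("profile normalization matches a hand computation", {
  # 4-bp toy: explicit probabilities, observed bases A C G T
  probs <- rbind(
    c(0.7, 0.1, 0.1, 0.1),
    c(0.2, 0.5, 0.2, 0.1),
    c(0.1, 0.2, 0.6, 0.1),
    c(0.25, 0.25, 0.1, 0.4)
  )
  norm <- normalize_profile(probs, "ACGT")
  p_bar <- colMeans(probs)
  expect_equal(unname(norm$p_bar), p_bar)
  expect_equal(norm$p_norm,
               c(0.7 / p_bar[1], 0.5 / p_bar[2], 0.6 / p_bar[3], 0.4 / p_bar[4]))
  # malformed rows are rejected
  expect_error(normalize_profile(probs * 2, "ACGT"), "sum to 1")
  # N positions are NA and excluded from the means
  norm_n <- normalize_profile(probs, "ACNT")
  expect_true(is.na(norm_n$p_norm[3]))
  expect_equal(unname(norm_n$p_bar), colMeans(probs[c(1, 2, 4), ]))
})

test_that("reconstruction masks one position at a time and is batch invariant", {
  # model that reveals whether position i was masked when predicting row i
  probe <- fn_model(function(ids) {
    pm <- matrix(0.25, length(ids), 4)
    for (i in seq_along(ids)) {
      if (ids[i] == 6L) pm[i, ] <- c(0.7, 0.1, 0.1, 0.1)
    }
    pm
  }, context = 64L)
  seq <- strrep("A", 30)
  prof <- reconstruct_likelihoods(probe, seq, batch_size = 7)
  # every row must come from the pass where that position was MASKed
  expect_true(all(abs(prof$p_a - 0.7) < 1e-12))
  prof2 <- reconstruct_likelihoods(probe, seq, batch_size = 30)
  expect_equal(as.data.frame(prof), as.data.frame(prof2))
})

test_that("contribution tracks carry log(p_norm) on the observed channel", {
  probs <- matrix(0.25, 10, 4)
  probs[3, ] <- c(0.5, 1 / 6, 1 / 6, 1 / 6)
  m <- fixed_model(probs, context = 32L)
  seq <- strrep("A", 10)
  prof <- reconstruct_likelihoods(m, seq)
  track <- contribution_track(prof)
  expect_equal(dim(track), c(10L, 4L))
  expect_true(all(track[, 2:4] == 0))
  expect_equal(unname(track[3, 1]), log(prof$p_norm[3]))
  # p_norm = 2 at an A gives exactly ln 2 on the A channel
  probs2 <- matrix(0.25, 10, 4)
  m2 <- fixed_model(probs2, context = 32L)
  prof2 <- reconstruct_likelihoods(m2, seq)
  prof2$p_norm[5] <- 2
  expect_equal(unname(contribution_track(prof2)[5, 1]), log(2), tolerance = 1e-12)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_contribution_tsv(track, seq, p)
  back <- readr::read_tsv(p, show_col_types = FALSE)
  expect_equal(nrow(back), 10L)
  expect_equal(back$contrib_a, track[, 1])
})

test_that("dinucleotide shuffle preserves exact dinucleotide counts", {
  count_dinucs <- function(s) {
    ch <- strsplit(s, "")[[1]]
    table(paste0(ch[-length(ch)], ch[-1]))
  }
  withr::with_seed(3, {
    for (i in 1:10) {
      s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
      sh <- dinuc_shuffle(s)
      expect_equal(count_dinucs(sh), count_dinucs(s))
      expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
      expect_equal(substr(sh, 60, 60), substr(s, 60, 60))
    }
  })
  # seeded determinism
  s <- "ACGTACGGTTCAACGT"
  withr::with_seed(5, a <- dinuc_shuffle(s))
  withr::with_seed(5, b <- dinuc_shuffle(s))
  expect_identical(a, b)
  expect_identical(dinuc_shuffle("AAAAAA"), "AAAAAA")
})

test_that("motif-vs-shuffle scoring behaves at the degenerate corners", {
  m <- uniform_model(context = 64L)
  seq <- paste0(strrep("C", 10), strrep("A", 8), strrep("G", 10))
  withr::with_seed(6, {
    res0 <- motif_vs_shuffle_score(m, seq, span = c(10L, 18L), n_shuffles = 0L)
  })
  expect_length(res0$replicates, 0)
  expect_true(is.na(res0$exceedance))
  # homopolymer span: shuffles identical, strict inequality never satisfied
  withr::with_seed(7, {
    res <- motif_vs_shuffle_score(m, seq, span = c(10L, 18L), n_shuffles = 5L)
  })
  expect_equal(res$exceedance, 0)
})

test_that("a context-sensitive model prefers its motif over span shuffles", {
  withr::with_seed(8, {
    ctx <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  })
  motif <- "TGACTCAG"
  seq <- paste0(substr(ctx, 1, 20), motif, substr(ctx, 29, 50))
  span <- c(20L, 28L)
  m <- motif_context_model(span, encode_tokens(motif), context = 64L)
  withr::with_seed(9, {
    res <- motif_vs_shuffle_score(m, seq, span, n_shuffles = 10L)
  })
  expect_gt(res$observed, mean(res$replicates))
  expect_gt(res$exceedance, 0.5)
})

test_that("dependency maps vanish for position-independent models", {
  withr::with_seed(10, {
    pm <- matrix(runif(30 * 4, 0.1, 1), 30, 4)
    pm <- pm / rowSums(pm)
  })
  m <- fixed_model(pm, context = 32L)
  seq <- paste(rep(c("A", "C", "G"), 10), collapse = "")
  e <- dependency_map(m, seq)
  expect_true(all(e == 0))
})

test_that("a deterministic copy dependency produces a large signed entry", {
  m <- copy_model(i_src = 4L, j_dep = 12L, p_hi = 0.97, context = 32L)
  seq <- strrep("A", 20)
  e <- dependency_map(m, seq)
  expect_gt(abs(e[4, 12]), 5)
  expect_equal(unname(diag(unclass(e))), rep(0, 20))
  # no other source position influences anything
  expect_true(all(abs(e[-4, ]) == 0))
})
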