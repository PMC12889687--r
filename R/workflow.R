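# Reproducible workflows: dispatching commands, run manifests, and the
# end-to-end tiny-scale demonstration used by the acceptance tooling.

file_digest <- function(path) {
  if (!file.exists(path)) return(NA_character_)
  rlang::hash(readBin(path, "raw", file.size(path)))
}

write_manifest <- function(out_dir, command, config, seed, outputs) {
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    tool_version = as.character(utils::packageVersion("motiflm")),
    started = attr(outputs, "started") %||% NA,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = lapply(outputs, function(p) list(path = p, digest = file_digest(p)))
  )
  path <- file.path(out_dir, "run_manifest.json")
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  file.rename(tmp, path) # atomic publish
  invisible(path)
}

#' Run a named workflow
#'
#' Dispatches to the package's pipelines with a validated config list and
#' writes a run manifest (resolved config, seed, output digests, tool
#' version, timestamps) into `out_dir`.
#'
#' @param command One of `simulate`, `corpus`, `train`, `reconstruct`,
#'   `score`, `generate`, `demo`.
#' @param config Named list of command arguments (see details in the CLI
#'   help); unknown fields raise an error naming them.
#' @param out_dir Output directory (created).
#' @param seed Integer seed for every random draw in the run.
#' @return Invisibly, a list with the command outputs and `manifest` path.
#' @export
run_workflow <- function(command, config = list(), out_dir = "motiflm_run",
                         seed = 1L) {
  commands <- c("simulate", "corpus", "train", "reconstruct", "score",
                "generate", "demo")
  if (!command %in% commands) {
    rlang::abort(sprintf("unknown command '%s'; expected one of %s",
                         command, paste(commands, collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  outputs <- switch(command,
    simulate = wf_simulate(config, out_dir, seed),
    corpus = wf_corpus(config, out_dir),
    train = wf_train(config, out_dir, seed),
    reconstruct = wf_reconstruct(config, out_dir),
    score = wf_score(config, out_dir),
    generate = wf_generate(config, out_dir, seed),
    demo = {
      rep <- end_to_end_demo(seed = seed, out_dir = out_dir)
      list(report = file.path(out_dir, "demo_report.json"))
    }
  )
  attr(outputs, "started") <- started
  manifest <- write_manifest(out_dir, command, config, seed, outputs)
  invisible(list(outputs = outputs, manifest = manifest))
}

need <- function(config, field, default = NULL) {
  if (!is.null(config[[field]])) return(config[[field]])
  if (!is.null(default)) return(default)
  rlang::abort(sprintf("missing required config field '%s'", field))
}

wf_simulate <- function(config, out_dir, seed) {
  spec <- synthetic_corpus_spec(
    n_sequences = need(config, "n_sequences", 1000L),
    length = need(config, "length", 350L),
    motifs_per_seq = need(config, "motifs_per_seq", 2),
    repeat_rate = need(config, "repeat_rate", 0.1)
  )
  gen <- generate_corpus(spec, seed = seed)
  vars <- make_variant_set(gen$corpus, gen$annotations, spec,
                           n_per_class = need(config, "n_per_class", c(50L, 50L)),
                           seed = seed)
  paths <- list(
    fasta = file.path(out_dir, "corpus.fa"),
    manifest_tsv = file.path(out_dir, "corpus.tsv"),
    bed = file.path(out_dir, "planted.bed"),
    variants = file.path(out_dir, "variants.tsv"),
    motifs = file.path(out_dir, "motifs.meme")
  )
  # plain sequence ids so the FASTA joins directly against the variant table
  write_fasta(setNames(gen$corpus$seq, gen$corpus$chrom), paths$fasta)
  readr::write_tsv(dplyr::select(gen$corpus, "chrom", "start", "end", "split"),
                   paths$manifest_tsv)
  readr::write_tsv(gen$annotations, paths$bed, col_names = FALSE)
  write_variants_tsv(vars, paths$variants)
  write_meme(spec$motifs, paths$motifs)
  paths
}

wf_corpus <- function(config, out_dir) {
  genome <- genome_source(need(config, "fasta"))
  corpus <- load_windows(need(config, "bed"), genome,
                         window = need(config, "window", 350L))
  paths <- list(fasta = file.path(out_dir, "windows.fa"),
                manifest_tsv = file.path(out_dir, "windows.tsv"))
  write_corpus(corpus, paths$fasta, paths$manifest_tsv)
  paths
}

wf_train <- function(config, out_dir, seed) {
  corpus <- read_corpus(need(config, "fasta"), need(config, "manifest"))
  model <- train_model(
    corpus,
    model_config = model_config(need(config, "preset", "tiny")),
    training_config = training_config(
      learning_rate = need(config, "learning_rate", 1e-3),
      epochs = need(config, "epochs", 4L),
      batch_size = need(config, "batch_size", 16L),
      no_prior = isTRUE(config$no_prior)
    ),
    seed = seed, quiet = TRUE
  )
  ckpt <- file.path(out_dir, "checkpoint")
  save_checkpoint(model, ckpt)
  readr::write_tsv(tidy(model), file.path(out_dir, "metrics.tsv"))
  list(checkpoint = file.path(ckpt, "weights.rds"),
       config_json = file.path(ckpt, "config.json"),
       metrics = file.path(out_dir, "metrics.tsv"))
}

wf_reconstruct <- function(config, out_dir) {
  model <- load_checkpoint(need(config, "checkpoint"))
  seqs <- genome_source(need(config, "fasta"))$seqs
  paths <- list()
  for (nm in names(seqs)) {
    prof <- reconstruct_likelihoods(model, seqs[[nm]])
    p <- file.path(out_dir, sprintf("%s_pnorm.tsv", nm))
    readr::write_tsv(as_tibble(prof), p)
    paths[[nm]] <- p
  }
  paths
}

wf_score <- function(config, out_dir) {
  model <- load_checkpoint(need(config, "checkpoint"))
  genome <- genome_source(need(config, "fasta"))
  vpath <- need(config, "variants")
  variants <- if (grepl("\\.vcf$", vpath)) read_variants_vcf(vpath) else read_variants_tsv(vpath)
  scores <- zero_shot_llr(model, genome, variants)
  paths <- list(scores = file.path(out_dir, "scores.tsv"),
                report = file.path(out_dir, "eval_report.json"))
  readr::write_tsv(scores, paths$scores)
  if (all(c("effect_size", "significant") %in% names(scores))) {
    jsonlite::write_json(as.list(evaluate_variant_scores(scores)), paths$report,
                         auto_unbox = TRUE, digits = NA)
  }
  paths
}

wf_generate <- function(config, out_dir, seed) {
  model <- load_checkpoint(need(config, "checkpoint"))
  seeds <- genome_source(need(config, "seed_fasta"))$seqs
  set.seed(seed)
  motifs <- default_motifs()
  obj <- objective_pwm(motifs[[need(config, "motif", names(motifs)[1])]])
  res <- targeted_design(
    model, seeds[[1]], obj,
    design = design_config(n_steps = need(config, "n_steps", 10L),
                           k = need(config, "k", 5L)),
    generation = generation_config(n_iter = need(config, "n_iter", 2L),
                                   p_mask = need(config, "p_mask", 0.1),
                                   temperature = need(config, "temperature", 1))
  )
  paths <- list(fasta = file.path(out_dir, "designed.fa"),
                trajectory = file.path(out_dir, "trajectory.tsv"))
  write_fasta(setNames(res$pool$seq, sprintf("design_%02d", res$pool$rank)), paths$fasta)
  readr::write_tsv(res$trajectory, paths$trajectory)
  paths
}

#' End-to-end tiny-scale demonstration
#'
#' Simulates a motif-planted corpus, trains the tiny preset with and without
#' the Fourier prior at matched seeds and step counts, reconstructs
#' likelihood profiles on held-out sequences, computes dependency contrasts,
#' scores the synthetic variant set, and runs a PWM-guided design — then
#' writes a single JSON report of every summary quantity. Two runs with the
#' same seed produce identical reports.
#'
#' @param seed Integer seed.
#' @param out_dir Directory for the JSON report.
#' @param n_sequences,epochs,n_eval_seqs,n_variants_per_class Problem sizes.
#' @param quiet Passed to [train_model()].
#' @return The report as a named list (invisibly written to
#'   `demo_report.json`).
#' @export
end_to_end_demo <- function(seed = 1L, out_dir = NULL,
                            n_sequences = 600L, epochs = 2L,
                            n_eval_seqs = 8L, n_variants_per_class = 40L,
                            quiet = TRUE) {
  spec <- synthetic_corpus_spec(n_sequences = n_sequences)
  gen <- generate_corpus(spec, seed = seed)
  variants <- make_variant_set(gen$corpus, gen$annotations, spec,
                               n_per_class = rep(n_variants_per_class, 2),
                               seed = seed + 1L)
  tconf <- training_config(learning_rate = 3e-3, epochs = epochs,
                           batch_size = 16L, patience = epochs)
  tconf_np <- training_config(learning_rate = 3e-3, epochs = epochs,
                              batch_size = 16L, patience = epochs,
                              no_prior = TRUE)
  with_prior <- train_model(gen$corpus, model_config("tiny"), tconf,
                            seed = seed, quiet = quiet)
  no_prior <- train_model(gen$corpus, model_config("tiny"), tconf_np,
                          seed = seed, quiet = quiet)

  eval_rows <- pick_eval_sequences(gen, n_eval_seqs, seed)
  summ <- function(model) {
    profile_motif_summary(model, gen$corpus, gen$annotations, eval_rows)
  }
  s_wp <- summ(with_prior)
  s_np <- summ(no_prior)

  genome <- genome_source(setNames(gen$corpus$seq, gen$corpus$chrom))
  scores <- zero_shot_llr(with_prior, genome, variants)
  report_cls <- scores |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(mean_score = mean(.data$score, na.rm = TRUE))
  ev <- evaluate_variant_scores(
    dplyr::mutate(scores, significant = .data$class == "motif_disrupting")
  )

  set.seed(seed + 2L)
  dep_seq <- gen$corpus$seq[eval_rows[1]]
  dep_spans <- dplyr::filter(gen$annotations,
                             .data$seq_id == gen$corpus$chrom[eval_rows[1]])
  dep <- if (nrow(dep_spans) > 0) {
    dependency_contrast(dependency_map(with_prior, dep_seq), dep_spans)
  } else {
    tibble(within_motif = NA_real_, background = NA_real_)
  }

  set.seed(seed + 3L)
  motif <- default_motifs()$ap1_like
  seed_seq <- paste(sample(BASES, 350, replace = TRUE, prob = spec$background),
                    collapse = "")
  des <- targeted_design(with_prior, seed_seq, objective_pwm(motif),
                         design = design_config(n_steps = 6L, k = 4L,
                                                children_per_parent = 2L),
                         generation = generation_config(n_iter = 2L, p_mask = 0.1))

  report <- list(
    seed = seed,
    n_sequences = n_sequences,
    epochs = epochs,
    mean_pnorm_motif_with_prior = s_wp$mean_pnorm_motif,
    mean_pnorm_background_with_prior = s_wp$mean_pnorm_background,
    mean_pnorm_motif_no_prior = s_np$mean_pnorm_motif,
    mean_pnorm_background_no_prior = s_np$mean_pnorm_background,
    inband_fraction_with_prior = s_wp$inband_fraction,
    inband_fraction_no_prior = s_np$inband_fraction,
    variant_auroc = ev$auroc,
    mean_llr_motif_disrupting = report_cls$mean_score[report_cls$class == "motif_disrupting"],
    mean_llr_background = report_cls$mean_score[report_cls$class == "background"],
    dependency_within_motif = dep$within_motif,
    dependency_background = dep$background,
    design_seed_score = des$seed_score,
    design_best_score = max(des$pool$score)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "demo_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  report
}

# Deterministically pick evaluation sequences that carry planted motifs,
# preferring the validation split.
pick_eval_sequences <- function(gen, n, seed) {
  with_motif <- gen$corpus$chrom %in% gen$annotations$seq_id
  pref <- which(with_motif & gen$corpus$split == "val")
  extra <- which(with_motif & gen$corpus$split != "val")
  head(c(pref, extra), n)
}

# Reconstruction summaries over a set of corpus rows: mean p_norm inside
# planted spans vs background, and the mean in-band spectral fraction of the
# original-base probability profile.
profile_motif_summary <- function(model, corpus, annotations, rows,
                                  prior_config = fourier_prior_config()) {
  motif_vals <- c()
  bg_vals <- c()
  inband <- c()
  for (i in rows) {
    seq <- corpus$seq[i]
    prof <- reconstruct_likelihoods(model, seq)
    spans <- annotations[annotations$seq_id == corpus$chrom[i], ]
    in_motif <- rep(FALSE, nchar(seq))
    for (r in seq_len(nrow(spans))) {
      in_motif[(spans$start[r] + 1L):spans$end[r]] <- TRUE
    }
    motif_vals <- c(motif_vals, prof$p_norm[in_motif])
    bg_vals <- c(bg_vals, prof$p_norm[!in_motif])
    profile <- reference_probability_profile(attr(prof, "probs"),
                                             encode_tokens(seq))
    inband <- c(inband, inband_spectral_fraction(profile, prior_config))
  }
  list(
    mean_pnorm_motif = mean(motif_vals, na.rm = TRUE),
    mean_pnorm_background = mean(bg_vals, na.rm = TRUE),
    inband_fraction = mean(inband)
  )
}
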