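# motiflm

Short-context masked language models of regulatory DNA with a motif-scale
frequency-domain prior, plus the zero-shot analysis and design toolkit that
goes with them.

## The problem

Cis-regulatory elements act through short (6–20 bp) transcription-factor
binding motifs scattered sparsely through sequence dominated by base
composition and repeats. Generic genome-wide language models tend to learn
that background and miss the motif-scale syntax that actually matters for
regulatory function, variant interpretation, and sequence design. `motiflm`
trains a 350 bp masked language model on regulatory-element windows and adds
a frequency-domain regularizer that pushes the model's per-base likelihood
landscape toward motif-scale structure.

## The objective

For a length-L sequence, the model's predicted probability of the original
base at every position forms a profile `p`. Its non-DC magnitude spectrum is
L1-normalized into `a`, and weighted by a plateau over the motif band with
hyperbolic shoulders (smoothing s):

    C_H = L/6,  C_L = L/20
    w_i = 1                        for C_L <= i <= C_H
    w_i = 1/(1 + (C_L - i)/s)      for i < C_L
    w_i = 1/(1 + (i - C_H)/s)      for i > C_H

    L_att   = 1 - sum_i w_i a_i
    L_total = L_MLM + lambda * L_att      (lambda = 0.002, s = 5)

`L_att` is 0 when all spectral mass sits at motif-scale frequencies and near
1 for flat or out-of-band landscapes. Masked-LM training (15% of tokens;
80/10/10 mask/mutate/keep) excludes N bases and soft-masked repeat runs of
at least 30 bp.

On top of the trained model the package provides per-position likelihood
reconstruction (`p_norm = p / p_bar_nuc`), contribution tracks for
seqlet-based motif discovery, nucleotide dependency maps, zero-shot variant
scoring by masked log-likelihood ratio `s = log p(alt)/p(ref)`, per-base
embeddings with chunked tiling for long inputs (e.g. 2,114 bp), and
oracle-guided beam-search sequence design.

## Worked example

Everything below runs on the synthetic motif-planted corpus generator, so it
needs no downloads and finishes in a few minutes on one CPU.

```r
library(motiflm)

spec <- synthetic_corpus_spec(n_sequences = 600)
gen  <- generate_corpus(spec, seed = 1)
vars <- make_variant_set(gen$corpus, gen$annotations, spec,
                         n_per_class = c(40, 40), seed = 2)

model <- train_model(
  gen$corpus, model_config("tiny"),
  training_config(learning_rate = 1e-3, epochs = 2, batch_size = 16),
  seed = 1, quiet = TRUE
)

prof <- reconstruct_likelihoods(model, gen$corpus$seq[1])
autoplot(prof, spans = subset(gen$annotations, seq_id == gen$corpus$chrom[1]))

genome <- genome_source(setNames(gen$corpus$seq, gen$corpus$chrom))
scores <- zero_shot_llr(model, genome, vars)
evaluate_variant_scores(
  dplyr::mutate(scores, significant = class == "motif_disrupting")
)
#> # A tibble: 1 x 6
#>   pearson spearman auroc n_significant n_total n_missing
#>     <dbl>    <dbl> <dbl>         <int>   <int>     <int>
#> 1   0.131   0.0841 0.747            40      80         0
```

The same pipeline, with the prior ablation and a design run, is wrapped in
one call:

```r
report <- end_to_end_demo(seed = 1)
str(report[c("inband_fraction_with_prior", "inband_fraction_no_prior",
             "variant_auroc", "design_seed_score", "design_best_score")])
```

which on this seed prints

```
List of 5
 $ inband_fraction_with_prior: num 0.231
 $ inband_fraction_no_prior  : num 0.231
 $ variant_auroc             : num 0.756
 $ design_seed_score         : num 1.29
 $ design_best_score         : num 7.88
```

— at this demo scale, |LLR| separates motif-disrupting from background
variants above chance, and the PWM-guided beam search lifts the design
objective from 1.29 to 7.88. The two in-band spectral fractions are
indistinguishable here: at the published prior weight (lambda = 0.002) the
regularizer's gradient is about 4e-5 of the MLM gradient, so its imprint
sits below seed-to-seed noise at desk-scale step counts — see the methods
vignette's discussion of what short training can and cannot show.

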