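---
title: "Masked DNA language modeling with a motif-scale Fourier prior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masked DNA language modeling with a motif-scale Fourier prior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Regulatory DNA — promoters, enhancers, and other cis-regulatory elements —
acts through short (6–20 bp) transcription-factor binding motifs embedded in
a background that is dominated by composition and repeats. A self-supervised
language model trained on such sequence tends to spend its capacity on
background statistics: base composition is everywhere, repeats are learned at
high confidence, and the sparse motif-scale signal is easy to ignore.
`motiflm` implements a short-context (350 bp) masked language model of
regulatory DNA whose training objective is explicitly biased toward
motif-scale structure, together with the zero-shot analyses that make such a
model useful: per-position likelihood reconstruction, nucleotide dependency
maps, log-likelihood-ratio variant scoring, per-base embeddings for
sequence-to-function models, and oracle-guided sequence design.

## Model

The model is a pre-LayerNorm transformer encoder over single-nucleotide
tokens A, C, G, T, N and MASK. The full-scale configuration has 8 blocks,
embedding size 768, 8 heads, feed-forward width 3072 and a 350 bp context;
rotary position embeddings (base 10,000) inject relative positional
information into the queries and keys of every attention layer. The language
modeling head is a linear layer to the embedding width, GeLU, LayerNorm, and
a final linear layer to 4 logits (A, C, G, T). The N-token embedding is
pinned at zero and never updated; N positions participate in attention but
never in the loss. A `tiny` preset (2 blocks, width 64, 4 heads,
feed-forward 128) is the desk-scale configuration used by the tests, the
demo workflow and this vignette.

Decisions the architecture description leaves open, resolved here once:
pre-LN block layout with a final LayerNorm before the head (the stable
modern default); GeLU in its tanh approximation; linear weights initialized
N(0, 1/d) — the 1/sqrt(d) scaling keeps attention logits O(1) at every model
width, where a fixed 0.02 would be far too small at width 64; no weight
tying. The forward and backward passes are hand-written single-precision
RcppArmadillo; all stochastic choices (masking, augmentation, sampling) are
made on the R side under R's RNG, so every compiled computation is
deterministic and every run is reproducible from one seed.

## Objective

Training uses standard masked language modeling: 15% of eligible tokens are
selected per sequence (Bernoulli per position), of which 80% are replaced by
MASK, 10% by a uniformly chosen different base, and 10% left unchanged; the
loss is the mean negative log-probability of the original base over all
selected positions. Eligible positions exclude N and the interiors of
soft-masked (lowercase) repeat runs of at least 30 bp, annotated from the
reference genome's case. The ablation variant (`no_prior = TRUE`) drops
*every* lowercase base from the loss, not just long runs.

The motif-discovery regularizer works in the frequency domain. Let `p` be
the length-L profile of predicted probabilities of the original base (from
the same masked forward pass; N positions filled with the mean of the
others). Its discrete Fourier transform is taken, magnitudes at positive
frequencies 1..L/2 (DC excluded) are L1-normalized into `a`, and each index
receives a weight

```
w_i = 1                       C_L <= i <= C_H
w_i = 1 / (1 + (C_L - i)/s)   i < C_L
w_i = 1 / (1 + (i - C_H)/s)   i > C_H
```

with real-valued cutoffs `C_H = L/6` and `C_L = L/20` — the index band in
which 6–20 bp features concentrate their spectral mass — and smoothing
`s = 5`. The prior loss is `L_att = 1 - sum(w * a)`, which is 0 when all
spectral mass is in-band and approaches 1 for flat or out-of-band profiles.
The combined objective is `L_total = L_MLM + lambda * L_att` with
`lambda = 0.002`. An `eps = 1e-8` floor in the L1 normalization makes a
zero non-DC spectrum (a perfectly flat profile) score `L_att ~ 1`,
deliberately penalizing uninformative landscapes. The analytic gradient of
`L_att` through the DFT is implemented in both the R diagnostics and the
compiled training path and is checked against finite differences in the
test suite.

Two readings of the published weight formulas are possible because of
typesetting; we read the shoulders as `1/(1 + (C_L - i)/s)` and
`1/(1 + (i - C_H)/s)`, which match the printed example values (w(175) ≈
0.0411, w(1) ≈ 0.2326 at L = 350, s = 5). Whether the profile feeding the
prior should come from the masked pass or a second unmasked pass is also
unstated; we use the masked pass, which costs nothing extra and couples the
prior to the very probabilities the MLM loss shapes.

## Training

The optimizer is Adam at the stated learning rate (1e-4 at full scale; the
desk-scale workflows use 1e-3–3e-3, chosen in pilot runs as the largest
stable rate for the tiny preset), gradient-norm clipping at 5, constant
schedule, no weight decay. Augmentation per epoch: reverse complement with
probability 0.5, and — when a backing genome is available so the window can
be re-extracted — a uniform shift in [-50, +50] bp, clamped at chromosome
edges. Standalone corpora (synthetic fixtures) only reverse-complement.
Validation MLM loss is computed each epoch under a masking stream that is
fixed across epochs (so values are comparable), and the best-validation
weights are retained with early-stopping patience 10.

Corpus windows are built from BED intervals (0-based half-open, the BED
convention) over a case-preserving FASTA: intervals shorter than 350 bp are
expanded symmetrically about their midpoint with the odd base going 3',
longer ones center-cropped; windows that would cross a chromosome edge are
slid inside when possible, otherwise skipped with a warning. Chromosome
splits follow the published held-out sets (validation: 6 and 21; test: 5,
10, 14, 18, 20, 22; everything else trains).

## Synthetic fixtures: what they emulate and what they do not

`generate_corpus()` plants PWM-sampled motif instances (defaults: four
hand-specified PWMs of widths 6, 8, 10, 12, one dominant base per column
with probabilities cycling 0.96/0.90/0.94/0.92 — information content ≈ 1.5
bits/column on average, with strong and weaker columns as in real binding
sites) sparsely and without overlap
on i.i.d. background (A/T 0.29, C/G 0.21, roughly genomic GC), on a uniform
strand, at a Poisson-distributed count per sequence (mean 3, capped at 5);
10% of sequences receive one lowercase repeat run of 30–60 bp placed clear
of motifs. `make_variant_set()` derives motif-disrupting variants by
substituting, at the most informative consensus-matching column of a planted
instance, the column's lowest-probability base — each candidate is verified
to strictly lower the sequence's best PWM score — with effect size
`log(p_alt/p_ref)` from the PWM column, flagged significant; background
variants fall outside all planted spans with small zero-centered effects.

These fixtures make every downstream stage testable without downloads, but
they are not chromatin: no dinucleotide or higher-order background
structure, no motif grammar (spacing, orientation, co-occurrence), no
cell-type heterogeneity, and repeat runs are random lowercase stretches
rather than transposon copies. Passing the tiny-scale tests therefore
demonstrates that the machinery — objective, gradients, reconstruction,
scoring, design — behaves as specified, not that the tiny model would
recover real regulatory syntax; that requires full-scale pretraining on a
real regulatory-element corpus, which the code supports but the package
does not validate.

## Zero-shot analyses

*Likelihood reconstruction* masks each position in turn (L forward passes,
batched; results invariant to batch size) and normalizes the probability of
the observed base by that base's mean predicted probability across all
non-N positions: `p_norm = p / p_bar_nuc`. The alternative reading of the
normalizer (averaging only over positions whose observed base is the
nucleotide in question) changes little in practice; we use the sequence-wide
mean of the predicted probability, which is well-defined even for bases that
never occur. Contribution tracks for seqlet-based motif discovery carry
`log(p_norm)` on the observed base's channel (optionally a hypothetical
all-base track `log(p/p_bar)`), written as TSV alongside the one-hot
sequence.

*Dependency maps* use no masking: one reference pass plus three passes per
position substituting each alternate base; for each source i and target j
the entry is the signed log2 odds ratio of maximal magnitude over the 3
alternates and 4 target bases, probabilities clamped to [1e-6, 1-1e-6],
diagonal fixed at 0. The published formula fixes only that the substituted
base differs from the reference; maximizing over the alternates as well as
the target base is our resolution, and we keep the signed value rather than
the absolute.

*Motif-vs-shuffle scoring* dinucleotide-shuffles only the motif span
(context fixed) with an Eulerian-path shuffle that preserves exact
dinucleotide counts, recomputes the reconstruction, and reports the fraction
of replicates the observed span strictly beats.

## Variant scoring and evaluation

The zero-shot score masks the variant position at the center of a 350 bp
window and returns `s = log(p(alt)/p(ref))` (natural log; recorded in
output headers — rank metrics are base-invariant). Variants whose stated
reference allele disagrees with the genome are flagged and withheld rather
than silently auto-swapped. Supervised-style scoring wraps any
strictly-positive oracle `g` over a longer window (2,114 bp by default) as
`log2(g(S_alt)/g(S_ref))`. Evaluation computes Pearson and Spearman
correlations against observed effect sizes on the significant subset only,
and AUROC separating significant from non-significant variants using
|score| — magnitude carries effect strength, sign carries direction.

## Embeddings for long inputs

Per-base embeddings average the outputs of the last `min(6, n_blocks)`
transformer blocks. Inputs longer than the context are tiled: when the
length M is an exact multiple of 350 the chunks tile directly; otherwise a
central chunk is placed symmetrically about the midpoint (ties 5'), full
chunks tile outward, and the uncovered ends take their rows from embeddings
of the first/last 350 bp. For M = 2,114 this yields 5 full chunks covering
[182, 1932) with edge fills from [0, 350) and [1764, 2114); every position
is covered exactly once, a property the tests assert for arbitrary M.

## Generation and design

Untargeted generation repeats `N_i` times: mask each token independently
with probability `p_m`, recompute probabilities with temperature-scaled
logits, and resample only the masked positions (N positions are never
touched). Targeted design wraps this in a beam search: each pool member
spawns `children_per_parent` candidates (default 4; unspecified in the
source description), parents compete with children at retention of the top
`k`, so the best score never decreases — a property asserted on every run.
Ties at the retention boundary break by earlier insertion, keeping runs
deterministic for a fixed seed. For oracle windows longer than the model
context, the seed's flanks are frozen and only the central 350 bp are
edited, with the full window passed to the objective. Built-in objectives
cover best-hit PWM log-odds, |prediction - target| minimization against a
single oracle, and a weighted two-oracle differential for cell-type
specificity designs.

## Numerical choices and problem sizes

The compiled core is float32 (adequate for network training; the test suite
compares it against a float64 R reference implementation at 1e-4). The DFT
inside the training loss uses precomputed cosine/sine tables; the R-side
diagnostics use `stats::fft`. Probabilities are floored at 1e-12 inside
log-losses; odds are clamped before ratios; PWM cells are floored at 0.01.

The test-suite study sizes are chosen for a single CPU: the learnability
checks train the tiny preset on a 2,000-sequence synthetic corpus for 2
epochs across 5 seeds (with and without the prior at matched seeds and step
counts), reconstruct likelihoods on a handful of motif-bearing sequences,
and score an 80-variant synthetic set. The `end_to_end_demo()` workflow
reproduces the same pipeline at a configurable scale and writes every
summary quantity to a JSON report; `scripts/acceptance.R` is a thin
deterministic driver around it.

What such short training can and cannot show deserves honesty. In the first
few thousand optimizer steps a masked language model spends its capacity on
the easy wins — base composition, per-sequence composition fluctuations,
and the "copy" solution for the mutated/unchanged loss positions — and
motif-conditional prediction at masked positions emerges only afterwards
(reliably so when a single strong motif is planted densely; slowly and
seed-dependently for a diverse sparse motif set). The desk-scale checks
therefore test *directions* (motif-span likelihood above background;
in-band spectral mass higher with the prior), not effect sizes. The prior
itself is a gentle regularizer by construction: at the default weight
`lambda = 0.002` its full-parameter gradient is orders of magnitude smaller
than the masked-LM gradient, so its imprint on a run of a few thousand
steps sits near or below float32 measurement noise; its intended effect is
cumulative over full-scale pretraining. These are properties of the scale,
not switches to tune around: the desk-scale suite validates the machinery,
and full-scale runs are where the biology is decided.

## Known limitations

The model is cell-type agnostic and strictly local (350 bp): enhancer–
promoter coupling and other long-range structure are out of reach by
construction. Sequence-only self-supervision is bounded by motif frequency
in the training distribution; rare but functional motifs may never be
learned. The frequency-domain prior biases *profiles*, not attention or
parameters — a model can in principle satisfy it with in-band oscillations
that are not motifs, which is why the synthetic tests check motif-aligned
contrasts rather than the loss value alone. Design results are purely in
silico and inherit every bias of the supplied oracle.
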