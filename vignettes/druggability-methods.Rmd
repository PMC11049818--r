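---
title: "Methods: sequence-based druggable-protein classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-based druggable-protein classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugseqr)
```

## The problem

Most approved small-molecule drugs act on a few thousand human proteins; the
great majority of the proteome has never been drugged, and deciding which
unstudied proteins are worth pursuing is expensive. `drugseqr` treats
druggability as a binary sequence-classification problem: given only an
amino-acid sequence (label 1 = druggable, 0 = undruggable), predict whether
the protein can bind a small-molecule modulator. The package implements two
complementary feature channels, four classical baselines, three deep
classifiers, an end-to-end decoder transformer, and the full evaluation
protocol, all testable offline through a deterministic synthetic benchmark.

## Feature representations

### Evolutionary-profile features (1200-D)

Each protein is described by an L x 20 position-specific scoring matrix
(PSSM) of integer log-odds scores \(p_{k,i}\), produced externally by
iterative homology search (the documented recipe is PSI-BLAST against
SWISS-PROT, three iterations, E-value cutoff 0.001; the package parses the
ASCII profile format but never runs the search). Three 400-dimensional
encoders summarize the profile:

* **Dipeptide composition** over profile space:
  \(y_{i,j} = \frac{1}{L-1}\sum_{k=1}^{L-1} p_{k,i}\,p_{k+1,j}\).
* **k-separated bigrams** (k = 3 by default), the same product taken between
  positions k apart: \(y^k_{i,j} = \sum_{t=1}^{L-k} p_{t,i}\,p_{t+k,j}\).
  This block is deliberately left unnormalized, matching the printed form of
  the descriptor; a `normalize` flag divides by \(L-k\) for users who want
  length-invariant values.
* **Filtered row sums**: negative scores are clipped to zero and column sums
  are accumulated per residue type,
  \(Y_j(i) = \sum_k \max(p_{k,j},0)\,[r_k = a_i]\).

The three blocks concatenate, in that order, to a 1200-D vector. Design
points worth noting: scores are used raw (log-odds integers) because the
defining equations apply \(p\) directly — a sigmoid-normalization flag
exists but defaults to off; the row index \(i\) follows the profile header's
column order, not alphabetical order, so features are reproducible across
files; no upper cap is applied to the filtered scores (some descriptor
lineages cap at 7 — only negative filtering is specified here); and a
record whose profile is missing featurizes as all zeros with a warning
rather than failing a batch.

### Protein-language-model embeddings (320-D)

The embedder contract is backend-pluggable: a backend maps a sequence to
per-residue representations, a pooled per-protein vector and an L x L
contact map. The intended production backend is the 6-layer, 320-dimensional
member of a pretrained protein-language-model family (representations read
from layer 6, its final layer); weights are supplied externally and are
never downloaded by the package. For offline development and testing a
`stub` backend provides deterministic random-feature encodings: a token
table and a bigram table drawn once per seed, so the residue representation
at position t depends on the residue and its predecessor. Pooling is the
arithmetic mean over residue rows (special tokens excluded) — the pooling
operator is not fixed by the architecture, and mean pooling is the community
convention. Because the stub sees bigrams, local motifs remain visible after
pooling, which is what makes the stub path separable on the synthetic
benchmark.

Contact maps are symmetrized as \((M + M^\top)/2\) and clipped to
\([0, 1]\); the stub derives a pseudo-map from the first
`contact_head_width` (default 24, the reduced width used after fine-tuning)
embedding dimensions with a short-range decay.

### Fine-tuning harness

`finetune_plm()` appends a fully connected layer and a single sigmoid unit
on top of the pooled backbone representation and minimizes binary
cross-entropy. Records are sorted by length and batched in twos so padding
within a batch is minimal. All backbone weights train; for the stub backend
the trainable backbone is a linear transform initialized at the identity,
which makes two contracts exactly testable: with learning rate 0 fine-tuning
is a bit-exact no-op on embeddings, and after training the extracted
embeddings (read immediately before the fully connected layer) differ from
the pretrained ones. Learning rate, epochs and the hidden width are exposed
as configuration because no canonical values exist for them.

## Classifiers

Four classical baselines run behind `fit_baseline()` with reference
hyperparameters centred on a published grid search: an RBF-kernel max-margin
classifier (C = 10, scale-style gamma), a random forest (1000 trees, depth
3), Gaussian naive Bayes (variance smoothing 1e-9, emulated by flooring the
per-feature standard deviations), and gradient-boosted trees (depth 15,
learning rate 0.1, 2000 rounds, subsample 0.8, column subsample 0.7, L2 0.4,
positive-class weight 0.8, logistic objective).

The three deep classifiers and the decoder transformer are implemented from
scratch on a small tape-based reverse-mode autodiff engine (`R/autograd.R`),
since the model architectures are the package's own contribution. All four
are bit-reproducible given a seed on a single CPU thread, and every op in
the engine is covered by central-difference gradient checks during
development.

* **DNN** — three ReLU hidden layers (180, 60, 30), dropout 0.5 after each,
  one sigmoid output, BCE loss, Adam at 0.001, batches of 10. On a 320-D
  input this is exactly 70,501 trainable parameters, which the tests verify
  against the closed form.
* **CapsNet** — a 1-D convolution (kernel 3, stride 1, no pooling anywhere)
  over the feature vector yields one 8-D primary capsule per position after
  the squashing nonlinearity \(v = \frac{\lVert s\rVert^2}{1+\lVert
  s\rVert^2}\frac{s}{\lVert s\rVert}\); per-capsule linear votes feed two
  16-D class capsules through three iterations of routing-by-agreement, and
  the class-capsule norms act as per-class probabilities trained with BCE
  against the one-hot target. Capsule dimensions and channel counts are not
  canonical for sequence input; the defaults (8-D primary, 16-D class, 2
  class capsules, 3 iterations) are the standard capsule-network settings
  and live in `capsnet_config()`. Gradients flow through the unrolled
  routing loop.
* **BiLSTM** — one bidirectional LSTM layer (input 320, hidden 64 per
  direction, so a 128-wide concatenated state), a 2-unit output, batches of
  16, Adam at 0.001. BCE is applied to the softmax probability of the
  positive class, reconciling a two-logit head with a binary loss. A flat
  feature vector is framed as a single time step by default; `n_steps` folds
  it into a genuine sequence when desired.
* **Modified decoder transformer** — a compact GPT-style classifier over the
  33-token protein alphabet (20 standard residues, extended codes including
  X, and cls/pad/eos/unk specials, ordered as in the small pretrained
  embedding family so ids are interchangeable). Token and position
  embeddings sum; pre-norm blocks apply causal self-attention (pad keys
  masked out) and a GELU feed-forward expansion; the two-class softmax head
  reads the representation of the last non-pad token, which under a causal
  mask has seen the whole sequence. The reduced size defaults (block 512, 4
  layers, 4 heads, width 128) are configuration, not architecture: the
  published description states only that block size, heads and layers were
  reduced. Over-length sequences are C-terminally truncated (keeping cls and
  restoring eos) with a warning. There is no language-model head and no
  pretraining — the model trains from random initialization, which is the
  point of the end-to-end variant.

## Evaluation protocol

Class balancing downsamples the larger class to the smaller with a seeded
draw (704 + 704 from 704 clinically validated targets versus 5516 unstudied
proteins, seed 42). Splitting is stratified and two-stage: per class,
`floor(0.2 N)` test, then `floor(0.2 (N - test))` validation, remainder
train. Floor-at-both-stages is the unique simple rounding that reproduces
all six published per-class counts from totals 1224/1319 and 704/704; the
tests assert all six. Five-fold cross-validation is stratified with fold
sizes differing by at most one, and fold metrics aggregate as mean ± sample
standard deviation.

Six confusion-matrix metrics (ACC, precision, sensitivity, specificity, F1,
MCC) are computed exactly; MCC returns 0 with a warning when a denominator
factor vanishes (the standard convention — the defining formula is silent on
this). AUC is the Mann-Whitney pair statistic with ties counted as one half,
which the tests verify equals trapezoidal integration of the ROC polyline to
1e-9 and matches an independent reference implementation. Attribution-group
aggregation (for SHAP-style matrices, which are an *input* — the package
does not compute attributions) takes the mean absolute attribution per
feature and averages within each feature group.

## The synthetic benchmark

`fixture_spec()` defines a two-class world with two independent signal
channels so each feature family is separable by construction: positives
carry a planted motif (default `WWWWW`) at a random position in otherwise
background-composition sequences (approximate vertebrate proteome
frequencies), and every record gets a synthetic profile whose rows score
`pssm_signal` (default 7, a typical strong log-odds value) in the true
residue's column with uniform noise (default ±2) elsewhere. Defaults are 100
positives + 100 negatives of 50–120 residues, seed 7. A single master seed
drives per-record substreams keyed by record id, so outputs are independent
of generation order. Setting `motif = ""` removes the class signal entirely,
and the test suite uses that to confirm classifiers fall to chance — a guard
against label leakage anywhere in the pipeline.

What the generator does *not* emulate: realistic evolutionary profiles
(columns are independent noise, not homology-derived), realistic druggability
biology, length confounding between classes, or class imbalance. Passing
tests therefore demonstrate that the pipeline recovers signal that is
present and finds none where none exists — not that any accuracy carries
over to real proteome-scale data, which additionally requires real profiles
and pretrained weights.

## Numerical choices and problem sizes

Weights initialize Glorot-uniform (embedding tables: normal, sd 0.02); Adam
uses \(\beta = (0.9, 0.999)\), \(\varepsilon = 10^{-8}\). Squash and row-norm
gradients are stabilized with small epsilons; BCE on probabilities clips to
\([10^{-7}, 1-10^{-7}]\); attention masking adds \(-10^9\) before the
softmax. Early stopping (patience 10 on validation loss) is available on the
feature-vector models but off by default. The test and acceptance workloads
are deliberately desk-scale — overfit checks use 40 separable 24-D samples
or 20 short sequences, oracle sweeps use 200 random profiles of length up to
60, and the benchmark is 100 + 100 records — sizes chosen so the whole suite
exercises every code path in a few minutes on one CPU.

## Known limitations

* The real pretrained backend is an interface, not an implementation: only
  the stub ships, so published real-data accuracies are out of scope here.
* The capsule network processes samples one at a time through the routing
  loop; it is the slowest of the models and meant for modest sample counts.
* The transformer trains per-sequence within batches rather than on padded
  tensors; fine for the intended scale, wasteful for thousands of long
  proteins.
* Gaussian naive Bayes relies on a variance floor to survive zero-variance
  features; genuinely constant features carry no information either way.
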