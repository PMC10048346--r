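---
title: "Methods: the grid-searched multilayer dynamic cascade"
author: "methCascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the grid-searched multilayer dynamic cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

N4-methylcytosine (4mC) is a bacterial-and-eukaryotic DNA modification in
which the exocyclic amine of cytosine is methylated. Experimental mapping
(SMRT sequencing, methylation-specific PCR) is expensive, so sequence-based
predictors are standard practice: given a fixed 41-bp window with a cytosine
at its centre, decide whether that centre C is a 4mC site. The positive and
negative classes differ only in the sequence context around the same central
residue, which makes the problem a balanced binary classification of short
DNA windows.

## The model

`methCascade` implements a cascaded, grid-searched ensemble of small 1-D
convolutional networks over word-embedding features.

**Features.** Each window is tokenized into overlapping 3-mers (a length-L
sequence yields L − k + 1 tokens; 39 for L = 41, k = 3). A CBOW word2vec
model — predict a token from its flanking context — maps each 3-mer to a
100-d vector, so a window becomes a 39 × 100 real matrix. The trainer
(`trainEmbedding()`) is written in C++ with negative sampling and a
self-contained RNG: with one thread and a fixed seed the vectors are
bitwise reproducible. Defaults (vector size 100, window 5, minimum count 5,
5 negative samples, 25 epochs) are the conventional small-corpus settings
for k-mer sentences. With 64 possible 3-mers and corpora of thousands of
tokens, the vocabulary is normally complete; a token that still falls below
the minimum count maps to the all-zero vector at embedding time, preserving
tensor shape without inventing values.

By convention for this family of methods the embedding corpus is the full
input dataset (training and test windows), since word2vec is unsupervised;
`runPipeline()` exposes `embedOnTrainOnly = TRUE` for a strictly
leakage-free variant.

**Base learners.** Three fixed presets, each two unpadded stride-1
convolutions with ReLU, one dropout layer on the flattened features, a
single dense unit and a sigmoid:

| preset | conv 1 | conv 2 | dropout |
|---|---|---|---|
| M1 | 16 filters, width 3 | 32 filters, width 5 | 0.5 |
| M2 | 32 filters, width 5 | 42 filters, width 7 | 0.3 |
| M3 | 42 filters, width 7 | 64 filters, width 9 | 0.6 |

Custom architectures are restricted to the standard search space (≤ 5
layers, filters from {16, 32, 42, 64}, kernels from {3, 5, 7, 9}). Training
details left open by the architecture specification are fixed as package
defaults and recorded in the run manifest: Adam with learning rate 1e-3,
batch size 32, binary cross-entropy, He initialization, 20 epochs by
default. The forward/backward pass is implemented directly on BLAS matrix
products (im2col layout); a numerical-differentiation test pins the
gradients.

**Weighted-average ensemble.** Member probabilities are combined as
\[ p_{ens} = \frac{\sum_m w_m\, p_m}{\sum_m w_m}, \]
normalized by the weight sum so the result stays in [0, 1] and rescaling
all weights changes nothing. Weights live on the grid {0.0, 0.1, ..., 1.0}
per member (step configurable); `gridSearchWeights()` enumerates all
11³ − 1 non-zero tuples and returns the accuracy-maximizing one, ties
broken toward the lexicographically smallest tuple so the search is
deterministic.

**The dynamic cascade.** Per layer: (1) every member is re-initialized and
refitted from scratch on the current training set; (2) weights are
grid-searched; (3) the current test set is thresholded at 0.5 and
partitioned; (4) correctly classified records join the training set with
their true labels and the misclassified remainder is the next layer's test
set. The loop stops when a layer adds no correct calls (TP + TN = 0), the
test set is exhausted, or a safety cap (default 20) is reached. The
headline statistic is the cumulative total accuracy
\[ TA = \frac{\sum_i (TP_i + TN_i)}{S_{Test}}, \]
with the *initial* test-set size as denominator; records never resolved
count as errors. Because every term is non-negative, cumulative accuracy is
monotone non-decreasing, and while a layer makes progress the test set
strictly shrinks, so termination is guaranteed even without the cap.

Two properties deserve emphasis. First, the procedure inspects true test
labels both to route records and (in the default, faithful mode) to select
ensemble weights; that is the method's definition, but it means total
accuracy is *not* a held-out generalization estimate. `mode = "honest"`
selects weights on an inner validation split carved from the training set
instead (routing unchanged, as it must be). Second, the per-layer ledger
satisfies hard accounting identities — TP+TN+FP+FN equals the layer test
size, the next layer's training size is the previous plus its correct
count, the next test size is the previous FP+FN — which the test suite
asserts on every run.

## Metrics

`computeMetrics()` uses the standard confusion-matrix definitions
(accuracy, precision, recall/TPR, FPR, TNR, FNR) at full precision,
formatting only at report time; zero-denominator metrics are `NA` with a
warning, never silently 0. `rocCurveAuc()` builds the ROC over sorted
unique score thresholds and integrates by trapezoid, which equals the
pairwise concordance probability with half credit for ties; the suite
checks this equivalence against a brute-force pairwise oracle and against
pROC. Balanced accuracy `(TPR + TNR)/2` is reported separately because for
a single hard classification it coincides numerically with that AUC.

## The synthetic generator

`generateDataset()` emulates the essential geometry of 4mC benchmark data:
fixed 41-bp windows, central cytosine in *both* classes (a negative is the
same unmethylated C), balanced classes, i.i.d. background elsewhere. The
positive signal is a position-weight-matrix motif planted immediately 3' of
the centre. Defaults, chosen once as a realistic desk-scale testbed: uniform
background; width-6 motif with dominant-base probability 0.91; motif
strength 1 (fully penetrant), making strength the single separability dial —
0 yields indistinguishable classes (chance-level accuracy, verified), 1
yields near-complete separability. The motif sits beside, not over, the
centre so the centre-C invariant holds in both classes.

What the generator does *not* emulate: species-specific 4mC motif biology,
GC skew (configurable but off), positional composition gradients, sequencing
noise, or inter-record redundancy. Passing tests therefore demonstrate that
the machinery is correct and can exploit a planted positional signal — not
that any particular accuracy will transfer to real genomes.

## Numerical and design choices

- **Identity filter.** CD-HIT-style clustering is replaced by a greedy
  single-pass positional-identity filter (`redundancyFilter()`), valid
  because all records share one length. It is applied per class — whether
  redundancy removal should pool classes is genuinely open; per class is
  the conservative choice (never discards a record because its opposite
  class contains a look-alike) and is switchable via `perClass = FALSE`.
- **Round-half-up split.** Per-class test counts use round-half-up of
  (1 − trainFraction)·n, which reproduces the conventional 80:20 counts
  for the benchmark class sizes (e.g. 388 → 78).
- **Decision threshold** 0.5 on the sigmoid/ensemble probability;
  configurable.
- **Weight grid** spans the full unit interval at step 0.1 even though
  reported optima in this literature concentrate below 0.8; the grid is a
  superset and the step is configurable.
- **Seeding.** One user-facing seed fans out to per-stage and per-layer
  seeds through a fixed integer derivation; every stochastic component
  (undersampling, splitting, embedding, CNN init/shuffle/dropout) draws
  from it, so a pipeline rerun reproduces its ledger byte for byte.
- **Ties.** Grid-search ties go to the lexicographically smallest tuple;
  record order is the tie-breaker in filtering and sampling.
- **Degenerate inputs.** Empty classes, empty test sets, non-disjoint
  train/test, kernels wider than their input, all-zero weight tuples and
  single-class ROCs are all hard errors, not silent degradation.

## Problem sizes in the test suite

Unit tests run on datasets of 10–240 windows with reduced embedding
dimensions (16–24) and epochs (4), which exercise every code path in
seconds. The end-to-end cascade check uses 400 + 400 windows, the three
convolutional presets at 8 epochs, and three seeds with a majority-pass
rule, reflecting the stochasticity of CNN training; the published-ledger
reproductions are exact integer arithmetic.

## Known limitations

- Faithful mode's total accuracy is an optimistic, self-referential
  statistic by construction (see above); use honest mode plus a genuinely
  held-out evaluation for generalization claims.
- The CBOW trainer and CNN are deliberately compact re-implementations:
  single-threaded, dense, CPU-only. They are sized for 41-bp windows and
  desk-scale corpora, not genome-scale training.
- Variable-length windows and ambiguous bases are out of scope; records
  containing N are rejected at parse time.
- The AE (equal-weights) ensemble mode is provided for comparison but gets
  no special optimization.
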