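---
title: "Multi-instance convolutional classification of TCR repertoires: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-instance convolutional classification of TCR repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrmil)
```

## The problem

A cancer patient's T-cell compartment carries receptors that respond to
tumour antigens. Their CDR3β sequences — the hypervariable loop that chiefly
determines antigen specificity — can in principle betray the disease state of
the whole repertoire, but nobody knows which individual sequences are
cancer-associated. The statistical structure is multi-instance learning
(MIL): labels attach to *bags* (repertoires), not to *instances* (TCRs).
`tcrmil` implements a deep MIL classifier for this setting, together with
everything needed around it: repertoire IO and quality control, amino-acid
encodings, an evaluation protocol, and a synthetic cohort generator with
planted motifs so that the complete pipeline can be exercised and benchmarked
without any external data.

## The model

**Per-TCR scorer.** A CDR3 of length $l$ is encoded row-wise by a $20 \times
d$ amino-acid biochemical feature matrix into an $l \times d$ input and
zero-padded at the C-terminal end to $l_{\max} = 24$ rows (the QC upper
bound). A bank of convolution filters $F_j$ of height $h$ scans the rows with
stride 1:
$$ o_a^{(j)} = \mathrm{ReLU}\!\big(W_{F_j} \cdot M[a:a+h-1] + b_{F_j}\big),
   \qquad a = 1, \dots, l - h + 1 . $$
Each feature map is reduced by 1-max pooling — the best-scoring window is the
candidate motif for that filter — and the pooled values are concatenated into
a feature vector $p_i$ (14-dimensional for the default bank). A one-layer
linear classifier with a sigmoid turns it into the probability that the TCR
is cancer-associated:
$$ \tilde y_i = \sigma\!\big(W_L^\top p_i + b_L\big). $$

**Filter-bank design.** Crystallographic analyses of TCR–peptide–MHC
complexes show that the contiguous runs of CDR3 residues in direct contact
with peptide span 2–8 residues, with short runs most common. The bank
mirrors the observed run-length distribution: sizes whose occurrence
frequency falls below 0.05 are dropped (this excludes size 8 at 0.017), and
14 filter slots are apportioned to the surviving sizes by largest-remainder
allocation over the renormalized frequencies. From the published run counts
(12, 12, 13, 8, 7, 5, 1 for sizes 2–8) this yields heights 2–7 with
3, 3, 3, 2, 2, 1 filters. Largest-remainder apportionment was chosen because
it reproduces the published allocation exactly and guarantees the slot total;
plain quota rounding is available behind a switch and agrees on the default
table. Remainder ties break toward the smaller height, since shorter contact
runs were the more frequent observation.

**Bag classifier.** The top $k = 100$ clonotypes of a repertoire (by clonal
frequency, after QC and reference-set removal) are scored by the shared CNN
and the $k$ scores, ordered by abundance rank, feed a second one-layer linear
classifier:
$$ \tilde Y = \sigma\!\big(W_{L'}^\top [\tilde y_1, \dots, \tilde y_k] +
   b_{L'}\big). $$
Unlike taking the mean (which assumes all TCRs matter equally) or the max
(the standard MIL assumption — one positive instance makes the bag positive),
$W_{L'}$ learns a weight per abundance rank. The model is trained end to end
on the bag-level cross-entropy; the per-TCR cross-entropy is used when
instance labels are available (`fit_tcr_scorer()`). Both classifier layers
receive 40% dropout during training. A repertoire is called cancerous when
$\tilde Y > 0.5$, strictly.

**Loss.** Both losses are the negative Bernoulli log-likelihood
$-[y \ln \hat y + (1-y)\ln(1-\hat y)]$ with predictions clamped to
$[10^{-12}, 1-10^{-12}]$. (Some printed statements of this loss put the
prediction in both slots, which would be the entropy of the prediction
rather than a likelihood; the standard cross-entropy with the true label is
what "log-likelihood" means and is what is implemented.)

## Encodings

Two published amino-acid feature tables ship with the package: the Atchley
factors ($d = 5$, condensed from 494 property scales) and the Kidera factors
($d = 10$, from 188 scales). The widely used $20 \times 15$ PCA table
condensed from 531 AAindex scales is not printed in full anywhere we can
ship from, so it is not bundled; `derive_pca_encoding()` reproduces the
construction from any user-supplied AAindex-format table (standardize
columns over the 20 amino acids, PCA, keep the first $d$ component scores,
report explained variance). Constant columns are dropped before
standardization; entries with missing values should be dropped upstream.
Each component's sign is fixed so its largest-magnitude loading is positive,
making the result reproducible across linear-algebra backends. The package
default is Atchley ($d = 5$) because it is fully published; every downstream
component is parameterised by $d$.

## Padding and masked pooling

Zero-padding changes the input distribution: a window that overlaps padding
rows is an artefact, not a $z$-mer. The claim that such windows are
discarded by 1-max pooling holds only if their activations never win the
max. With `mask_padding = TRUE` (the default) windows overlapping padding
are excluded from pooling outright, which turns that claim into an enforced
invariant — a sequence's score is bit-identical whether it is processed at
its true length or padded to 24 (this is a tested property).
`mask_padding = FALSE` reproduces the naive behaviour for ablation.

## Preprocessing

Quality control removes CDR3s that are shorter than 10 or longer than 24
residues, contain any character outside the 20 standard one-letter codes
(X, `*`, `+`, B, Z, lowercase, ... all count), do not start with cysteine
and end with phenylalanine, or lack a resolved V-gene call. Sequences
abundant in both cancer and non-cancer training samples are collected into a
reference set (by default the top 20,000 per sample; membership requires
presence in at least one sample of *each* class) and removed everywhere
before ranking — they are shared machinery of the repertoire, not evidence.
Whether the top-20,000 ranking happens before or after QC is unspecified in
the sources; QC-first is implemented, with a flag to disable. Frequency ties
in top-$k$ selection break lexicographically so results are platform
independent. Bags with fewer than $k$ surviving clonotypes keep $W_{L'}$'s
dimension by filling the missing score slots with 0 — the natural
"no evidence" value — rather than resampling sequences.

## Training

Adam (learning rate 0.001 by default) minimizes the mean cross-entropy, full
batch up to 512 bags and shuffled mini-batches beyond; every run is fully
seeded (initialization, shuffling, dropout) and bit-reproducible. Filter
weights use Xavier/Glorot uniform initialization, which mitigates dead ReLU
units; biases start at zero. The model is trained `n_runs` times (default 5)
from different seeded initializations and the run with the highest
validation AUC is kept, ties to the lowest seed.

Three training-dynamics choices deserve explanation because the design was
genuinely open:

* **Mean-aggregator initialization of $W_{L'}$** (`aggregator_init =
  "mean"`). With symmetric random rank weights, roughly half of a bag's
  instances receive gradients of the wrong sign until the aggregator
  uniformizes, and on small cohorts the bag head — $k$ weights against a few
  dozen bags — can interpolate the training labels outright before the
  convolutional scorer learns anything. Starting at $W_{L'} = 1/k$, $b_{L'}
  = 0$ (exactly the calibrated mean aggregator, a special case the
  architecture contains) gives every instance a correct-sign gradient from
  the first epoch. Xavier initialization of the bag head remains available.

* **Aggregator warm-up** (`warmup`, default half the epochs). For the first
  `warmup * epochs` epochs the rank weights stay frozen at the mean
  aggregator — the intercept keeps training, so the frozen head remains a
  *calibrated* mean — while the scorer trains under coherent bag-level
  gradients; afterwards the rank weights are released. This is a curriculum
  on the same end-to-end objective, not a different model. Note that with
  the rank weights frozen the bag logit spread is bounded by 1, so scores
  cluster near the decision point even when ranking is essentially perfect;
  threshold-based metrics at the fixed 0.5 cut benefit from releasing the
  rank weights or from Youden-index thresholding.

* **Early stopping monitors validation AUC** (patience 50, best checkpoint
  restored), with validation loss as a tiebreak at equal AUC. Validation
  AUC is already the between-run model-selection criterion, so using it for
  checkpointing is consistent; validation loss alone is a poor monitor here
  because rank-weight memorization can keep improving calibration while
  ranking degrades.

## Evaluation

ROC curves sweep every distinct score; the trapezoid AUC of this
construction equals the Mann–Whitney pairwise statistic exactly (tested to
1e-10 against an explicit pairwise oracle). Youden's $J$ and
sensitivity-at-0.9-specificity search the midpoints between adjacent
distinct scores plus the extremes; predictions are positive strictly above
the threshold. Cross-validation is stratified and repeated: the plain scheme
rotates test and validation folds (three folds train, one selects, one
tests, matching the 3/1/1 protocol); the nested scheme selects the inner
candidate with the highest inner-validation AUC and reports the outer fold.
Aggregates are mean ± 1.96 SE over all fold evaluations (the CI formula is a
documented choice; the sources state intervals without one).

## The synthetic benchmark

`generate_cohort()` emulates the MIL structure the model assumes: each
sample holds `seqs_per_sample = 100` CDR3-like strings ("C" + i.i.d.
background residues + "F", lengths 10–24 with a unimodal peak at 15,
emulating real CDR3 length profiles) with clonal frequencies proportional
to $\mathrm{rank}^{-1}$ — a heavy-tailed, Zipf-like clone-size profile. In
each of the 40 cancer samples, 20% of sequences (`witness_rate = 0.2`)
receive a motif drawn uniformly from `{"LQ", "WGQW", "RGNTEAF"}` — one
short, one medium, one long motif, spanning the filter-height range —
planted at a uniform interior position; the 40 control samples receive
none. Witness assignments are returned as hidden ground truth.

What the generator does *not* emulate: V(D)J recombination statistics, real
generation probabilities, V-gene/length covariation, HLA restriction, or the
biological tendency of cancer-associated clones to sit at particular
abundance ranks. Witness ranks are uniform by construction, so the learned
rank weights have nothing to learn *on this benchmark* — passing tests here
demonstrates motif recovery and pipeline correctness, not that learned
aggregation beats the mean on real repertoires.

The benchmark experiments in the test suite therefore train with the
aggregator held at its mean warm start (`warmup = 1`), mini-batches of 16
bags and learning rate 0.01 for up to 600 epochs — on an 80-sample cohort
this reaches convergence in a few thousand parameter updates, where the
default full-batch schedule (tuned for larger cohorts) converges far more
slowly. Problem sizes used by the checks: one 64/16 train/test split of the
default cohort for motif recovery (held-out bag AUC and witness-retrieval
AUC), and pooled out-of-fold predictions from one 5-fold cross-validation
for the null cohort (`witness_rate = 0`), whose pooled AUC over 80 bags has
a null standard deviation of about 0.065 — small enough that the
chance-level band [0.35, 0.65] is a meaningful type-I check rather than
noise.

## Numerical choices and degenerate inputs

* Predictions are clamped to $[10^{-12}, 1-10^{-12}]$ before logarithms.
* Max-pool ties take the leftmost window; the pooled value itself is
  tie-free.
* A filter taller than a sequence contributes a zero feature (no eligible
  window) and no gradient; the per-sequence API raises an error instead, so
  the caller decides.
* Raw counts and fractions are both accepted on load; counts are normalized
  per sample so reference-set ranking is well defined.
* All-zero region counts, single-class cohorts, folds a class cannot fill,
  and empty repertoires after preprocessing raise immediate errors.

## Limitations

The classifier ships untrained: the real cohorts behind the published
evaluations are controlled-access and are not bundled, so the package
provides the architecture, training protocol and benchmark machinery, not a
pretrained clinical model. Only TCRβ CDR3 amino-acid sequences are
considered (no TCRα, no nucleotide-level information, no V/D/J
re-annotation), the scorer head is deliberately a single linear layer, and
the synthetic benchmark's simplifications are listed above.
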