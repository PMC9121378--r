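# tcrmil

Multi-instance deep learning for cancer detection from T-cell receptor
repertoires.

## The problem

T cells that respond to tumour antigens leave a trace in the blood: their
receptor sequences. The CDR3 region of the TCRβ chain chiefly determines
antigen specificity, so a repertoire — one sample's collection of CDR3
clonotypes with clonal frequencies — may reveal whether its donor has
cancer. Two things make this hard. First, the biochemical motifs that
distinguish cancer-associated TCRs (caTCRs) vary in length, so methods that
chop sequences into fixed-length k-mers lose information. Second, no one
knows *which* sequences in a repertoire are cancer-associated: labels exist
only at the repertoire level. That is multi-instance learning (MIL) — bags
(repertoires) are labeled, instances (TCRs) are not.

`tcrmil` is for computational immunologists who want a tested, reusable
implementation of a deep MIL repertoire classifier: sequence-level motif
detection with a multi-width convolutional filter bank, and a learned linear
aggregation of per-TCR scores into a repertoire-level cancer score.

## The model

Each CDR3 (length *l*, 10–24 after QC) is encoded row-wise by a 20 × *d*
amino-acid biochemical feature table (Atchley *d* = 5 and Kidera *d* = 10
ship with the package; PCA encodings can be derived from any AAindex-format
table) and zero-padded to 24 × *d*. A bank of convolution filters scans it,

&nbsp;&nbsp;&nbsp;&nbsp;*o&#8336; = ReLU(W<sub>F</sub> · M[a : a+h−1] + b<sub>F</sub>)*,

one filter height per observed size of contiguous peptide-contacting CDR3
residue runs: heights 2–7 with 3, 3, 3, 2, 2, 1 filters (14 total), height 8
excluded because its occurrence frequency (0.017) falls below 0.05. Each
feature map is reduced by 1-max pooling — the best-matching window is the
candidate motif — and a one-layer linear classifier with sigmoid maps the
pooled 14-vector to a per-TCR cancer score *ỹ = σ(W<sub>L</sub>ᵀp + b<sub>L</sub>)*.
The top *k* = 100 clonotypes' scores, in abundance-rank order, feed a second
one-layer classifier *Ỹ = σ(W<sub>L′</sub>ᵀ[ỹ₁…ỹ<sub>k</sub>] + b<sub>L′</sub>)* —
rather than the mean (all TCRs weighted equally) or the max (one positive
instance decides), the rank weights are learned. Training is end-to-end
(Adam on the bag-level cross-entropy, 40% dropout on both classifier
layers, early stopping on validation AUC, best of *n* seeded runs kept).
Windows overlapping the zero padding are excluded from pooling, so a
sequence scores identically at its true length and padded.

The whole pipeline is exercisable without any external data through a
synthetic cohort generator that plants variable-length motifs into a
configurable fraction of cancer-sample sequences and keeps the assignments
as hidden ground truth.

## Worked example

Simulate a cohort with planted motifs, fit the classifier, and score
held-out repertoires:

```r
library(tcrmil)

design_filter_bank(contact_region_table(), d = 5)
#> Convolution filter bank: 14 filters over 6 heights (d = 5)
#>   2 x 5: 3
#>   3 x 5: 3
#>   4 x 5: 3
#>   5 x 5: 2
#>   6 x 5: 2
#>   7 x 5: 1

cohort <- generate_cohort(seed = 42)       # 40 cancer + 40 control samples,
labs <- sapply(cohort$repertoires,         # 100 CDR3s each, 20% witnesses
               function(r) r$label)
set.seed(42)
test_ix <- unlist(lapply(split(seq_along(labs), labs),
                         function(ix) sample(ix, 8)))

fit <- tcrmil(cohort$repertoires[-test_ix], k = 100, epochs = 600,
              n_runs = 1, seed = 42, patience = 600, val = 0.2,
              batch_size = 16, lr = 0.01, warmup = 1)
fit
#> Multi-instance TCR repertoire classifier
#>   filters: 14 over heights 2,3,4,5,6,7 (d = 5, encoding 'atchley')
#>   bag size k = 100, pooling = max, masked padding = TRUE
#>   validation AUC of selected run: 1.000

scores <- predict(fit, cohort$repertoires[test_ix])
round(scores[c(1, 2, 9, 10)], 3)
#> control_37 control_01  cancer_36  cancer_25
#>      0.463      0.448      0.491      0.497
roc_auc(scores, labs[test_ix])$auc
#> [1] 0.953125
```

The held-out bag AUC of 0.95 says the model separates cancer from control
repertoires almost perfectly on this benchmark; the per-TCR scores
(`predict(fit, ..., type = "tcr")`) rank the planted motif carriers above
background sequences with AUC ≈ 0.83. Control scores sit below cancer
scores but all near 0.5 — with the aggregator held at the calibrated mean
(`warmup = 1`) the bag logit spread is compressed, so use `youden_threshold()`
rather than the raw 0.5 cut when a hard decision rule is needed.

A command-line front end wraps the same functions
(`inst/exec/tcrmil simulate|train|predict|evaluate|cv`); see the script
header for flags. The methods vignette (`vignettes/tcrmil-methods.Rmd`)
documents the model, the training-dynamics design choices, and what the
synthetic benchmark does and does not demonstrate.

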