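---
title: "Predicting RNA 5hmC sites with a dual-branch sequence model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting RNA 5hmC sites with a dual-branch sequence model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rna5hmc)
```

## The problem

5-hydroxymethylcytosine (5hmC) is a cytosine modification, formed by
TET-mediated oxidation, that occurs on RNA and is implicated in splicing,
stability and disease. Experimentally mapping RNA 5hmC (hMeRIP-seq,
chromatography) is expensive, so sequence-based classifiers are used to
prioritize candidate sites. The unit of prediction in this package is a
41-nt window over `{A,C,G,U}` whose central position (0-based index 20) is
the candidate cytosine; the label says whether that C is a 5hmC site.

`rna5hmc` implements, as a single tested library:

* a **dual-branch neural classifier** — an inception branch over learned
  per-nucleotide word embeddings and a transformer-encoder branch over
  per-nucleotide RNA language-model embeddings, fused into one sigmoid
  output;
* the **fourteen classical nucleotide descriptors** (NAC, DNC, TNC, Kmer,
  RCKmer, binary one-hot, ANF, EIIP, PseEIIP, ENAC, NCP, DAC, PseDNC,
  PCPseDNC) used as baselines during feature selection;
* the **nine-metric evaluation protocol** (SN, SP, ACC, BACC, PREC, F1,
  MCC, AUC, AUPR) with stratified splitting and k-fold cross-validation;
* the **selection experiments** (per-descriptor XGB benchmarking,
  branch-combination comparison, classical baselines on mean-pooled
  embeddings, ablation, epoch/dropout grid search) with Wilcoxon
  signed-rank and Friedman tests;
* the **positional neighbourhood analysis**: count/frequency profiles,
  region aggregation, two-sample enrichment, Shapley-value attribution
  over position ranges, and the two-feature A/G-count classifier for the
  motif block at positions 21–26;
* a **synthetic-data generator** that makes the whole pipeline testable
  without any external data or model downloads.

## The model

Branch 1 (inception) consumes the integer-encoded sequence
(A=0, C=1, U=2, G=3), maps each nucleotide to a learned 32-dimensional
word embedding, and applies three inception modules. Each module runs four
parallel, length-preserving convolutional paths — a 1×1 convolution, 1×1
then kernel-3, 1×1 then kernel-5, and a kernel-3 max pool followed by 1×1 —
whose outputs are concatenated along channels (4 × 16 = 64 by default),
batch-normalized and passed through ReLU. A kernel-2/stride-2 max pool over
the 41 positions, a flatten, and a linear layer produce a 256-dimensional
branch output.

Branch 2 (transformer) consumes a 41 × D matrix of per-nucleotide
embeddings served by a *provider* (D = 1280 for the full-scale RNA language
model). Six post-norm transformer encoder layers (multi-head self-attention
plus a position-wise feed-forward network) are followed by a max pool along
the feature axis with kernel 3 and stride 2 — 1280 dimensions pool to 639
per position — a flatten, and two fully connected layers down to 256.

The two 256-vectors are concatenated (512) and passed through the fusion
head: linear to 128, ReLU, dropout, 1-D batch norm, and a final linear to a
single sigmoid unit. Probabilities at or above 0.5 classify positive (the
tie goes to the positive class). Single-branch ablation variants
(`branch_mode = "inception_only"` / `"transformer_only"`) route one
256-vector into the same head shape, and LSTM/RNN branch types used during
model selection replace a branch with a recurrent stack whose final hidden
state feeds a linear layer to 256.

### Training recipe and its parameters

| Parameter | Default | Notes |
|---|---|---|
| optimizer | Adam | β₁ = 0.9, β₂ = 0.999, ε = 1e-8 |
| learning rate | 1e-5 | initial and constant |
| epochs | 18 | fixed; no early stopping |
| batch size | 500 | last batch of an epoch may be smaller |
| loss | binary cross-entropy | on the sigmoid output |
| dropout (inception branch) | 0.5 | one layer after the module stack |
| dropout (elsewhere) | 0.3 | encoder sublayers, head, dense layers |
| maximum L2 norm | 1 | gradient-norm clip; see below |
| threshold | 0.5 | ties classify positive |

"Maximum L2 norm 1" is interpreted as global gradient-norm clipping at 1.0
during training; a per-unit weight max-norm constraint is available instead
via `l2_mode = "weight_maxnorm"`, since either reading is defensible.

Unspecified internal widths are package decisions: 16 channels per
inception path (64 per module), one kernel-2 pool after the inception
stack (41 → 20 positions, so the flatten feeds 64 × 20 = 1280 into the
256-unit linear), 8 attention heads (1280 is divisible by 8), feed-forward
width 2048, and a 512-unit then 256-unit dense pair after the transformer
pooling. The anchored quantities — 32-dim word embeddings, 6 encoder
layers, 256-dim branch outputs, the 639-dim pooled feature axis, a
(batch, 1) sigmoid output — are fixed by the published architecture and
asserted in the test suite at full scale.

### Numerical design choices

Three choices deserve explanation because the published recipe trains for
very few optimizer steps (18 epochs at batch 500 over ~10³ samples is a few
dozen Adam updates at learning rate 1e-5):

* **Zero-initialized output layer.** The final linear layer starts at
  exactly zero, so the initial output is 0.5 for every sample and early
  gradient steps align the output weights with the class-contrast of the
  penultimate features. This removes random-projection noise from the
  logit, letting the learned signal dominate immediately; it is a standard
  classifier-head initialization. All other weights use fan-in uniform
  initialization under the run seed.
* **Head ordering.** In the fusion head the 1-D batch norm sits directly
  before the output layer (linear → ReLU → dropout → batch norm →
  linear). Centring the pre-logit features keeps the 0.5 threshold at the
  class midpoint even while the output bias is still essentially at its
  initialization.
* **Batch-norm re-estimation.** After the last epoch, every batch-norm
  layer's running statistics are recomputed over the training set with
  dropout disabled (cumulative-average momentum over the batches).
  Statistics accumulated during training describe dropout-perturbed
  activations; evaluation runs without dropout, and with a lightly-trained
  network the resulting shift is material. Re-estimation is deterministic
  and seed-free.

Other numerics: softmax rows are max-shifted before exponentiation;
cross-entropy clamps probabilities at 1e-12; batch-norm and layer-norm use
ε = 1e-5; max-pool ties resolve to the earlier element; dropout uses
inverted scaling so evaluation needs no rescaling. Every source of
randomness (initialization, epoch shuffling, dropout masks) derives from a
single integer run seed, and runs are bit-reproducible given
(data, provider, config, seed). Checkpoints serialize weights, buffers,
config and seed, and reload bit-exactly.

## Embedding providers

The RNA language model itself is never loaded by this package. Embeddings
enter through a provider contract — a pure function from a labelled sample
to a (41, D) matrix:

* `synthetic_provider()` builds rows from a seeded random basis of the
  trinucleotide centred at each position, plus a nucleotide-identity basis
  and a sinusoidal positional component. It is deterministic across
  platforms given the seed, and by construction the sequence (and hence
  the planted class signal) is recoverable from the embeddings.
* `external_lm_adapter()` serves matrices that an offline extraction
  script stored with `cache_store()` (an R-native serialized container
  plus a JSON manifest recording provider, dimension and dialect).
  Requests for uncached ids fail loudly — there is no silent fallback.
  Which model layer the external embeddings come from, and whether special
  tokens were stripped, are properties of the extraction and are recorded
  in the cache manifest rather than assumed here.

`mean_pool()` averages a matrix along the sequence dimension; the
flat-feature experiments (descriptor benchmarking, classical baselines)
consume mean-pooled embeddings. Alternative poolings (max,
attention-weighted) would slot in at the same point.

## Descriptors

All k-mer-indexed descriptors use lexicographic base order A < C < G < U
(this fixes downstream feature indices and is independent of the A0/C1/U2/G3
integer encoding used by the word-embedding layer). Descriptor parameters
are the unique values reproducing the documented vector sizes: Kmer/DNC
k = 2, TNC k = 3, RCKmer k = 2 (10 reverse-complement classes), ENAC window
5 (37 windows × 4), DAC six properties × lag ≤ 2, PseDNC/PCPseDNC λ = 2
with weight w = 0.05 (w is configurable; no published value exists).
PseDNC uses the averaged squared-difference correlation between
dinucleotide property vectors; PCPseDNC uses averaged per-property
products. Both share the 16 + λ layout and sum to one. The EIIP constants
(A 0.1260, C 0.1340, G 0.0806, U 0.1335) and the six RNA base-step
physicochemical indices (Shift, Slide, Rise, Tilt, Roll, Twist;
standardized to mean 0, population variance 1 over the 16 dinucleotides)
ship as plain-text data files and are swappable. PseEIIP multiplies the
*sum* of the three constituent EIIP values by the normalized trinucleotide
frequency. DAC and the pseudo-composition correlation sums are verified
against brute-force double-loop oracles in the tests.

## The synthetic generator: what it does and does not emulate

`generate_dataset()` draws balanced sets of 41-nt windows with a central C.
Non-central positions are i.i.d. from a background distribution (uniform by
default); in positives, positions 21–26 come from a motif-adjusted
distribution: `a_delta` is added to A (funded equally from C and U) and
`g_delta` moves probability from G to A. This reproduces the direction of
the signal found in real data — an A-rich, G-poor block immediately
downstream of the site — with a tunable effect size; the composition is
chosen so that the package's reference study condition
(`a_delta = 0.4`, `g_delta = 0.2`) remains a valid distribution
(A 0.85, C 0.05, G 0.05, U 0.05 at motif positions). Invalid adjustments
error before any sampling. The generator is a pure function of its config;
the same seed regenerates byte-identical FASTA.

What it deliberately does **not** emulate: dinucleotide autocorrelation and
codon structure of real transcripts, sequence-identity redundancy (the real
benchmark was identity-reduced below 20% with an external clustering tool),
position-dependent background composition, and any relationship between
sequence and true language-model embeddings (the synthetic provider encodes
local context, which is a best case for the transformer branch). Passing
the end-to-end tests therefore demonstrates that the pipeline can recover a
planted positional composition signal — not that the published accuracy on
hMeRIP-seq data is reproduced, which would require the original dataset and
the 650M-parameter language model.

## Study sizes used by the test suite

The packaged studies run the full published recipe (6 encoder layers, 3
inception modules, 18 epochs, learning rate 1e-5, batch 500, dropout
0.5/0.3, gradient clip 1) at a reduced embedding width — 16-dimensional
synthetic embeddings, 2 attention heads, feed-forward width 32 — which the
package treats as its reference simulation scale: the signal-recovery
question does not depend on the embedding width, while full-width
(41 × 1280) six-layer training is a GPU-scale job. Architecture anchors are
asserted separately at full width via a single forward pass. The end-to-end
study uses 500 samples per class with an 80/20 split and five seeded runs;
the ablation study uses 250 per class and three shared seeds; the
enrichment type-I calibration uses twenty null simulations at 1000 per
class; the attribution study explains 24 held-out samples with 12 seeded
background permutations per sample.

## Statistical components

* **Wilcoxon signed-rank** (`wilcoxon_compare()`): two-sided, zero
  differences dropped; the null distribution is enumerated exactly over all
  2ⁿ sign assignments for up to 14 non-zero pairs (which also handles rank
  ties exactly), with a tie-corrected normal approximation beyond. All
  differences zero returns p = 1 with a degeneracy flag.
* **Friedman test** (`friedman_across_folds()`): delegated to
  `stats::friedman.test` on the folds × conditions matrix; constant rows
  short-circuit to statistic 0, p = 1.
* **Two-proportion enrichment** (`two_sample_enrichment()`): per
  position/nucleotide z-test without continuity correction, matching the
  two-sample-logo convention of unadjusted per-cell tests at 0.05;
  Benjamini–Hochberg adjustment is available behind a flag but off by
  default to mirror that convention.
* **AUC** is computed by midranks (each tied positive–negative pair counts
  half) and **AUPR** as the step-interpolated area under the
  precision–recall curve, the conservative choice. Metrics with a zero
  denominator report 0 and carry an `undefined` flag instead of aborting
  batch experiments; AUC/AUPR on single-class truth are flagged `NA`.
* **Grid search** selects the epochs/dropout combination with the minimum
  rank-sum across F1, MCC, AUC and AUPR (ties broken by F1, then MCC) on an
  internal stratified 80/20 validation split — a pure function of the score
  table, so re-ranking the stored table reproduces the choice.

## Attribution

`range_attribution()` explains the output of a trained model with respect
to the 41 inception-branch input positions while each embedding-branch
contribution is held fixed at the sample's own value, isolating the
sequence branch (the convention used for the published motif analysis). The
default method is a sampling-based Shapley approximation: seeded position
permutations with backgrounds drawn by per-position shuffling of the
dataset, incremental evaluations batched into one forward pass per
permutation. `gradient_input` is the fast fallback (gradient of the logit
with respect to the word-embedding activations, contracted with the
activations). Absolute attributions are averaged over samples and then over
positions within each range; the default ranges partition 0–40 into six
blocks with the motif block 21–26 on its own. The method id travels with
the result.

## Known limitations

* The network trains on one CPU in plain R (with a compiled attention
  kernel); it is suitable for the packaged simulation scales, not for
  full-width language-model embeddings.
* Published scores on the real benchmark are not reproducible here by
  design: they require the original hMeRIP-seq-derived dataset and true
  language-model embeddings. The package's claims are structural
  (dimensions, arithmetic, exact oracles) and behavioural on synthetic
  data (signal recovery, calibration).
* With the published step budget the model is lightly trained; the
  zero-init/centred-head/BN-re-estimation choices above are what make the
  0.5 threshold meaningful in that regime, and they are deliberately
  conservative rather than accuracy-maximizing.
* PseDNC and PCPseDNC are distinct implementations here; whether the
  published pipeline distinguished them is unknowable from its outputs
  (identical scores were reported for both), so no equality is assumed.
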