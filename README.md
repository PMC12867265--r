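# rna5hmc

Prediction of RNA 5-hydroxymethylcytosine (5hmC) modification sites from
sequence. The unit of prediction is a 41-nt RNA window whose central
position (0-based index 20) is a candidate cytosine; the classifier decides
whether that C carries the 5hmC mark.

The core model is a dual-branch neural network:

* an **inception branch** — the sequence is integer-encoded
  (A=0, C=1, U=2, G=3), mapped to learned 32-dim word embeddings, and
  passed through three inception modules (four parallel length-preserving
  convolution paths with kernels 1/3/5 plus a pooled path, concatenated to
  64 channels), then pooled and projected to a 256-vector;
* a **transformer branch** — a 41 × 1280 matrix of per-nucleotide RNA
  language-model embeddings passes through six transformer encoder layers,
  a feature-axis max pool (1280 → 639 per position), and dense layers to a
  256-vector;
* a **fusion head** — the concatenated 512-vector goes through two linear
  layers to a single sigmoid unit; probability ≥ 0.5 classifies a site.

Training follows a fixed recipe: Adam, learning rate 1e-5, 18 epochs,
batch size 500, binary cross-entropy, dropout 0.5 in the inception branch
and 0.3 elsewhere, gradient L2 norm clipped at 1. Everything is seeded and
bit-reproducible. Around the model, the package provides the fourteen
classical nucleotide descriptors (Kmer, RCKmer, binary, ANF, EIIP, PseEIIP,
ENAC, NCP, DAC, PseDNC, PCPseDNC, NAC, DNC, TNC), the nine-metric
evaluation protocol (SN, SP, ACC, BACC, PREC, F1, MCC, AUC, AUPR),
model-selection and ablation experiments with Wilcoxon/Friedman tests,
positional enrichment and Shapley-attribution analysis of the A-rich/G-poor
block at positions 21–26, and a synthetic-data generator so the entire
pipeline runs without external data. Language-model embeddings enter only
through a provider interface: a deterministic synthetic provider for
simulation, or a cache adapter for embeddings extracted offline.

## Worked example

Generate a labelled synthetic dataset with the planted downstream motif,
train the dual model at the package's reference simulation width, and
evaluate on the held-out split:

```r
library(rna5hmc)

bundle <- generate_split_bundle(
  generator_config(500, 500, seed = 11, motif = motif_spec(0.4, 0.2)),
  fraction = 0.8, seed = 11)
provider <- synthetic_provider(provider_spec("synthetic", dim = 16, seed = 11))
cfg <- model_config(embed_dim = 16, transformer_heads = 2,
                    transformer_ffn_dim = 32)   # published recipe, narrow width

fit <- train_model(bundle$train, provider, cfg, seed = 2)
report <- compute_metrics(bundle$test$label,
                          predict(fit, bundle$test, provider))
print(report)
#>     SN     SP    ACC   BACC   PREC     F1    MCC    AUC   AUPR
#> 0.9600 0.8400 0.9000 0.9000 0.8571 0.9057 0.8058 0.9714 0.9653
```

The positives carry extra A (and depleted G) at positions 21–26; the test
sensitivity/specificity around 0.9 and AUC around 0.97 show the model
recovering that signal from sequence plus synthetic embeddings. The same
motif is visible without any model:

```r
data <- generate_dataset(generator_config(500, 500, seed = 11,
                                          motif = motif_spec(0.4, 0.2)))
enr <- two_sample_enrichment(positional_profile(data, 1),
                             positional_profile(data, 0))
subset(enr, nucleotide == "A" & position %in% 21:26)$diff
#> [1] 0.614 0.614 0.554 0.622 0.626 0.616   # A-frequency excess, all p < 1e-68
```

and a trained model attributes its output mostly to that block
(`range_attribution(fit, ...)` ranks range 21–26 top among six equal
blocks). The command-line front end (`exec/rna5hmc`) exposes the same
pipeline as subcommands: `simulate`, `split`, `features`, `embed`, `train`,
`evaluate`, `neighbourhood`.

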