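---
title: "Substructure interaction maps for DTI prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substructure interaction maps for DTI prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dtimap` casts drug–target interaction (DTI) prediction as binary
classification over (SMILES, protein sequence) pairs, built on the premise
that interactions are sub-structural: a few chemical groups of the ligand
engage a few short motifs of the target. This vignette documents the model,
its assumptions, the tunable parameters, the numerical choices, and what the
synthetic benchmark does and does not establish.

## The model

**Sub-structure mining (FCS).** Both molecule classes are linear strings, so
recurring sub-structures are recoverable by frequency alone. The miner
initializes the vocabulary V with the distinct single characters of the
corpus, tokenizes every sequence into characters, and then repeats a
scan–identify–update loop: count adjacent token pairs, merge the most
frequent pair (A, B) into a new token AB everywhere, and append AB to V. It
stops when the best pair's count falls below θ or |V| reaches ℓ. Counting
and rewriting are both greedy, left-to-right and non-overlapping, so a
pair's count always equals the number of replacements its merge would
perform ("AAA" contains one (A, A), not two). Equally frequent pairs are
broken toward the lexicographically smallest concatenated token under C
collation, which makes mining deterministic across platforms. New sequences
are tokenized by replaying the merge list in learned order; characters never
seen at mining time become UNK, and for fully in-alphabet inputs the
concatenation of the tokens reconstructs the input exactly (a tested
invariant). Drugs and proteins get separate miners and vocabularies; SMILES
are split into single characters, so two-character atoms such as `Cl` enter
the vocabulary as learned merges.

**Augmented embedding.** A sub-structure sequence is truncated/padded to a
maximum length (head kept), mapped to indices, and embedded as the sum of a
content lookup and a learned positional lookup. A stack of post-norm
transformer encoder layers (multi-head self-attention, position-wise
feed-forward, residual connections, layer norm) then contextualizes the
embeddings. PAD positions are excluded from attention *keys*: padding
content can never leak into real-token context (a tested invariant), while
PAD rows still receive outputs because they feed the fixed-shape interaction
map downstream.

**Interaction head.** The map I[j, i] = ⟨Ẽᵈⱼ, Ẽᵖᵢ⟩ scores every drug
sub-structure against every protein sub-structure; the dot product is the
default because a scalar per cell keeps the map two-dimensional and directly
interpretable (`sum` and `average` are provided as scalar reductions of the
embedding pair). One convolution layer — three 3×3 filters, stride 1, valid
padding, ReLU — aggregates neighborhood interactions, and a sigmoid linear
decoder on the flattened features yields the probability. Training minimizes
the negative Bernoulli log-likelihood (binary cross-entropy) with Adam.

**Protocol.** Pairs are split 7:1:2 by a seeded permutation; negatives are
sampled uniformly from drug×protein pairs unseen in the positive set across
*all* splits, which avoids label leakage rather than excluding only training
positives; affinity data are binarized at Kd < 30 (strict inequality, the
boundary is negative). After each epoch the validation ROC-AUC is computed
and the best epoch's weights are kept. Reported metrics are ROC-AUC (rank
statistic with tie correction), PR-AUC (step-wise average precision over
distinct-threshold blocks), and sensitivity/specificity at the threshold
maximizing validation F1 (candidates at midpoints of sorted unique scores
plus an all-positive candidate; F1 ties go to the lowest threshold).

## Ablation variants

Reduced configurations isolate each component's contribution:
`no_cnn` flattens I straight into the decoder; `no_augembed` removes the
transformer stack (raw content+positional embeddings feed the map);
`no_interaction` additionally removes the map and decodes the concatenated
masked-mean drug and protein embeddings. The pooling choice for
`no_interaction` is a masked mean over real positions — the minimal decoder
over the FCS fingerprint.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| θ (`theta`) | 500 (production), 3–5 (desk) | minimum sub-structure frequency; scale with corpus size |
| ℓ (`max_vocab`) | unbounded | vocabulary cap including 2 reserved tokens; θ-driven stopping is the default because a principled ℓ depends on the corpus |
| Θd, Θp | 50, 545 | maximum sub-structure sequence lengths (drug, protein) |
| ϑ (`embed_dim`) | 384 | latent width per sub-structure |
| layers / heads / FFN | 2 / 12 / 1536 | transformer encoder shape |
| dropout | 0.1 | inside encoder layers, training only |
| CNN | 3 filters, 3×3 | interaction aggregation |
| optimizer | Adam, lr 1e-5, batch 64, ≤30 epochs | Adam moments (0.9, 0.999), ε = 1e-8 |

The desk profile (`desk_model_config()`, `desk_train_config()`) shrinks this
to ϑ = 16, 1 layer, 4 heads, FFN 32, dropout 0, Θd = 24, Θp = 48, lr 1e-3,
batch 32 — every architectural element retained at a size that trains in
about ten seconds per epoch on one CPU. The package's own experiments (test
suite and `scripts/acceptance.R`) use this profile with 5 training epochs on
a 2,000-pair benchmark (1,400 train / 200 validation / 400 test, 60 drugs ×
60 proteins).

## Numerical choices

- Probabilities are clamped to [1e-7, 1−1e-7] before logs.
- Weight init: truncated normal (σ = 0.02, |x| ≤ 2σ) for all tables and
  linear maps; layer-norm gain 1, bias 0. All init and shuffling flow
  through one explicit seed; the caller's RNG state is restored afterwards.
- Layer norm uses ε = 1e-5; attention masking uses an additive −1e30 before
  the softmax (never NaN because at least one real key exists).
- Backpropagation is hand-derived per layer and verified against central
  finite differences (relative error < 1e-3 on sampled parameters of an
  ϑ = 8 model) in the test suite.
- Zero encoder layers is a valid configuration and is the identity map,
  which makes the `no_augembed` equivalence testable exactly.
- Degenerate inputs: empty sequences are rejected (tokenizer, indexer);
  empty corpus entries are dropped with a warning; single-class label
  vectors are errors for ROC/PR; maps smaller than the kernel are errors.
- PAD rows/columns of I are left unmasked through the CNN; their content is
  a learned constant (PAD embedding + positional), so the decoder can learn
  them away. Masking them is the plausible alternative; the choice is
  recorded in the checkpoint via the stored configuration.

## The synthetic benchmark

`synthetic_spec()` emulates the statistical structure the method assumes,
at toy scale: an 8-symbol drug alphabet and the 20 amino acids, uniform
random sequences (drugs 16–24 characters, proteins 30–45), one planted
motif per side (`NCCO`, `KNWVH`) written over a uniform window of 70% of
sequences, and the deterministic interaction rule *label 1 iff both motifs
are present*, optionally flipped with probability ε. Motifs overwrite
characters rather than inserting them so lengths stay in range. Pairs are
drawn uniformly without replacement from the rule-positive and
rule-negative cross spaces to a 50:50 balance.

What it establishes: that mining recovers planted frequent sub-structures,
that the full architecture can learn a sub-structural co-occurrence rule to
high held-out ROC-AUC from a few thousand pairs, that held-out performance
respects the Bayes ceiling 1−ε under label noise (a leakage check), that
the full model dominates the pooled-embedding ablation, and that the
trained interaction map concentrates intensity at the causal
(drug motif × protein motif) block — tested as a statistical property
(block maximum above the map-wide median |intensity| for most positive
pairs in most seeds) because per-pair argmax localization is noisy at this
scale.

What it does not establish: real SMILES grammar (rings, branches,
stereochemistry), realistic motif degeneracy or binding physics, class
imbalance, or covariate shift between unlabeled mining corpora and labeled
pairs. Performance on the synthetic benchmark is an architecture
verification, not a chemistry claim.

## Known limitations

- Pure-R tensor math: fine at desk scale (seconds per epoch), slow for
  production-scale corpora; the design isolates the layer primitives so a
  compiled backend could replace them without interface changes.
- The miner is frequency-driven only; it has no chemical awareness and no
  vocabulary pruning.
- Truncation keeps sequence heads; for proteins whose binding region lies
  deep in the chain, Θp must be raised.
- The explanation reports name sub-structure pairs with high map intensity;
  this is a model-introspection tool, not a mechanistic binding-site
  prediction.
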