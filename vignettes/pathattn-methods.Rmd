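---
title: "pathattn: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pathattn: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`pathattn` performs supervised cell-type label transfer with a
transformer whose first layer is a knowledge-masked linear embedding.
The design rests on one biological assumption: *cell identity is
expressed through coordinated gene-set activity*. Pathways and regulons,
not individual genes, are taken as the units of identity, which is what
makes the learned representation interpretable and comparatively robust
to gene-level technical noise such as batch effects.

## Masked embedding

Let `e ∈ R^n` be one cell's (normalized) expression over the model's
gene vocabulary and `M ∈ {0,1}^{n×k}` the binary membership matrix of
`k` gene sets. The embedding weight tensor `W` (one `n × k` slice per
embedding dimension) is gated elementwise:

```
W' = W ⊙ M,     T[j, d] = Σ_i  W'[i, j, d] · e[i]
```

so token `j` receives input *only* from the member genes of set `j`.
The constraint is enforced exactly, not approximately: after every SGD
step the weights are re-multiplied by the mask, so off-mask entries are
identically zero at all times, and perturbing a non-member gene can
never change a token (this is asserted numerically in the tests). The
embedding is repeated `m = 48` times in parallel; each token is thus a
48-dimensional learned summary of one gene set's expression.

Genes in the vocabulary that belong to no retained set keep an all-zero
row in `M`. They occupy an input position but cannot influence any
token; this keeps reference/query gene alignment independent of the
gene-set resource.

## Attention and classification

A learnable class token (CLS) is prepended to the token matrix. Each
attention block computes, per head `i` of `H = 4` heads with head
dimension `d = m/H`:

```
A_i = softmax(Q_i K_iᵀ / √d),   head_i = A_i V_i
```

with `Q, K, V` linear projections of the block input, heads concatenated
and projected by `W^O`, a residual connection, then a two-layer
feed-forward sublayer (GELU nonlinearity, width `2m`) with its own
residual. The per-head logits are scaled by the square root of the
*per-head* dimension, the standard scaled dot-product convention, which
keeps logit variance constant as heads are added. The classifier is a
fully connected network (one GELU hidden layer of width `2m`) with
softmax over the `nc` training classes, reading the CLS row of the final
block.

The head-averaged CLS→token attention of the final block — the k-vector
of post-softmax weights the class token places on each pathway token —
is exported as the **attention embedding** of the cell. The CLS-to-CLS
share is excluded (the embedding describes attention *to pathways*), so
rows sum to at most 1 rather than exactly 1.

## Normalization placement: why post-norm

Layer normalization is applied **after** each residual sum (post-norm,
as in the original attention architecture), not before each sublayer.
This is a deliberate and consequential choice. A token row is `m`
reweighted copies of the same gene-set activity; normalizing a token row
*before* attention divides out its scale, and the scale — how active the
gene set is in this cell — is precisely the signal the masked embedding
exists to carry. In development we found that with pre-norm blocks the
model could only exploit within-set composition patterns: training
accuracy saturated while validation accuracy plateaued far below it
(memorization), whereas post-norm blocks let the first attention layer
see raw token magnitudes and closed the train/validation gap entirely.
Both variants were verified against finite-difference gradients; the
difference is representational, not a defect.

Layer normalization is non-affine (no learned gain/bias): the adjacent
linear maps absorb any affine reparametrization, and exact backprop
stays simple. The normalization epsilon is 1e-5.

## Unknown calling

Prediction returns the argmax class unless the maximum softmax
probability falls below the cutoff (default 0.95), in which case the
cell is labeled `"Unknown"`. This is the mechanism for novel-cell-type
discovery: a query type absent from the reference produces diffuse
probabilities and is rejected. The cutoff is a plain threshold, not a
calibrated quantity; raising it can only increase the number of Unknown
calls (tested as a monotonicity property). Argmax ties break to the
first label in sorted order, for reproducibility.

# Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| `m` (embedding dim) | 48 | token width; the embedding repeat count |
| `H` (heads) | 4 | must divide `m`; head dim `m/H` = 12 |
| `depth` | 1 | one block keeps CLS attention directly traceable to tokens |
| `ffnHidden` | `2m` | feed-forward width |
| `dropout` | 0 | applied to attention output and FFN hidden when > 0 |
| `unknownCutoff` | 0.95 | Unknown-calling threshold |
| `maxSetSize`, `maxSets` | 300, 300 | gene-set filters when building the mask |
| `epochs` | 20 | convergence budget |
| `batchSize` | 256 | SGD minibatch |
| `lr0` | 0.3 | initial learning rate, cosine-decayed to ~0 |
| `momentum`, `weightDecay` | 0.9, 1e-4 | SGD with momentum; decay on matrices only |
| `valFraction` | 0.30 | stratified validation split |
| `sizeFactor` | 1e4 | library-size target for normalization |

Depth, head count, feed-forward width, activation, and all optimizer
hyperparameters beyond "SGD with cosine decay" are package decisions,
exposed in `modelConfig()` / `trainConfig()`. The learning rate deserves
a note: on desk-scale references (a few thousand cells) an epoch is only
a handful of minibatches, so convergence within the ~20-epoch budget
requires a much larger initial rate (0.3 with momentum 0.9, annealed by
the cosine schedule) than deep-learning folklore suggests; this was
calibrated on the training-loss trajectory of the synthetic fixture.

Model-input normalization (library-size to 1e4 + `log1p`) mirrors the
preprocessing convention used for the attention embedding itself and is
standard scRNA-seq practice; `normalize = FALSE` feeds raw counts for
workflows with their own normalization.

## Gene-set handling

Oversize gene sets (more than `maxSetSize` members after vocabulary
restriction) are **dropped** by default rather than truncated — a
truncated pathway is no longer the named pathway — with
`oversize = "truncate"` available. When more than `maxSets` sets
survive, the largest are kept, ties broken lexicographically
(deterministic, and larger sets are the better-supported tokens). Gene
matching is case-insensitive exact string matching; identifier
conversion (symbol/Ensembl, orthology) is out of scope. Random masks
(`randomMask`) draw `ceiling(density · n)` member genes per token
uniformly without replacement, emulating the no-prior-knowledge setting
with a small reserved-connection fraction (e.g. 1% or 5%).

# Training procedure

The reference is split 70/30, stratified by label so rare types appear
in validation (a simple random split would let validation accuracy
ignore them); each class contributes `round(0.3 · n_class)` cells, at
least one when the class has two or more, and singleton classes stay in
training with a warning. The loss is mean cross-entropy; the optimizer
is SGD with momentum; the learning rate follows
`lr0 · (1 + cos(π · epoch/epochs)) / 2`. The returned model is the epoch
checkpoint with the **best validation accuracy**, ties to the earlier
epoch (last-epoch checkpointing would throw away the selection signal
the validation split exists to provide). Class reweighting by inverse
frequency is available behind `classWeights = TRUE` but off by default.
All randomness (initialization, split, shuffling, dropout) derives from
the two configured seeds, and package functions restore the caller's
RNG state, so identical inputs and seeds give bit-identical training
histories.

# Interpretation tools

*Differential attention* (`rankAttentions`): attention scores are
library-size-normalized to 1e4 and log-transformed — the same
preprocessing as for clustering, so markers are computed on the scale on
which cells are compared — then each cell type is tested one-vs-rest per
token with a two-sided Wilcoxon rank-sum test (exact where the
implementation allows, normal approximation with tie correction
otherwise). BH adjustment is applied within each group across the k
tokens (the family of interest is "tokens for this comparison";
`adjust = "global"` pools all tests). Tokens are ranked by the signed
normal-deviate statistic, so rank 1 is the most enriched token.

*Sub-clustering* (`subclusterCells`): the selected cells are
re-preprocessed alone, projected to at most 50 principal components
(capped at k−1), connected by a symmetric 15-nearest-neighbor graph and
partitioned by Louvain modularity at resolution 0.3. Neighbor count and
PC count are conventional defaults, exposed as arguments.

*Gene importance* (`geneImportance`): the importance of gene `i` for
token `j` is the mean over embedding dimensions of `|W'[i, j, ·]|`.
Off-mask genes have importance exactly zero and are omitted. The measure
is sign-invariant by construction; it quantifies how strongly a gene's
expression moves the token, not the direction.

# Dataset-difficulty statistics

`datasetStats` reports log10 cell count, number of types, label entropy
and reference→query Kullback–Leibler divergence. Entropy and divergence
are implemented in their standard non-negative forms, in bits:
`H(p) = −Σ p_i log2 p_i` and `D_KL(p‖q) = Σ p_i log2(p_i/q_i)`. (Sign
conventions vary in the literature; the non-negative forms are the ones
for which "larger = harder" holds, which is how these statistics are
used.) Since a query may lack types present in the reference — which
would make the divergence infinite — both distributions are aligned on
the union of labels, smoothed with an additive pseudo-count (default
1e-9) and renormalized. The divergence of a distribution from itself is
0 after smoothing, and the statistic is asymmetric by design: it asks
how surprised the reference composition is by the query.

# The synthetic world

`simulatePathwayData` generates the validation world the test suite
relies on: 500 genes partitioned into 20 disjoint pathways of 25 genes;
5 cell types, each activating exactly one driver pathway whose member
genes have their negative-binomial mean multiplied by 3.0 over a
baseline of 0.5; dispersion 0.3 (variance `μ + 0.3 μ²`, typical
overdispersion for UMI counts); per-cell log-normal library-size factors
(log-sd 0.3); 2000 reference and 1000 query cells in balanced
proportions. Optional gene-wise log-normal batch factors (log-sd 0.2)
are technical by construction — drawn per gene and batch, independent of
cell type, with batch assigned randomly so it carries no label
information. An optional holdout type is excluded from the reference but
kept in the query, mirroring the deletion of an abundant cell type to
test novel-type rejection. The ground-truth gene sets are emitted as a
`GeneSetCollection` so the mask used in testing is exactly the
generating structure.

What the generator does **not** emulate: zero-inflation beyond the NB,
gene–gene correlation within or across pathways beyond the shared
driver shift, overlapping or hierarchical gene sets, cell-type
proportion imbalance, and per-cell (as opposed to per-gene) batch
effects. A green test on this world therefore establishes that the
implementation recovers pathway-mediated signal under realistic count
noise — not that the model outperforms alternatives on real tissue, and
not that Unknown calling is calibrated for arbitrary novel types.

# Numerical choices and degenerate inputs

* Softmax is computed with max-subtraction; probabilities sum to 1
  within 1e-6 and this is asserted.
* All-zero cells normalize to all-zero with a warning rather than NaN.
* Query genes are aligned to the vocabulary by (case-insensitive) name,
  never by position; missing genes are zero-filled, which the masked
  embedding treats as "unmeasured". An overlap below 10% aborts, since
  nearly disjoint gene spaces indicate a species or identifier mismatch
  rather than missing genes.
* Prediction streams in chunks (`chunkSize`); results are independent of
  chunking up to floating-point associativity of the underlying BLAS.
* Checkpoints are R serializations of the full model object; a reloaded
  model reproduces forward outputs bit-exactly (tested).

# Known limitations

* The embedding tensor is stored dense (`n × k·m`); at the default
  filters (300 sets × 48 dims on a few thousand genes) this is
  hundreds of MB of doubles. Desk-scale and typical HVG-restricted uses
  are fine; atlas-scale vocabularies would need a sparse parameter
  store.
* Training loops over cells in R for the attention blocks; a reference
  of a few thousand cells trains in about a minute, but the
  implementation is not tuned for millions of cells.
* `h5ad` input is not supported (no HDF5 R interface available in the
  target environment); CSV and MatrixMarket are.
* Softmax confidence is not calibrated; the 0.95 Unknown cutoff is a
  convention, and the appropriate value may differ for references with
  many closely related types.
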