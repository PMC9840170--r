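# pathattn

Interpretable cell-type annotation for single-cell RNA-seq by
pathway-token attention.

## The problem

Transferring cell-type labels from an annotated reference to new query
datasets is a routine step in single-cell analysis, but most deep
annotators trade interpretability for accuracy: their latent spaces mix
genes non-linearly and cannot be traced back to biology. `pathattn`
implements a transformer classifier whose **first layer is a
knowledge-masked linear embedding**: every learned token corresponds to a
named gene set (a pathway or regulon), and a gene can contribute to a
token only if it belongs to that gene set. A learnable class token (CLS)
attends to the pathway tokens through multi-head self-attention, and its
final representation drives a softmax cell-type classifier. Because the
attention of CLS over pathway tokens is a probability-like weight per
pathway, it doubles as an interpretable, batch-insensitive per-cell
embedding.

## The model

For a cell with expression `e ∈ R^n` and a binary membership mask
`M ∈ {0,1}^{n×k}` (gene i in set j ⇔ `M[i,j] = 1`), the masked embedding
is

    W' = W ⊙ M          (elementwise; enforced exactly after every step)
    t  = W'ᵀ e          (repeated m = 48 times in parallel → T ∈ R^{k×m})
    I  = rowbind(CLS, T)

Multi-head self-attention (H = 4 heads, head dimension m/H) follows the
scaled dot-product form: per head, `A = softmax(Q Kᵀ / √(m/H))`,
`head = A V`, heads are concatenated and projected, with residual
connections and a two-layer feed-forward sublayer (post-norm residual
blocks). The CLS row of the output feeds a fully connected classifier
with softmax over `nc` cell types; cells whose maximum probability falls
below a cutoff (default 0.95) are called **"Unknown"**, which is how
novel cell types are discovered. The head-averaged CLS→token attention
row (k values in [0,1]) is the cell's **attention embedding**.

Training: cross-entropy loss, SGD with momentum under cosine
learning-rate decay, a stratified 70/30 train/validation split, and
best-validation-epoch checkpointing; convergence within ~20 epochs.

Also included:

* GMT parsing and mask construction (`readGMT`, `buildMask`,
  `randomMask`), with the standard size filters (at most 300 genes per
  set, at most 300 sets).
* Differential-attention markers per cell type (one-vs-rest Wilcoxon
  rank-sum with Benjamini–Hochberg adjustment, `rankAttentions`),
  Louvain sub-clustering on the attention embedding
  (`subclusterCells`), and gene-importance tracing
  (`geneImportance` = mean |W'| over embedding dimensions).
* Dataset-difficulty statistics (`datasetStats`): log10 size, number of
  types, label entropy (bits) and reference/query Kullback–Leibler
  divergence (bits).
* A negative-binomial simulator of pathway-driven cell types
  (`simulatePathwayData`) that emits its ground-truth GMT.

## Worked example

```r
library(pathattn)

sim  <- simulatePathwayData(seed = 1)        # 5 types, 20 pathways, 2000+1000 cells
mask <- buildMask(sim$geneSets, rownames(sim$reference))
mask
#> MaskMatrix: 500 genes x 20 gene sets, 500 connections

model <- trainModel(sim$reference, mask,
                    config = modelConfig(seed = 2),
                    training = trainConfig(seed = 3))
model
#> TokenTransformer: 500 genes -> 20 tokens (m = 48, H = 4, depth = 1)
#>   classes (5): T1, T2, T3, T4, T5
#>   trained 20 epochs; best validation accuracy 0.980

predictCellTypes(model, sim$query)           # cutoff 0.95 -> Unknown calling
#> CellTypePrediction: 1000 cells, 5 classes, cutoff 0.95
#>   calls: T4 (199), T5 (198), T3 (196), T1 (195), T2 (186), Unknown (26)
```

Argmax accuracy against the held-back query labels is 0.978. The
attention embedding recovers each type's driver pathway as its top
marker token — for type T1 (driven by PW01):

```r
att <- attentionEmbedding(model, sim$query)
rk  <- rankAttentions(att, sim$query$label)
rk[rk$group == "T1" & rk$rank == 1, ]
#>    group token statistic       p_value         p_adj direction rank
#> 1     T1  PW01  21.87058 4.966880e-106 9.933760e-105         1    1

head(geneImportance(model, "PW01"), 3)       # token -> gene tracing
#>    gene importance
#> 1 G0018  0.2354168
#> 2 G0005  0.2314706
#> 3 G0010  0.2292128

datasetStats(sim$reference, sim$query)
#>   log_size n_types  entropy d_kl
#> 1  3.30103       5 2.321928    0
```

The rank-sum statistic of 21.9 (BH-adjusted p ≈ 1e-104) says T1 cells
concentrate their class-token attention on PW01 far more than all other
cells do; the entropy of 2.32 bits is the maximum for 5 balanced types,
and the near-zero divergence says reference and query share the same
type composition (an easy transfer task).

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch —
simulates the default pathway-driven world, builds the mask from the
emitted GMT, trains for 20 epochs, predicts the query and reports the
dataset statistics — and writes its JSON report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/pathattn-methods.Rmd`) describes the
model, its assumptions, the numerical design decisions, what the
simulator does and does not emulate, and known limitations.
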