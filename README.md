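# pathcomm

Path-centric inference of intra- and inter-cell communication from
single-cell expression, built around a graph transformer that classifies
cells between two conditions and, as a by-product of that classification,
learns an interpretable importance score for every predefined signaling
path.

## The problem

Single-cell RNA-seq contrasts (disease vs control, treated vs untreated)
are usually summarised gene by gene. But signals travel through cells along
*paths*: a receptor activates signaling intermediates, which activate
transcription factors, which regulate target genes; across cells, a
ligand secreted by one cell type engages a receptor on another. `pathcomm`
asks directly: **which receptor-anchored signaling paths separate the two
conditions, and how do they join into communication networks within and
between cell types?**

## The model

The inputs are (i) a role-annotated directed gene–gene interaction graph
built from ligand–receptor, signaling and gene-regulation edge tables, with
every edge classified into one of nine categories
(`LR_directional`, `LR_bidirectional`, `ligand/receptor/TF_regulation`,
`receptor_TF`, `receptor_signaling`, `signaling_TF`,
`signaling_signaling`); (ii) a predefined list of paths
`P = {p_1 … p_p}` enumerated from that graph — all tied-shortest paths from
receptors and/or all simple receptor→target paths with 3–10 nodes (a direct
receptor-regulation edge counts as a length-2 path); and (iii) a
log-normalized cells × genes matrix with binary condition labels.

Three encoder stages process each cell:

- **Node encoder** — `L` transformer layers over the `n` graph genes. Each
  gene's input embedding is a learned identity vector plus its expression
  value along a learned direction plus in/out-degree centrality encodings.
  Attention logits are biased by a *direct-edge encoding* (a learned
  per-category embedding dotted with a per-head vector, with a learned
  "no edge" row) and a *node-index encoding* (a free per-gene-pair bias per
  head and layer, possible because the graph is shared by all cells).
- **Path encoder** — for every layer `l`, node embeddings are scattered
  into the `k` path slots, projected, augmented with path-positional and
  edge-type encodings, scored by a small MLP into `r` score sets,
  softmax-normalized *within each path* (scatter-softmax), and summed per
  path to give path embeddings `P^l ∈ R^{p×h_emb}`.
- **Graph encoder** — a trainable score vector `M ∈ R^p` gives path
  importances `I = sigmoid(M)`; layer-wise graph embeddings `g^l = I^T P^l`
  are max-pooled across layers (JumpingKnowledge style) and classified by
  softmax.

Training minimises `L = L_class + β·L_reg` where `L_class` is the negative
log-likelihood of the condition labels and `L_reg` is a KL divergence
pulling `I` toward a fold-change prior: per path, the min-max-normalized
mean of signed (`up`), negated (`down`) or absolute (`deg`) gene log fold
changes. After repeated runs (fresh random 0.7/0.1/0.2 splits,
best-validation-AUC model selection), the per-repeat importances are
averaged, the top-`K` paths are merged into an **intra-cell network**, and
ligands differentially expressed in a second cell type are linked onto its
receptors to form an **inter-cell network**.

The forward *and* backward passes are implemented directly in vectorized R
(no autodiff framework); the analytic gradients are validated against
central finite differences in the test suite.

## Worked example

Everything below runs from scratch in about two minutes on one CPU, using
the bundled synthetic-data generator (no downloads):

```r
library(pathcomm)
fx <- make_fixture("small", file.path(tempdir(), "demo"), seed = 1)

cfg <- model_config(L = 2, h_emb = 16, h = 2, r = 2, dropout = 0.1)
ctx <- graph_context(fx$db, fx$path_list, cfg$max_degree_bucket)
protocol <- train_protocol(repeats = 2, epochs = 8, batch_size = 32,
                           beta = 1.0, mode = "deg", seed = 1)
res <- run_experiment(fx$expr, fx$labels, ctx, cfg, protocol)
print(res)
#> train_result: 2 repeat(s)
#>      accuracy recall precision specificity     F1    AUC
#> mean    0.975      1    0.9505      0.9505 0.9746 0.9975
#> sd      0.000      0    0.0085      0.0085 0.0045 0.0000

top <- order(-res$mean_I, seq_along(res$mean_I))[1:5]
#>   path 15  I=0.514  G0009 -> G0058 -> G0017 -> G0025
#>   path 19  I=0.514  G0010 -> G0052 -> G0049 -> G0039 -> G0016 -> G0024
#>   path  3  I=0.503  G0007 -> G0015 -> G0023
#>   path  1  I=0.503  G0006 -> G0038 -> G0040 -> G0014 -> G0022
#>   path  5  I=0.502  G0008 -> G0056 -> G0021 -> G0027
fx$truth$planted_path_ids
#> [1]  1  3  5 15 19
```

The held-out AUC says the model separates the two conditions almost
perfectly, and the five highest-importance paths are exactly the five
paths whose genes were shifted between conditions by the generator — the
interpretability claim the package is built around. Merging the top paths
gives the intra-cell network:

```r
net <- extract_intra_network(res$mean_I, fx$path_list, fx$db, K = 5)
#> comm_network (intra): 22 nodes, 17 edges
write_sif(net, "intra.sif")
```

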