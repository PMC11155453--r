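---
title: "Path-centric communication inference: model, priors, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path-centric communication inference: model, priors, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its method: what is modelled,
which knobs matter, what the synthetic benchmark does and does not show, and
where the design was genuinely open and a choice had to be made.

## 1. The interaction graph and its nine edge categories

The graph is assembled from three raw resources — ligand–receptor edges,
signaling edges, and gene-regulation edges — plus a transcription-factor
list. Classification is purely rule-based and deterministic:

* Ligands and receptors are the sources and targets of the LR table; a gene
  may hold both roles. An LR interaction present in both directions becomes
  one `LR_bidirectional` edge stored in lexicographic orientation (and
  traversable both ways during path sampling); all others are
  `LR_directional`.
* TFs are the supplied list minus any gene that is a ligand or receptor.
* Regulation edges are kept only when their source is a ligand, receptor or
  TF and are labelled by that role. When a source holds several roles, the
  priority is receptor > ligand > TF: receptors anchor the downstream path
  machinery, so the receptor reading is the one that keeps information.
  This situation is not covered by the classification rules themselves; the
  priority is this package's choice and is logged whenever it fires.
* Signaling edges already present in the LR or regulation sets are removed,
  and the remainder are labelled `receptor_TF`, `receptor_signaling`,
  `signaling_TF` or `signaling_signaling` by endpoint roles; edges that fit
  none of the four patterns (for example a TF source with a plain target)
  are dropped.
* Self-loops are removed at load: they would generate degenerate paths.
* Gene symbols are case-sensitive and never mapped across species;
  identifier mapping is the caller's responsibility.

Two invariants are asserted on every build: each retained edge has exactly
one category, and the signaling categories never overlap the LR or
regulation sets.

## 2. The predefined path list

Paths are node sequences anchored at receptors with 3–10 nodes; a single
receptor-regulation edge is admitted as a length-2 path. Two samplers are
provided:

* **all tied-shortest paths** from every receptor to every reachable gene
  (BFS; *all* geodesics per pair, not one representative), and
* **all simple receptor→target paths** by depth-limited enumeration, where
  the default target set is "genes regulated by TFs that hold no
  ligand/receptor/TF role" (the notion of a path's endpoint is otherwise
  undefined; a user-supplied target list overrides this).

Receptor-anchored enumeration to targets is the default mode. Simple-path
enumeration is combinatorial, so each (receptor, target) pair is truncated
at `cap_per_pair = 1000` with a logged warning; a run that trips the cap is
flagged because truncation affects reproducibility claims. Both samplers
deduplicate by gene sequence (first labelling wins) and order the result by
the gene-sequence tuple, so a fixed graph always yields a byte-identical
path list. The test suite proves both samplers equal to an independent
brute-force enumerator on random digraphs.

## 3. Model architecture

With `n` genes, `L` layers, hidden width `h_emb`, `h` heads
(`d_k = h_emb/h`) and `r` score sets (`u = h_emb/r`):

* **Input embedding.** `H0_u = E_u + x_u·w + Z_in[deg_in] + Z_out[deg_out]`,
  where `E_u` is a learned gene-identity vector and `x_u` the cell's
  log-normalized expression of gene `u`. The raw formulation feeds only
  expression; adding the identity embedding keeps two genes distinguishable
  when their expression coincides, which the attention bias tables then
  refine. Degree buckets are clipped at 64.
* **Node encoder.** Standard pre-LN multi-head self-attention plus a
  position-wise FFN with hidden width `h_emb` (both sublayers with residual
  connections and dropout). Attention logits receive two additive biases
  shared by every cell: the *direct-edge encoding*
  `c_uv = x_cat(u,v)·w_head` (with a learned no-edge row, so absence of an
  edge is itself informative) and the *node-index encoding*, a free `n×n`
  table per head and layer (`node_index_mode = "low_rank"` factors it as
  `a bᵀ` with rank 8 for graphs beyond a couple thousand genes). Whether
  the original design used layer normalization at all is unstated;
  `layer_norm` is a config switch, on by default because pre-LN is the
  stable default for small-batch transformer training. The FFN's first bias
  is taken at width `h_emb` (its printed dimension `2·h_emb` is inconsistent
  with the stated hidden size and is treated as a typo).
* **Path encoder.** Per layer: scatter `H^l` into the `k` path slots, project
  to width `u`, add path-positional (position ≤ 10) and edge-type (9
  categories; the last slot gets none) encodings, score each slot into `r`
  sets through `tanh(Ū W_s1 + b_s1) W_s2 + b_s2` (hidden width `r`),
  softmax within each path per set, and scatter-sum the score-weighted
  slot embeddings, flattening the `r` sets into `h_emb`. Whether the path
  encoder's weights are shared across layers is ambiguous in the original
  description; per-layer weights are used (the layer superscripts suggest
  so).
* **Graph encoder.** `I = sigmoid(M)` with `M` initialized at zero (every
  path starts at importance 0.5), `g^l = Iᵀ P^l`, element-wise max over
  layers (ties resolve to the earliest layer), then a linear softmax
  classifier.

Everything — forward and backward — is dense matrix algebra in R. The
backward pass is hand-derived; a finite-difference check over every
parameter tensor is part of the unit tests, which is the strongest
correctness evidence the package offers. Per-batch scatter plans (flat
indices and sparse aggregation operators) are memoized on the graph
context, which is what makes the path encoder affordable at thousands of
path slots.

## 4. Losses, priors, and two deliberate interpretation choices

The objective is `L = L_class + β·L_reg`. `L_class` is the NLL of the true
condition (probabilities clamped at 1e-12); the optimizer uses the mean per
batch, which differs from the summed form only by the constant batch size
— but note this makes the effective trade-off against `β`
interpretation-dependent, so `β` values should be read relative to this
package's convention.

The prior path score in mode `up`/`down`/`deg` is the per-path mean of
(signed / negated / absolute) gene log fold change, min-max normalized
across paths (all 0.5 if degenerate). Fold change is the difference of mean
log-normalized expression (test − control); inputs are assumed already
log-normalized, so no pseudo-bulk count ratio is involved. During the
repeated protocol the prior is computed from the training split only.

`L_reg` is declared as a KL divergence between `I` and the prior score
vector — but neither vector is a distribution, so the formula admits two
readings, both implemented:

* `"bernoulli"` (default): each score is read as an independent
  probability and the element-wise Bernoulli KL terms are summed. The
  gradient on each path score is O(1) whatever the path count.
* `"distribution"`: both vectors are renormalized to distributions over
  paths (1e-8 smoothing) before a standard KL. Its per-path gradient
  carries a `1/sum(I)` factor — about `2/p` at initialization — so with
  hundreds of paths the regularizer is numerically unable to reorder the
  scores within a realistic epoch budget. This reading is kept because it
  is the textbook KL, but it is not the default for exactly that reason.

**Optimizer.** The network weights use Adam (standard for transformers at
the configured learning rate; the original description names no
optimizer). The path-score vector `M` is deliberately updated by plain
gradient descent instead: Adam's per-coordinate normalization moves every
coordinate with a consistently-signed gradient at roughly the same rate
regardless of gradient magnitude, which collapses the learned importance
to a sign pattern and erases the graded ordering the prior is supposed to
impose. Plain SGD keeps score differences proportional to accumulated
gradient magnitude, so the final ranking reflects both the prior and the
classification signal. This was measured, not conjectured: under full Adam
the planted-path benchmark recovers 4/20 with all top scores tied; under
the mixed rule it recovers 20/20.

**Protocol defaults** follow the study design: 0.7/0.1/0.2 random splits,
five repeats with fresh splits and fresh parameters, 30 epochs, learning
rate 5e-4, dropout 0.1, `β = 0.1`, AUC-based model selection with ties
keeping the later checkpoint, batch size 32 (unstated; config-exposed),
threshold 0.5 for the confusion-matrix metrics, repeat seeds derived from
the protocol seed and recorded in the result.

## 5. The synthetic benchmark: what it emulates and what it does not

The generator builds a layered graph (ligands → receptors → signaling →
TFs → targets, every receptor guaranteed an incoming LR edge) with
`n_planted_paths` gene-disjoint receptor→target routes of 3–6 nodes plus
random background edges, then simulates log-scale expression: per-gene
baselines `N(1, 0.5²)`, gene noise of sd `noise_sd`, a per-cell offset
emulating depth variation, zeroing at `dropout_rate`, and a mean shift of
`effect_size` on every planted-path gene in the test condition (half the
paths shifted down under `signed = TRUE`). Because zeroing hits both
conditions, the realized fold change is attenuated to
`(1 − dropout_rate)·effect_size`; the truth object records both the
planted shift and this expected value.

Two constructions keep the ground truth *identifiable*, which the recovery
metric silently requires:

* background edges never connect two planted-route genes, so the only
  receptor→target path drawn entirely from planted genes is the planted
  route itself;
* planted selection rejects any candidate family whose gene union fully
  contains some other path in the list (such a path would be exactly as
  differentially expressed as a planted one, making "recovery" ill-posed).

This is also the benchmark's main departure from real data: in real
signaling networks, differential paths overlap and interleave, and no
ranking can single out one of several gene-equivalent paths. Passing the
recovery benchmark therefore shows the machinery works end-to-end — it
does not show that real cohorts admit uniquely attributable paths. Other
simplifications: gaussian log-scale noise rather than negative-binomial
counts (the model consumes log-normalized values, and the gaussian form
keeps the planted truth analytically transparent), no batch effects, no
cell-type mixture.

Standard conditions: the `recovery` fixture uses 200 genes, 20 planted
paths, 500 cells per condition, `effect_size = 1.0`, `noise_sd = 0.5`,
10% dropout, background density 0.01 (chosen so the sampled list holds
comfortably over 200 paths across seeds), and its predefined list is
sampled with a 6-node bound matching the span of the planted routes. The
`small` fixture (60 genes, ~30 paths, 200 cells) is the integration-test
size; `tiny` (6 genes, 3 paths, 20 cells) is handcrafted for unit tests.

## 6. Benchmark protocol and problem sizes

The end-to-end checks train a reduced configuration — `L = 2`,
`h_emb = 32`, 2 heads, 4 score sets — for 8 epochs at batch 64 with
`β = 1.0` and the `deg` prior, three repeats with different splits. Two of
these choices deserve their rationale:

* `β = 1.0` rather than the 0.1 default: the reduced runs take roughly two
  orders of magnitude fewer optimizer steps than a full cohort run, and the
  score vector accumulates prior signal linearly in step count while split
  noise accumulates as its square root; the stronger printed
  regularization value is the appropriate setting at this scale.
* 8 epochs at batch 64: validation-selected checkpoints saturate the
  classification task well before this on the benchmark; further epochs
  only refine `I` marginally.

On one CPU the three-repeat benchmark takes roughly ten minutes; the
acceptance script runs two repeats in about six.

## 7. Network construction

Intra-cell networks merge the edges of the top-`K` paths by run-averaged
importance (descending, ties broken by ascending path id — stable and
deterministic), recording supporting path ids per edge; `K = 300` is the
default for biological use and `K`-nesting is monotone by construction.
The score-quality diagnostic compares the mean absolute fold change of the
top-`n` paths against the remainder. DEG calling for ligand candidates
uses the single-cell convention — two-sided Wilcoxon rank-sum,
Benjamini–Hochberg, `|log fc| > 0.25`, adjusted p < 0.05 — because the
original description names no test or thresholds; an `up_only` flag
restricts candidates to upregulated ligands, off by default. Inter-cell
networks add every LR edge whose ligand is a DEG-ligand of the ligand cell
and whose receptor sits in the receptor cell's intra network; an empty
link set is a warning, not an error.

## 8. Known limitations

* Dense `n×n` node-index tables are quadratic in the model gene set; the
  model gene set is therefore restricted to genes appearing in the path
  list, and the low-rank factorization is offered beyond a few thousand
  genes. Full-transcriptome attention is out of scope.
* The KL direction, the NLL reduction, and hence the meaning of `β` are
  interpretation choices; comparisons of `β` across implementations are
  not meaningful.
* Wall-clock cost is dominated by the path encoder (`B·k` slot rows per
  batch); path lists with very long paths or tens of thousands of paths
  call for the `cap_per_pair` truncation, a tighter length bound, or a
  restricted gene set.
* The recovery benchmark certifies machinery, not biology: real intra-cell
  networks must be read as rankings over entangled, partially confounded
  paths, with the stability diagnostic (cross-repeat Spearman) as the
  practical reliability check.
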