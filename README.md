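# omicbridge

Graph-guided embedding for **unpaired single-cell multi-omics
integration** and regulatory inference, in pure R.

Single-cell RNA-seq, ATAC-seq and DNA-methylation experiments measure
different cells and live in different feature spaces (genes, peaks,
methylation sites), yet they sample the same underlying cell states.
omicbridge aligns such datasets *without* feature conversion and
*without* known cell pairing ("diagonal integration"), for analysts who
want a shared embedding of cells across modalities plus data-driven
peak–gene (and methylation–gene) regulatory scores.

## The model

Each omics layer k gets a variational autoencoder over a shared latent
cell state u ∈ R^m. A prior-knowledge **guidance graph** over the union
of all feature spaces — signed, weighted edges such as "this peak
activates that gene" (+) or "gene-body methylation represses it" (−) —
is itself modelled by a graph-convolutional variational encoder that
yields one embedding v_i per feature, decoded by
σ(s_ij v_i'v_j) against negative samples. Data decoders reconstruct
each layer from the inner products v_i'u:

* counts (RNA/ATAC): NB(x; μ, θ) with
  μ = softmax(α_b ⊙ V_k'u + β_b) · Σ_j x_j (library size preserved
  exactly; α, β, θ batch-specific),
* methylation levels: zero-inflated log-normal with
  μ = α ⊙ V_k'u + β.

An adversarial discriminator classifies the omics layer of each cell
embedding and the encoders are trained to defeat it, with per-cell
**balancing weights** w_i = Σ_matched cos⁴(u_i,u_j)/n_i (matches =
centroid cosine > 0.5) protecting against unequal cell-type
compositions, and annealed embedding noise stabilising the first
training stage. Everything — including all gradients — is implemented
in base-R matrix algebra; no deep-learning runtime is required.

After training, cosine similarities of feature embeddings are
**regulatory scores** (significance via shuffled-embedding permutation
null + BH FDR), and the **integration consistency score** (guidance
edges correlated across jointly clustered metacells) diagnoses
over-integration. A full benchmark suite — FOSCTTM, MAP, cell-type and
omics-layer silhouettes, Seurat alignment score, graph connectivity,
neighbour/feature consistency, and the 0.6/0.4 overall score — is
included, each metric tested against a brute-force reference.

## Worked example

```r
library(omicbridge)

# a synthetic two-layer dataset with known ground truth
sim <- simulate_multiomics(sim_config(
  n_types = 4, cells_per_type = 60, n_genes = 100, n_peaks = 150,
  m_true = 8, seed = 21))

cfg <- glue_config(m = 8, hidden = 64, hidden_disc = 64,
                   hidden_graph = 64, r_reduce = 30, minibatch = 64,
                   anneal_iters = 600, patience_lr_iters = 200,
                   patience_stop_iters = 400, max_iters = 2400, seed = 5)
fit <- fit_glue(sim$layers, sim$graph, cfg)

emb <- get_embeddings(fit)
foscttm(emb$cells$rna, emb$cells$atac)
#> [1] 0.01327083
all_emb <- rbind(emb$cells$rna, emb$cells$atac)
seurat_alignment_score(all_emb, rep(c("rna", "atac"), each = 240))
#> [1] 1
mean_average_precision(all_emb, rep(sim$truth$types, 2))
#> [1] 0.9980952
```

FOSCTTM (fraction of cells closer than the true match) is ~0.5 for an
uninformative embedding and 0.013 here: cross-modal neighbours are
almost always the truly paired cells. The alignment score 1 means the
two layers are fully interleaved, and MAP ≈ 0.998 means cell types
stay cleanly separated in the shared space.

Regulatory inference on the fitted model:

```r
V <- coef(fit)                         # feature embeddings
pairs <- data.frame(feature_i = sim$truth$planted_edges$i,
                    feature_j = sim$truth$planted_edges$j)
tab <- regulatory_scores(V, pairs)
tab <- regulatory_significance(tab, V, n_shuffles = 1000, seed = 1)
head(tab[order(tab$q), ])
```

A command-line front-end wrapping the same functions ships in
`inst/scripts/omicbridge-cli.R`
(`simulate`, `graph-build`, `graph-corrupt`, `train`, `embed`,
`reg-infer`, `consistency`, `metrics`, `transfer-labels`).

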