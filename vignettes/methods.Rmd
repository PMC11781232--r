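---
title: "Methods: annotating cell types from subcellular transcript arrangements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating cell types from subcellular transcript arrangements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Imaging-based spatial transcriptomics platforms — MERFISH, CosMx SMI,
Xenium — resolve individual RNA molecules at subcellular resolution.
Standard cell type annotation collapses each cell to a gene-count vector
and discards where the molecules sit. Yet transcripts are not placed
uniformly: localization to the perinuclear region, the cell periphery, or
discrete foci is gene- and cell-state-dependent. Two cells can share a
count profile and still be different cell types if their transcripts are
arranged differently. This package annotates cell types from that
arrangement, semi-supervised: a labeled reference set and an unlabeled
query set from the same panel are trained jointly, and the query cells
are then assigned types.

## The model

### Gene neighborhood networks

Each cell becomes a graph. Nodes are its transcripts, carrying one-hot
gene identity (dimension = panel vocabulary size); edges connect
transcript pairs within Euclidean distance `d`. `d` is a platform
property, exposed via `platform_preset()`: 12 pixels for CosMx
(≈2.16 µm at 0.18 µm/pixel), 2 µm for MERFISH, 3 µm for Xenium.
The intent is a mean degree in roughly the 10–30 band —
`build_cell_graphs()` warns outside it. Construction uses a uniform grid
bucket index (linear in points for bounded density) and an optional
mutual-k cap (`k_cap`) for pathologically dense regions; the test suite
validates both against a brute-force quadratic oracle. Each graph is
partitioned into "RNA communities" — spatially coherent transcript
neighborhoods — by Louvain modularity clustering (`igraph`), with the
partition seeded and canonically relabeled so results are reproducible.

### Learnable augmentation scores

Contrastive learning needs augmented views, and uniform random
perturbation is a poor prior here: destroying the arrangement of a
discriminative transcript neighborhood destroys the signal itself. The
model therefore *learns* what to perturb. A GIN (graph isomorphism
network) scorer embeds the raw graph's nodes; two small heads (one for
dropping, one for masking) map each node embedding to two logits
(augment / keep) passed through Gumbel-Softmax sampling at temperature 1.
The per-node score is

```
p_v = (1 - y_drop) + (1 - y_mask)  in [0, 2],
```

the aggregate probability of being kept by the two operators. Edge keep
probabilities average the endpoint scores, `(p_u + p_v)/2 / 2`; community
scores `p_S` are member means. In evaluation mode the Gumbel noise is
dropped (plain softmax), making scores deterministic — these eval-mode
scores are the interpretability output of the package
(`node_scores()`, `gene_importance()`, `subgraph_scores()`).

Five operators compose a policy, applied coarse-to-fine:
inter-community edge perturbation, community swap, node dropping, node
masking, within-view edge perturbation. `augment_policy("all")` is the
default; `augment_policy("identical")` is the control policy, and the
test suite asserts it is an exact fixed point of the pipeline.

### Encoder and objective

Views are encoded by a residual GCN: layer 1 projects one-hot features to
the hidden width through the symmetric-normalized adjacency
`D^{-1/2}(A+I)D^{-1/2}`; layers ≥ 2 add residually,
`H' = ReLU(Â H W) + H`, with inverted dropout between layers in training
mode. Sum pooling yields the cell embedding, which is invariant to node
relabeling (tested to 1e-5).

Training minimizes `L = L_cl + λ · L_cls` per batch. `L_cl` is NT-Xent
over the 2N views (cosine similarity, temperature τ = 0.5): positive
pairs are the two views of one cell, everything else in the batch is a
negative. `L_cls` is cross-entropy of the labeled cells' class logits.
The classifier reads the *L2-normalized* graph embedding — the same
cosine geometry the contrastive loss organizes — which also makes logits
invariant to the systematic magnitude difference between augmented
training views (fewer, partly masked nodes) and the full identity view
used at inference.

All gradients are computed analytically in R (no autodiff framework is
used); the suite verifies them against central finite differences.
Optimization is Adam with bias correction.

## Design decisions the objective does not pin down

Three choices stabilize joint training of the scorer, encoder, and
classifier. They are deliberate, documented here because the combined
objective alone underdetermines them:

1. **The supervised loss includes the identity view.** Cross-entropy is
   computed on both augmented views *and* the un-augmented identity view
   of each labeled cell. Annotation encodes identity views; without this
   anchor the classifier fits augmented-view statistics and inference
   operates out of distribution (we observed training cross-entropy near
   0.07 with query accuracy at chance before adding it).
2. **Only the supervised loss drives the scoring heads.** Gradients reach
   the heads through a straight-through estimator: the hard keep/mask
   decision `w` multiplies the feature rows, and `dL/dw` is routed to the
   sampled probabilities. The contrastive term is excluded from this
   path: its degenerate optimum is to drop nearly everything, since
   near-empty views align trivially. Under the supervised signal a node's
   keep score means "how much this transcript contributes to recognizing
   the cell's type" — which is exactly the interpretation the
   importance tables give it.
3. **Scoring heads read directions, not magnitudes.** GIN embeddings are
   row-normalized before the heads. Unnormalized embedding norms grow
   with node degree and saturate the sigmoid, freezing scores at their
   early random values. The backward pass chains through the
   normalization Jacobian `dH = (dU − U⟨dU, U⟩)/r`.

An optional keep-rate regularizer (`train_config(keep_reg = )`,
default 0) penalizes the mean augmentation probability. It is off by
default: with the identity-view anchor it is unnecessary, and a strong
penalty pushes keep probabilities into sigmoid saturation where the score
gradient vanishes — in our experiments that froze marker rankings at
noise while leaving accuracy intact. It remains available for custom,
unusually aggressive policies.

The head biases initialize the augment logit at −2.2 (≈0.9 initial keep
probability per operator), the standard mild-perturbation starting regime;
head weights are scaled-down Glorot draws so initial scores vary smoothly
around it.

## Parameters and defaults

| Parameter | Default | Rationale |
|---|---|---|
| `d` (connection radius) | platform preset (12 px / 2 µm / 3 µm) | target mean degree 10–30 |
| `alpha` (QC threshold) | 50 (CosMx, Xenium), 100 (MERFISH) | platform transcript yield |
| `tau` (NT-Xent) | 0.5 | standard contrastive temperature |
| `lambda` | 1 | 1 and 5 perform equivalently in our runs |
| `batch_size` | 32 | 2N = 64 views per contrastive batch |
| `lr` | 5e-4 | Adam; desk-scale runs in this document use 1e-3 |
| `epochs` | 50 | fixed-epoch training, no early stopping |
| `hidden` | 128 | tuned operating point; 16–64 appropriate for small panels |
| `dropout` | 0.3 | between ResGCN layers, training only |
| `gumbel_temperature` | 1 | softmax sharpness of the sampled scores |

Small synthetic panels (20 genes, a few hundred cells) train well at
`hidden = 16–32`, `lr = 1e-3`, 15–30 epochs — that is what the test
suite and `scripts/acceptance.R` use to keep runtimes in minutes.

## The synthetic generator

`simulate_cells()` provides ground-truth data scaled to desk experiments:
cells are disks (radius 7 µm) on a grid with per-type transcript counts
drawn negative-binomial (mean 150, size 20 — overdispersed like imaging
panels), gene identities multinomial per type, and per-gene subcellular
*niches*: `niche_uniform()`, `niche_ring(r_in, r_out)` (perinuclear or
peripheral), `niche_cluster()` (discrete foci). A background fraction
(5%) is placed uniformly regardless of niche, negative-control probes
(3%, `NegPrb###`) exercise the QC path, and coordinates carry Gaussian
jitter (σ = 0.1 µm).

`make_benchmark()` wraps four presets. The central one, `"spatial-only"`,
gives two types *identical* gene frequencies (marker `g01` at 25%) and
moves only the marker's niche: perinuclear ring for TypeA, peripheral
rim for TypeB. Any count-based method is at chance by construction — the
suite asserts a multinomial-logistic count baseline stays in [0.4, 0.6] —
while the graph model reads the arrangement directly. `"mixed"` plants
one niche-marker per type on top of distinct count profiles, and
`"reference-fraction-sweep"` provides nested stratified reference subsets
(10/40/70/100%) for label-efficiency experiments.

Realism limits, explicitly: cells are circular and non-touching; niches
are radially symmetric functions of one gene at a time; there is no
segmentation error, no z-axis, no cell-cell signal spillover, no
spatially correlated background, and counts are independent across genes.
The generator is built for controlled recovery experiments, not for
mimicking any platform's full noise structure.

## Numerical choices

- NT-Xent and softmax use max-subtraction log-sum-exp stabilization.
- The NT-Xent gradient is computed in closed form including the cosine
  normalization Jacobian; cross-entropy uses `(P − Y)/n`.
- Checkpoints serialize to JSON text (`save_model()`); decimal round-trip
  reproduces parameters to 1 ulp. Exports are plain text (CSV/TSV/
  GraphML/`.rnk`).
- All stochastic stages (simulation, partitioning, initialization,
  batching, Gumbel noise, dropout) are seeded through `withr::with_seed`;
  two runs with one seed are bitwise identical.

## Limitations

- Training is O(cells × epochs × n² hidden) in dense per-cell adjacency
  operations; hundreds of cells and tens of genes train in minutes on one
  core, but platform-scale panels (≈1000 genes, 10⁵ cells) need the
  documented defaults and patience, or a subsampled reference.
- The straight-through estimator is biased; score gradients are heuristic
  (exact gradients through discrete graph edits do not exist).
- Reference and query must share a gene panel and coordinate scale;
  cross-platform transfer is not attempted.
- Louvain partitions are resolution-dependent; community-level operators
  and scores inherit that dependence.
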