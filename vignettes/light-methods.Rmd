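---
title: "Knowledge-guided line-graph transformers for molecular representation learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-guided line-graph transformers for molecular representation learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Molecular property prediction from SMILES suffers from scarce labels;
self-supervised pre-training on unlabelled molecules is the standard remedy.
This package implements a line-graph transformer (LiGhT) with a
knowledge-guided masked-graph pre-training objective.

**Line graphs.** A molecule is first parsed into a heavy-atom graph
$\mathcal{G}=(\mathcal{V},\mathcal{E})$ (hydrogens implicit). The encoder
does not operate on atoms but on the *line graph* $\hat{\mathcal{G}}$: one
node per chemical bond, with two nodes adjacent iff their bonds share an
atom. This puts bond features on the same footing as atom features — each
line-graph node $\hat v_{i,j}$ carries the raw triple
$(x^v_i, x^v_j, x^e_{i,j})$ and is embedded as

$$h_{\hat v_{i,j}} = \mathrm{concat}\!\left(W_v x^v_i + W_v x^v_j,\; W_e x^e_{i,j}\right),$$

which is symmetric in the two endpoint atoms. A single-atom molecule yields
a one-node line graph storing the atom features twice with a zero bond
vector, so every parseable molecule is encodable.

**Structural attention biases.** A plain transformer ignores connectivity,
so two biases are added inside every attention head:

- *path encoding*: for each reachable node pair, the stored shortest path
  $(\hat v^p_1,\dots,\hat v^p_{N_p})$ is encoded as
  $a^p_{ij} = W^p_a \frac{1}{N_p}\sum_n W^p_n h_{\hat v^p_n}$, a per-position
  projection bank applied to the *initial* embeddings, averaged and
  projected to a scalar;
- *distance encoding*: $a^d_{ij} = W^d_2\,\mathrm{GELU}(W^d_1 d_{ij})$ on
  the hop count, clipped at 20 to keep the two-layer MLP's input bounded.

Attention is then
$\mathrm{softmax}(QK^\top/\sqrt{D_h} + A^p + A^d)$, followed by the
post-norm residual FFN
$\hat H = \mathrm{LN}(H^{l-1}+H^l)$,
$H^l = \mathrm{LN}(W_2\,\mathrm{GELU}(W_1\hat H)+\hat H)$ — the post-norm
form exactly as the layer equations are written, not the pre-norm variant.

**The knowledge node.** Each graph is augmented with one extra node
connected to all others, initialized from 712 numbers of "additional
knowledge": 200 molecular descriptors and a 512-bit hashed path-based
topological fingerprint. The K node gives the encoder a molecule-level
channel and anchors the semantic part of the pre-training objective.

## Design choices in detail

**Bias sharing.** The layer equations write $A^p$ and $A^d$ without layer or
head indices, so both matrices are computed once per graph from the initial
embeddings and shared across all layers and heads; a switch
(`recomputeBiasPerLayer`, inference-only) recomputes the path bias from each
layer's hidden states instead. K-node pairs and unreachable pairs (the line
graph of a multi-fragment molecule can be disconnected; distances then carry
a `-1` sentinel) bypass both encoders and use dedicated learned scalar
biases. The K node's universal connectivity would otherwise shortcut every
shortest path to at most two hops and destroy the structural encoding; a
huge sentinel distance would saturate the distance MLP.

**Shortest-path tie-breaking.** Breadth-first search distances are unique
but shortest paths are not. Ties are broken *canonically by node content*:
among equal-length candidate paths the one whose sequence of node-feature
keys is lexicographically smallest is kept (node index only as a final
fallback between content-identical nodes). An index-based tie-break would
make the path bias depend on the arbitrary node numbering and break the
encoder's permutation equivariance on substituted rings, where tied paths
pass structurally different nodes. Paths are truncated to their first
`maxPathNodes` (default 5) nodes because the per-position projection bank
$W^p_n$ is finite.

**Knowledge.** Descriptors come from a fixed 200-name registry: eight
OpenBabel physicochemical properties (MW, logP, TPSA, MR, H-bond
acceptor/donor counts, ...) plus 192 deterministic 2D graph descriptors
(element/ring/degree/bond counts, Wiener/Zagreb/Randić/Balaban/kappa/chi
indices, a topological distance histogram, adjacency/Laplacian/Burden
spectral terms, walk counts, and Moreau–Broto, centered, and Moran
autocorrelations over atomic mass, electronegativity, degree, charge,
aromaticity and hydrogen count). Descriptors that are undefined for a
structure (connectivity indices of a single atom, autocorrelations at
unrealized lags) yield non-finite values, never errors. The fingerprint is
OpenBabel's FP2 — hashed linear fragments up to seven atoms — folded from
1024 to 512 bits by OR-ing halves; a bond-less molecule has no paths to
hash and gets the zero vector.

Raw descriptors live on wildly different scales (molecular weight vs. a
0–1 fraction), and a regression loss on raw values would be dominated by
the large-magnitude ones. Descriptors are therefore standardized with
robust statistics — median location, IQR/1.349 scale, constant descriptors
get scale 1 — clipped at ±10 z-units, with non-finite values imputed to 0
after centering. The normalizer is fit on the pre-training corpus and
persisted inside every checkpoint.

**Pre-training objective.** Each base node is selected independently at
rate 0.5; selected nodes are replaced by a learned mask token, by a random
node drawn from the current batch's node pool, or kept, at 8:1:1. Knowledge
entries are masked independently at the same rate (plain masking with a
parallel 0/1 indicator channel projected into the K-node embedding — the
8:1:1 scheme applies to nodes only). The loss is the unit-weighted sum of
(i) mean cross-entropy of recovering the original node *type* — the
unordered element pair of the source bond plus its bond type, with a
reserved UNK class — over all selected nodes, (ii) RMSE over masked
descriptor entries only, and (iii) mean binary cross-entropy over masked
fingerprint bits only. The mask token lives in embedding space: raw one-hot
space has no natural learnable token, and a zero vector would be
indistinguishable from genuinely zero features. Random replacement samples
from the mini-batch pool rather than a corpus-wide store; the batch
approximates the corpus node distribution at negligible cost.

**Optimization.** Decoupled-weight-decay Adam (reference setting: learning
rate 2e-4, weight decay 1e-6); truncated-normal initialization
($\sigma = 0.02$, resampled beyond $2\sigma$) for projections, zeros for
biases and bias scalars, unit layer-norm gains; dropout (default 0.1) on
attention weights and FFN hidden units during training only. The forward
and reverse passes are written directly in base R matrix algebra; gradients
of every parameter bank are verified against central finite differences in
the test suite.

**Finetuning strategies.** Four independently switchable strategies
transfer the pre-trained encoder: LLRD (geometric layer-wise learning
rates — head and top layer at the base rate, layer $i$ from the top at
$\gamma^i$, the embedding block at $\gamma^L$; conventional
$\gamma = 0.95$), ReInit (re-initialize the top $n$ layers, audited to
change exactly those parameters), FLAG (adversarial perturbation of the
post-embedding node features: $\delta$ starts at zero and takes $m$ ascent
steps of size $\alpha$ along the normalized loss gradient, the loss
averaged over steps, so $\|\delta\|_\infty \le m\alpha$ and $m=0$ is
exactly the plain step; perturbing discrete one-hot inputs would be
ill-defined), and L2-SP ($\lambda\|\theta-\theta_{\mathrm{ref}}\|^2$ over
encoder parameters, head excluded since it has no pre-trained reference).
Feature extraction freezes the encoder entirely and reads pooled
evaluation-mode embeddings as *neural fingerprints*, probed with an exact
Euclidean kNN vote (neighbour ties broken by the smaller training index).

**Pooling.** The readout averages all final node embeddings. Whether the K
node belongs in the average is ambiguous ("all the nodes"); it is included
by default and configurable (`poolIncludeK`).

**Evaluation machinery.** Scaffold splits group molecules by Bemis–Murcko
framework (iterative pruning of degree-1 atoms; acyclic molecules form
singleton groups keyed by canonical SMILES so no giant empty-scaffold group
forms), order groups by size descending with ties broken by the scaffold
string, and fill train to ≥80%, then valid to ≥10%, remainder test — whole
groups only, so realized ratios are approximate. Metrics use exact
rank-based formulas: AUROC via average ranks (ties get half credit,
verified against a brute-force pairwise-concordance oracle), AUPRC as
average precision, plus RMSE/MAE/Spearman/Pearson for regression, with
pairwise missing-label exclusion and per-task-then-mean aggregation.

## The fixture generator

Tests and desk-scale runs use a closed deterministic grammar instead of
downloaded corpora: a ring core drawn from 28 aromatic, heteroaromatic,
saturated, fused, spiro and linked bicyclic systems, prefixed by up to
`complexity` chain fragments (alkyl, carbonyl, ester, amide, ether, amine,
thioether) and an optional terminal substituent (halogens, hydroxyl, amino,
trifluoromethyl, nitrile — valence-saturating groups may only open the
string). Every generated string parses; at $n \ge 100$ the set covers ≥20
distinct Murcko scaffolds with overwhelming probability. Synthetic labels
are a stated function of a computed descriptor (logP above the set median,
or logP itself for regression), so downstream tasks are learnable by
construction.

What the generator does *not* emulate: real pharmacological label noise,
activity cliffs, stereochemistry, tautomerism, large macrocycles, or the
scale and diversity of a multi-million-molecule corpus. Passing tests
demonstrate that the machinery is correct and that the objective is
learnable at desk scale — not that desk-scale pre-training transfers to
real assay endpoints.

## Problem sizes and numerical choices

The test suite and the reproduction script run everything at desk scale, a
deliberate configuration of this package: oracle checks on 200 generated
molecules; a 2-layer, 128-hidden, 4-head encoder pre-trained on 200
molecules for 200 steps (batch 128, peak learning rate 3e-3 with a 40-step
linear warmup, cosine decay, global gradient-norm clipping at 1, and
Polyak averaging of the last quarter of the iterates — desk-scale choices
replacing the reference constant 2e-4, which is tuned for batch 1024 and
100,000 steps; short post-norm transformer runs underfit badly without
warmup, and the averaged iterate is a lower-variance endpoint); an
end-to-end
fixtures → scaffold split → pretrain → finetune →
extract → kNN pipeline on 60 molecules run twice under one seed to verify
bit-identical metrics. The reference configuration (12 layers, 768 hidden,
12 heads, ~10^8 parameters) is instantiated and counted but not trained.

Numerical details: layer-norm uses population variance with eps = 1e-6;
GELU is the exact Gaussian-CDF form $x\Phi(x)$; softmax is max-shifted; the
RMSE gradient is guarded at zero loss; descriptor failures propagate as
non-finite values and are neutralized by the normalizer; all randomness
(plans, corruption, batching, dropout, initialization) flows from explicit
seeds through a single restored-RNG helper, and every character ordering
(vocabulary keys, scaffold groups, path tie-breaks) uses locale-independent
radix sorting, so runs are bit-reproducible across environments.

## Known limitations

- OpenBabel's perception drives aromaticity, canonicalization and
  hybridization; molecules outside its organic-subset assumptions (exotic
  valences, organometallics) degrade to "other" feature slots.
- Chirality uses molfile parity codes, which OpenBabel rarely emits from
  plain SMILES; stereo-dependent properties are effectively out of reach.
- The descriptor registry is a documented substitution, not a bit-exact
  reproduction of any other toolkit's 200 descriptor names.
- Training is single-threaded base R; it is meant for desk-scale
  experiments, not the multi-GPU pre-training regime the architecture
  supports in configuration.
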