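---
title: "Structure-aware protein language modelling with graph adapters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-aware protein language modelling with graph adapters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pst)
```

## The model

Protein language models learn residue representations from sequence alone.
This package augments such a model with explicit structural knowledge at
minimal parameter cost.  The protein is represented twice:

* as a token sequence `<cls> x_1 ... x_n <eos>` over a 25-token vocabulary
  (20 canonical amino acids, `X`, and four specials), and
* as an *ordered contact graph* `G`: one node per residue, in sequence
  order, labelled with the amino-acid type, with an edge between residues
  whose representative-atom (CA) distance is at most a threshold
  (default 8.0 Å, the range that captures most local inter-residue
  interactions).

The backbone is an encoder-only transformer.  At each block, token states
`X` are normalized and projected to queries, keys and values
(`Q = X W_Q`, etc.), rotary position embeddings rotate `Q` and `K` so
attention logits depend only on relative position, and the block output is
the usual skip + feed-forward composition `X'' = X' + FFN(X')` with
`X' = X + Attn(X)`.

The structural augmentation attaches, to **every** attention block, a small
graph isomorphism network (GIN) `phi_theta`.  It reads the same normalized
residue states that feed that block's Q/K/V projections, runs two rounds of
message passing over the contact graph,

```
h_i <- MLP( (1 + eps) * h_i + sum_{j in N(i)} h_j ),
```

and its output, through three `d x d` injection matrices, is added to the
projections:

```
Q_s = Q + phi_theta(X, G) W_Qs,   K_s = K + phi_theta(X, G) W_Ks,
V_s = V + phi_theta(X, G) W_Vs.
```

The injection matrices are **initialized at exactly zero**, so a freshly
assembled structural model computes, operation for operation, the same
function as its backbone.  This zero-initialization equivalence is the
package's primary internal oracle: `forward_pst()` on a new
`assemble_pst()` model agrees with `forward_backbone()` to machine
precision, and the test suite asserts it over 100 random
(sequence, structure) pairs.

Because special tokens have no residue, `cls`/`eos`/`pad` positions receive
a zero structural term; the graph covers residue positions only.

## Pretraining

Training uses masked language modelling: a fraction of residue positions is
replaced by the mask token and the model is trained to recover the original
amino acids from the unmasked context, minimizing the mean
`-log p(x_i | x_without_M)` over masked positions.  Masking selects exactly
`max(1, floor(rate * n))` positions without replacement — a deterministic
count that makes contracts exactly testable and matches per-position
Bernoulli masking in expectation.  The default rate is 0.15, the standard
masked-LM choice; plain mask-token corruption is the default, with the
BERT-style 80/10/10 split available behind `corruption = "bert"`.

Optimization is AdamW (`beta1 = 0.9`, `beta2 = 0.98`, `eps = 1e-8`, decay
0.01 on weight matrices only) under linear warmup followed by
inverse-square-root decay: `lr(t) = base_lr * min(t/w, sqrt(w/t))`.

Two strategies exist.  `"full"` updates everything.  `"struct_only"`
updates only the extractors and injection matrices; backbone parameters
stay **bitwise** unchanged, which preserves a useful inference-time
property: bypassing the extractors (`bypass = TRUE`) reproduces the
original sequence model's computation exactly, so one model serves both
structural and sequence-only representations, and the two can be averaged
(`fuse_struct_seq()`).

Gradients are computed by a hand-written reverse-mode pass that mirrors the
forward computation (there is no autodiff framework dependency); it is
validated in the tests against central finite differences at relative
error below `1e-4`.

## Representations and variant scoring

`embed_protein()` mean-pools each block's residue states (special tokens
excluded) and concatenates the `L` means into a length `L*d` protein
vector; per-residue embeddings concatenate the per-block states.  Pooling
after the *full* block (post-FFN, post-skip) is used; the embedding-layer
output before the first block is not included, so the vector has exactly
`L*d` entries.

`score_variant()` scores a substitution `wt -> mut` at position `i` as a
log-likelihood ratio.  The default `masked_marginal` method masks the
token at `i`, runs the structural forward with the wild-type contact graph
(a mutation changes the residue identity, not the geometry), and returns
`log p(mut | context) - log p(wt | context)`.  Since the masked position's
identity never enters the computation, the score is exactly antisymmetric
under swapping wild type and mutant, and a self-substitution scores
exactly zero.  `wt_marginal` computes the same ratio from the unmasked
forward.  The literature uses several such likelihood statistics without a
single canonical choice; masked marginals are the most common convention,
which is why they are the default.

## Graph construction choices

* **Distance convention.** Inter-residue distance is CA–CA, the dominant
  convention for epsilon-neighborhood residue graphs.  Residues without a
  CA atom are skipped (with a warning) at parse time.
* **Indexing.** Nodes and positions are 1-based throughout, matching both
  R convention and mutation nomenclature (A42G).
* **Edge features.** Optionally, each edge carries a 16-dimensional
  Gaussian radial-basis expansion of its distance over centers evenly
  spaced in `[0, threshold]`, width equal to the spacing — a standard
  distance featurization.  Feature values lie in `(0, 1]` and peak exactly
  at the centers.  With features enabled the extractor modulates messages
  GINE-style: `m_ij = relu(h_j + e_ij W_e)`.
* **Perturbation modes.** For ablations, `perturb_graph()` can reduce the
  graph to sequential edges only, rewire it to a uniformly random simple
  graph with the same edge count, or complete it.  Perturbed graphs drop
  distance edge features, since the perturbed topology no longer
  corresponds to the geometry.
* **Sequential edges** appear in the base graph only when geometrically
  within threshold (at ~3.8 Å spacing they essentially always are), keeping
  the base graph purely geometric; `sequential_only` includes them
  unconditionally.

## Numerical and architectural decisions

Several details are unconstrained by the general block equations and were
fixed as follows:

* **Pre-layer-norm blocks** (normalization before attention and before the
  FFN), the modern encoder arrangement, for stability at small scale.  The
  zero-initialization oracle is unaffected by this placement.
* **GELU** feed-forward activation by default, mirroring the backbone
  family this design targets; ReLU is selectable
  (`backbone_config(activation = "relu")`) to match the generic transformer
  formulation literally.
* **GIN epsilon fixed at 0** (non-learnable), the standard default.
* **Extractors are independent per layer** by default; a shared-extractor
  mode exists for inference-time ablation but is rejected by `pretrain()`,
  where per-layer gradient bookkeeping assumes independence.
* **The extractor input** is the same normalized hidden state that feeds
  that block's Q/K/V projections — the minimal reading of "the residue
  embedding at the layer it is applied to".
* **Attention masking** uses a large negative additive constant (`-1e30`)
  rather than `-Inf`, keeping softmax rows NaN-free while driving padded
  keys to exactly zero weight after underflow.
* **Maximum sequence length** defaults to 1024 tokens; longer inputs are
  rejected rather than silently cropped.
* **Checkpoints** are JSON archives of a flat name-to-array map with 17
  significant digits, which round-trips IEEE doubles exactly — save/load
  is bitwise.
* **Weight import** (`import_backbone_weights()`) is a generic named-weight
  contract: shapes must match exactly, missing keys and transposed arrays
  are hard errors, unknown keys are reported.  Published-model vocabularies
  differ from the fixed 25-token vocabulary here; the contract requires
  matching shapes, not a particular vocabulary.

## Evaluation heads and metrics

`fit_head()` trains either a linear probe or a 3-layer MLP whose hidden
widths halve twice (`D -> D/2 -> D/4 -> K`), with dropout 0 or 0.5 after
each activation, binary cross-entropy, AdamW, and a plateau schedule that
halves the learning rate after 5 epochs without validation improvement
(validation metric: protein-centric Fmax for multi-label tasks, accuracy
otherwise).  The parameters achieving the best validation metric are kept.

The metrics follow the conventions standard in protein function
prediction: `fmax()` is the CAFA protein-centric maximum F-measure over a
0.01-spaced threshold grid (precision averaged over proteins with at least
one prediction, recall over proteins with at least one true term);
`aupr()` is micro-averaged over protein–term pairs with step-wise
summation and tie grouping, no interpolation; `mcc()` returns 0 for
degenerate denominators; `spearman_rho()` is Pearson on average ranks.
Each is tested against an independently coded brute-force oracle on over a
hundred random instances at `1e-9`.

## The synthetic-structure generator

`make_chain()` produces three idealized chain families with uniformly
random sequences: a parametric helix (radius 2.3 Å, rise 1.5 Å/residue,
twist 100°/residue — close to an ideal alpha-helix, placing `i, i+4`
neighbors within the 8 Å contact range), an extended collinear chain at
3.8 Å spacing (the canonical CA–CA distance), and a fixed-step random-walk
coil without self-avoidance (dense, sometimes colliding neighborhoods are
deliberate: graph code must tolerate them).  Generation is a pure function
of the spec: identical arguments give byte-identical structures.

`make_corpus()` mixes the three kinds and emits a one-hot label table of
generator kind — a structure-determined label for head smoke tests.
`make_mutagenesis()` plants a deep-mutational-scanning-style signal: each
sampled substitution's "experimental" score is the negative absolute
Kyte–Doolittle hydropathy difference (conservative substitutions tolerated)
plus seeded Gaussian noise (sd 0.25, roughly a quarter of the hydropathy
component's dynamic range).

What the generator does **not** emulate: real backbone geometry and
side-chain packing, realistic sequence composition or conservation
patterns, and any genuine sequence–structure coupling beyond the contact
geometry itself.  Passing tests therefore demonstrate that the machinery
is correct and trainable — masked-LM loss falls, structural information
flows, contracts hold — not that the learned representations transfer to
real proteins; that claim would require pretraining on real structure
databases at scale.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full cycle exercises every component: equivalence oracles use a
4-layer, 64-dimensional model over 100 random structures of 10–30
residues; the pretraining demonstration uses a 2-layer, 32-dimensional
model on a 20-structure corpus for 200 steps (peak learning rate `1e-3`,
20 warmup steps, batch size 4); graph oracles enumerate all pairs on 200
structures up to 50 residues at thresholds 4, 8 and 12 Å.  Parameter-budget
checks are closed-form shape arithmetic on configurations mirroring the
published 6-, 12-, 30- and 33-layer backbones; all come out near 1.58,
under the factor-2 budget.

## Known limitations

* Pure-R matrix computation: fine at fixture scale, not meant for
  production-scale pretraining.
* Single chain per structure; no mmCIF, hetero-atoms, insertion-code
  arithmetic or multi-model NMR handling.
* Batching pads to the longest sequence; no cross-protein attention and no
  cross-protein graph edges (by design), and no multi-device training.
* Scores from `score_variant()` are log-likelihood ratios, not calibrated
  to physical units.
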