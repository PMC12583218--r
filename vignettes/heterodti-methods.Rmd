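---
title: "Predicting drug-target interactions on heterogeneous graphs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-target interactions on heterogeneous graphs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Drug–target interaction (DTI) prediction asks, for a set of $m$ small
molecules $D$ and $n$ proteins $T$ with a sparsely observed binary
interaction matrix $Y \in \{0,1\}^{m \times n}$, which of the unobserved
pairs are likely to interact. Two features make the problem awkward for
off-the-shelf classifiers. First, the data are *positive–unlabeled* (PU):
$y_{ij} = 0$ means "not recorded", not "does not bind", so negatives must be
chosen, not read off. Second, most of the usable signal is relational —
chemically similar drugs bind similar targets, homologous proteins share
ligands — and lives in networks rather than in per-entity feature vectors.

`heterodti` addresses both. It builds a heterogeneous graph over drugs and
targets, learns embeddings with an attention-weighted multi-relational
graph-convolutional encoder, regularizes them against a biomedical
knowledge graph, and trains the interaction decoder with a
reliability-based PU negative-sampling scheme.

## Graph construction

For each drug pair, chemical similarity is the Tanimoto coefficient over
fingerprint bit sets; for each target pair, sequence similarity is the
Smith–Waterman local-alignment score normalized as
$\mathrm{SW}(a,b) / \min(\mathrm{SW}(a,a), \mathrm{SW}(b,b))$. The
normalizer is the smaller of the two self-alignment scores, which is the
largest score the cross-alignment can attain, so self-similarity is exactly
1 and all values lie in $[0,1]$. Similarity matrices are thresholded (default
0.5, overridable; a grid $\{0.3, \dots, 0.7\}$ can be swept from the trainer)
into binary adjacencies with self-loops removed — self-information re-enters
through the encoder's bias term. Multiple edge types of one class are
combined by a weighted sum with nonnegative weights (uniform by default,
learnable by the same meta-optimization used for dataset adaptation; the two
mechanisms are deliberately one and the same).

The unified adjacency is the block matrix
$\bar A = \begin{pmatrix} A_{DD} & A_{DT} \\ A_{TD} & A_{TT} \end{pmatrix}$
with $A_{DT}$ the *training* interaction matrix and $A_{TD} = A_{DT}^\top$.
Each block row is normalized with a softmax **restricted to the structural
support**: a softmax over a full dense row would assign equal attention to
all non-neighbors and erase sparsity, so unsupported entries stay exactly 0
and rows without any edge are all-zero (an isolated node keeps only its bias
term). Supported rows sum to 1 to within $10^{-8}$.

## The encoder

Raw features (fingerprint bit vectors for drugs; amino-acid composition plus
dipeptide frequencies, 420 dimensions, for targets) are first projected
linearly to the embedding width $h$ — the layer equations require a uniform
width, so the projection sits before layer 1. Each of $L$ layers then updates

$$Z_D \leftarrow \sigma\!\big(M_{DD} Z_D W_{DD} + M_{DT} Z_T W_{DT} + \mathbf 1 b_D^\top\big),$$

with the symmetric update for $Z_T$. The operator $M$ is the normalized
block, optionally modulated per edge by an attention weight
$\alpha_{ij} = \mathrm{sigmoid}(\mathrm{MLP}([z_i \| z_j]))$ (one hidden
layer of width $h$, shared across layers, one MLP per block). After the
elementwise product $\bar A \odot \alpha$ the rows are re-normalized over
the support by default: the raw product leaves rows sub-stochastic, which
destabilizes deeper stacks; re-normalization preserves the property that
each node's incoming weights sum to one. The un-renormalized behavior is
available via `renormalize_attention = FALSE`.

$\sigma$ is the rectifier on hidden layers and the **identity on the final
layer**. A terminal rectifier would force all embeddings nonnegative, making
every inner-product score nonnegative and every predicted probability at
least 0.5 — the refinement threshold of the negative sampler (0.5 on the
probability scale) could then never select a pair. A linear last layer is
the standard resolution and is what the package uses.

Interaction scores are inner products $\hat y_{ij} = z_{D_i}^\top z_{T_j}$,
with probabilities through a sigmoid. Cold entities (no interaction edges)
still receive embeddings through their similarity and auxiliary edges,
which is what makes cold-start prediction possible at all.

## Losses

Four components:

* **Weighted interaction loss.** With positive set $P$ and sampled negative
  set $N$ carrying importance weights $w$,
  $L_w = -\sum_{P} \log \sigma(\hat y) - \sum_{N} w \log(1 - \sigma(\hat y))$.
* **Reconstruction.** Decoder MLPs map embeddings back to the raw feature
  space; $L_{rec}$ is the summed squared error. This anchors embeddings to
  chemistry and sequence rather than letting them memorize $Y$.
* **Knowledge graph.** Triples $(h, r, t)$ are scored with the
  relation-diagonal bilinear form $f_r(h,t) = z_h^\top R_r z_t$ ($R_r$
  diagonal) and trained with a margin ranking loss
  $\sum \max(0, \gamma + f(h',t') - f(h,t))$ over corrupted triples
  (head or tail replaced uniformly at random, filtered against known
  triples). Entities that are drugs or targets share the encoder
  embeddings; pure ontology terms get free vectors of width $h$ trained
  only by this loss — the sharing is what lets ontology structure shape the
  predictive embeddings. A translational scorer
  $-\lVert z_h + w_r - z_t\rVert$ is available behind
  `kg_score = "transe"`, but the bilinear form is the default. The KG term
  is trained jointly with everything else under one optimizer; alternating
  updates added nothing in our experiments.
* **Adaptation regularizer** (optional, off by default for single-dataset
  runs): $\sum_k \alpha_k \lVert \tilde A^{k,D} - A^{k,global}\rVert_F^2$
  with $\alpha_k$ proportional to edge counts, used when dataset-specific
  subnetworks are filtered, CDF-reweighted and re-combined with meta-learned
  weights.

**Scaling.** As written, the importance weights sum to one over $N$ while
the positive term is an unnormalized sum, so the negative evidence would
carry the mass of a single pair. The optimizer therefore minimizes a
mean-reduced form: the positive term is averaged over the batch, the
reconstruction term divided by $m + n$, and the KG term by the number of
triples. This makes the trade-off weights `lambda_rec` (default 1.0) and
`lambda_kg` (default 0.1) scale-free; the exported loss functions keep the
plain unnormalized definitions.

The observed-but-unused confidence column of interaction tables is parsed
and stored (it is part of the on-disk contract) but enters no loss.
Drug–disease and target–pathway associations are likewise not graph nodes:
the unified adjacency has only drug and target blocks, and ontology
information enters solely through the KG regularizer.

## PU negative sampling

Each unlabeled pair gets a reliability
$r_{ij} = \alpha\,\mathrm{ChemDissim} + \beta\,\mathrm{SeqDissim}$, where
ChemDissim is one minus the best Tanimoto similarity between the drug and
the target's known binders, and SeqDissim one minus the best normalized
alignment similarity between the target and the drug's known partners. An
empty binder/partner set yields dissimilarity 1, so cold entities are
eligible reliable negatives rather than undefined. Before any predictions
exist, round 0 takes the `ratio * |P|` most reliable unlabeled pairs (ties
broken by index). Importance weights are a softmax of $\gamma r$ over the
set ($\gamma = 0$ recovers uniform weights). Every `refresh_interval`
epochs the set is re-selected as the unlabeled pairs with predicted
probability below `theta_neg` **and** reliability above `theta_rel`;
probabilities are compared on the sigmoid scale so the threshold lives in
$[0,1]$. An empty selection falls back to the previous set with a warning.
The "random sampling" ablation arm draws uniformly, weights uniformly, and
never refines.

Defaults: $\alpha = \beta = 0.5$, $\gamma = 1$, thresholds 0.5,
refresh every 50 epochs, ratio 1.

## Training, evaluation, hyperparameters

The optimizer is Adam (learning rate $10^{-3}$, weight decay
$5 \cdot 10^{-4}$ at full scale) with early stopping on validation AUPR.
Evaluation uses 10-fold cross-validation over the positive pairs: per
rotation, one fold tests, one validates (early stopping and the F1
operating point, chosen on validation and applied unchanged to test), and
the rest train. Test positives are ranked against every pair that is
positive nowhere — the standard protocol when true negatives are unknown.
Cold-start scenarios hold out 20% of drugs (S1), targets (S2), or pairs
with both endpoints retained in training (S3). Metrics are AUROC (rank
form, average ties), AUPR (stepwise interpolation; tied scores enter as one
operating point, so all-tied scores give the prevalence), F1, and
precision@K (K = 10, deterministic id tie-break).

Hyperparameter search is Bayesian optimization: a Gaussian-process
surrogate (squared-exponential kernel with per-dimension length scales,
hyperparameters by marginal likelihood) over observed configuration–score
pairs, choosing each next trial by expected improvement over 1000 random
candidates, after 5 random initial points. Failed evaluations are recorded
and excluded from the surrogate.

## Dataset adaptation

`filter_subnetwork` extracts exact submatrices for a dataset's entities;
`cdf_reweight` maps each edge weight through the global empirical CDF and
back through the dataset's quantile function
($w' = w \cdot Q_D(F_{global}(w))$). Both use the midpoint tie convention
$F(v) = (\#\{<v\} + \#\{=v\}/2)/N$, and $Q_D$ linearly interpolates the
knots $(F_D(w_{(k)}), w_{(k)})$; this pairing makes the transform invariant
to duplicating the weight list and reduces $Q_D(F(w))$ to $w$ itself when
the two distributions coincide, while preserving rank order. Combination
weights $\lambda^D$ are learned by projected (finite-difference) gradient
descent on a validation objective — learning rate 0.01, decay 0.95 every 50
iterations, patience 20 — in a two-stage protocol: learn $\lambda^D$, then
freeze it and train the full model.

## The synthetic data generator

`simulate_dti_dataset()` emulates the statistical structure the method
assumes, with nothing downloaded:

* latent factors drawn around cluster centroids (5 drug clusters, 5 target
  families at the standard scale), so entities form families;
* $Y$ = the top `density` fraction of $U V^\top$ with balanced label noise
  (a fraction `noise` of positives unlabeled and the same count of
  negatives flipped positive, keeping the density exact);
* fingerprints = cluster-prototype bit sets with per-drug bit flips, so
  within-cluster Tanimoto exceeds between-cluster;
* sequences = family-prototype strings (length 80–120, 20-letter alphabet)
  with 10% per-site mutations, so within-family alignment similarity
  exceeds between-family;
* auxiliary drug–drug / target–target edges from cluster co-membership
  (probability 0.9 within, 0.02 between — strong but imperfect family
  networks);
* a two-level ontology: each entity `member_of` its cluster term, cluster
  terms `is_a` a root, consistent with the planted structure.

The standard fixture is $m = 60$, $n = 50$, rank 8, density 0.15, noise
0.05, seed 7 — small enough that the full pipeline trains in seconds. The
within-cluster spread (0.4 of the centroid scale) and prototype parameters
(16 of 64 bits set, 5 flips) were fixed once as values that give clear but
non-trivial family structure.

What the generator does **not** emulate: valence-correct chemistry, real
protein evolution, realistic degree distributions of curated databases,
and — importantly — the heavy contamination of the unlabeled set with
unrecorded true positives found in real interaction databases. Passing
tests on this fixture show the machinery is correct and that relational
signal is recovered; they do not certify performance on real data.

## Problem sizes and the small-scale configuration

Tests and the acceptance script use `dti_config_small()`: $h = 32$,
$L = 2$, learning rate 0.01, negatives ratio 8, batch 512, up to 300 epochs
with patience 100 (validation every 5 epochs). These were selected by
validation AUPR on the standard fixture — the package's own
hyperparameter protocol — and are deliberately small; the full-scale
defaults of `dti_config()` ($h = 128$, $L = 3$, learning rate $10^{-3}$,
batch 256, 1000 epochs) are the method's stated operating point for
database-scale corpora.

## Numerical choices and degenerate inputs

* Two empty fingerprints have Tanimoto 0, not 1; mismatched lengths error.
* Alignment scores are floored at 0 (local convention); an empty sequence
  scores 0 with a warning; `SWmax = 0` gives similarity 0.
* Masked softmax rows with empty support are all-zero.
* Attention-modulated rows are re-normalized by default (see above).
* Gradients are analytic throughout and checked against central finite
  differences in the test suite; rectifier kinks are the only
  non-differentiable points (subgradient 0 at exactly 0).
* All randomness flows from one master seed through named sub-streams
  (`substream_seed`), so toggling one stage does not perturb another's
  draws, and identical seeds reproduce runs exactly.
* Prediction files sort by descending score with lexicographic id
  tie-breaks; entity order is file order, recorded once and reused by every
  matrix.

## Known limitations

* The encoder is dense-matrix based; it is intended for the
  hundreds-to-thousands entity range, not web-scale graphs (no neighbor
  sampling).
* On the clean synthetic fixture, the reliability-filtered negative set is
  systematically biased toward *easy* (cross-cluster) negatives, and the
  refinement rule keeps only pairs the model already scores low. With few
  unrecorded positives in the unlabeled set, uniform random sampling —
  which includes hard negatives — can therefore rank better in AUPR than
  the combined PU scheme. The PU machinery is expected to pay off in the
  regime it was designed for: heavily contaminated unlabeled sets.
* The meta-learned combination weights use finite-difference gradients of
  the supplied validation objective; with an expensive objective this is
  the dominant cost.
* The bundled fingerprint backend hashes SMILES k-mers; it preserves
  similarity structure but is not a substructure-aware chemistry
  fingerprint. Synthetic fixtures carry explicit bit sets and do not use
  it.
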