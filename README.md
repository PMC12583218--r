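# heterodti

Drug–target interaction (DTI) prediction on heterogeneous graphs with
knowledge-based regularization, for computational chemists and
bioinformaticians who need a self-contained, fully reproducible DTI
pipeline in R.

Given drugs $D$ (SMILES or feature vectors), targets $T$ (protein
sequences) and a sparse binary interaction matrix $Y$, the package:

1. builds a heterogeneous graph with blocks
   $\bar A = \left(\begin{smallmatrix} A_{DD} & A_{DT} \\ A_{TD} & A_{TT} \end{smallmatrix}\right)$
   from thresholded Tanimoto (fingerprint) and normalized Smith–Waterman
   (sequence) similarities plus any auxiliary edge types, each row
   softmax-normalized over its structural support;
2. learns embeddings $Z_D, Z_T \in \mathbb R^{\cdot \times h}$ with an
   attention-weighted multi-relational graph-convolutional encoder,
   $Z_D \leftarrow \sigma\big((\bar A_{DD} \odot \alpha_{DD}) Z_D W_{DD} +
   (\bar A_{DT} \odot \alpha_{DT}) Z_T W_{DT} + b_D\big)$, with per-edge
   attention $\alpha_{ij} = \mathrm{sigmoid}(\mathrm{MLP}([z_i \| z_j]))$;
3. scores pairs by inner products $\hat y_{ij} = z_{D_i}^\top z_{T_j}$ and
   trains with three losses: a positive–unlabeled interaction loss
   $-\sum_P \log\sigma(\hat y) - \sum_N w_{ij}\log(1-\sigma(\hat y))$ whose
   negatives are chosen by reliability
   $r_{ij} = \alpha\,\mathrm{ChemDissim} + \beta\,\mathrm{SeqDissim}$ and
   weighted by $w_{ij} \propto e^{\gamma r_{ij}}$, a feature-reconstruction
   loss, and a knowledge-graph margin-ranking loss over bilinear-diagonal
   triple scores $f_r(h,t) = z_h^\top R_r z_t$;
4. evaluates by 10-fold cross-validation and three cold-start scenarios
   (cold drug / cold target / cold pair) with AUROC, AUPR, F1 and
   precision@K, and tunes hyperparameters by Gaussian-process Bayesian
   optimization with expected improvement.

A synthetic-data module generates datasets with planted low-rank
interaction structure, clustered fingerprints, protein families and a
matching ontology, so the entire pipeline is testable offline.

## Worked example

```r
library(heterodti)
# simulate a small study: 30 drugs, 25 targets, planted low-rank interactions
ds <- simulate_dti_dataset(m = 30, n = 25, rank = 4, density = 0.15,
                           n_drug_clusters = 4, n_target_families = 4,
                           seed = 42)
ds <- prepare_dataset(ds)   # Tanimoto + Smith-Waterman similarity matrices

cfg <- dti_config_small(seed = 1, max_epochs = 150)
res <- evaluate_cv(ds, cfg, k = 5, seed = 1, rotations = 1)
round(res$folds, 3)
#>   fold auroc  aupr    f1 p_at_k
#> 1    1 0.945 0.289 0.405    0.2

model <- train_dti(ds, cfg)
preds <- predict_scores(model)
head(preds[order(-preds$score), ], 5)
#>  drug_id target_id score probability
#>     D012      T017  15.1           1
#>     D012      T025  12.7           1
#>     D012      T013  12.7           1
#>     D012      T005  12.6           1
#>     D012      T021  12.5           1
```

The fold row reports ranking quality of held-out positives against all
unlabeled pairs: AUROC 0.945 means a held-out true interaction outranks a
random unlabeled pair ~94% of the time; AUPR 0.289 is ~19x the positive
prevalence of this split (0.015); `p_at_k` is the fraction of true
interactions among the 10 top-ranked pairs. The prediction table ranks
every drug–target pair for prioritization; ties and ordering are
deterministic.

A command-line wrapper with `simulate`, `build-graph`, `train`, `predict`,
`evaluate`, `hyperopt` and `ablate` subcommands ships in
`inst/scripts/heterodti.R`.

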