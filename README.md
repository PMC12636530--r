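# bridgesyn

Predicting drug-combination synergy in cancer cell lines with a
bridge-token fusion network, implemented as a self-contained, trainable R
package.

Only a small fraction of drug pairs act synergistically, and screening the
combinatorial space experimentally is expensive, so regression models that
rank candidate (drug, drug, cell line) triplets by predicted synergy are a
standard tool in combination-therapy discovery. This package implements
one such architecture end to end — featurization, model, training,
evaluation protocols and interpretability analyses — with a synthetic data
generator that plants a known ground truth, so every component is testable
without external screens or pretrained-model downloads.

## The model

A triplet $(D_A, D_B, C)$ maps to a scalar synergy score $\hat y$,
trained by minimising $\frac{1}{N}\sum_i (y_i-\hat y_i)^2$:

* **Drugs** enter as token-embedding matrices (e.g. from a pretrained
  molecular encoder; a one-hot SMILES fallback is built in) and pass
  through a weight-shared three-layer MLP (linear → layer-norm → GELU per
  stage).
* **Cell lines** enter as expression-enriched gene matrices
  $g_i = E_i \cdot P_i$ (expression value times per-gene protein
  embedding). A density-peaks clustering variant (DPC–KNN: density
  $\rho_i = \exp(-\frac1k\sum_{j\in \mathrm{KNN}(i)}\|g_i-g_j\|^2)$,
  separation $\delta_i$, centers by largest $\rho_i\delta_i$) compresses
  the $L$ genes to $|C|$ cluster features before projection.
* **Fusion** happens through $N_b$ bridge tokens generated from global
  (max / mean / attention) pools of all three sequences. Each fusion
  layer applies four Bridge Attention Units in parallel: the drug and
  cell sequences attend to the bridge tokens, and the bridge tokens
  attend to the concatenated sequences, giving cross-modal cost linear in
  the sequence lengths.
* **Prediction** pools entity-level and bridge-level summaries, refines
  each with residual blocks (channel mixing + SwiGLU feed-forward with
  LayerScale and DropPath) and sums them into a linear readout.

Training uses AdamW with early stopping on validation MSE. Evaluation
covers random, leave-cell-out and leave-combination-out protocols (after
a 10% hold-out) with RMSE / $R^2$ / Pearson metrics and per-tissue
aggregation. Interpretability tools include null-baseline perturbation
contributions, integrated-gradients attributions, and a drug-order
sensitivity analysis. The network and its backpropagation are implemented
in R with small C++ kernels; no deep-learning framework is required.

## A worked example

```r
library(bridgesyn)

gen  <- gen_dataset(synth_config(n_triplets = 500, seed = 1))
prep <- prepare_features(gen$dataset, feature_config(),
                         ccf_config(k = 8, n_clusters = 8))
sp   <- make_splits(gen$dataset$triplets, split_spec("random", seed = 1))
pool <- setdiff(seq_len(500), sp$holdout)
vs   <- validation_split(gen$dataset$triplets, pool, "random", seed = 1)

model <- bridgesyn(prep$d_in_drug, prep$d_in_cell,
                   bs_model_config(d_model = 64, n_heads = 2, n_bridge = 4,
                                   n_layers = 2, ffn_ratio = 2,
                                   grr_blocks = 1, grr_ratio = 2,
                                   dropout = 0.2, droppath = 0), seed = 1)
fit <- train_bridgesyn(model, prep, gen$dataset$triplets, vs$train, vs$valid,
                       bs_train_config(learning_rate = 2e-3, batch_size = 128,
                                       max_epochs = 45, patience = 12,
                                       schedule = "cosine", seed = 1))
yh <- predict(fit$model, prep, gen$dataset$triplets, idx = sp$holdout)
compute_metrics(gen$dataset$triplets$y[sp$holdout], yh)
#> n = 50  RMSE = 1.7486  R2 = 0.6079  PCC = 0.7995
```

The generator plants
$y = f(u_a) + f(u_b) + 0.6\,\langle u_a \odot u_b, v_c\rangle + \varepsilon$
with a signal-to-noise (SD ratio) of 4, so the ceiling on $R^2$ is about
0.94. Even this quick 500-triplet demonstration recovers well over half
of the variance; the reference study (2000 triplets, same model) reaches
a held-out $R^2 \approx 0.82$, including much of the drug×drug×cell
interaction term that additive baselines cannot express. `order_sensitivity(fit$model, prep, ...)` then reports the
correlation between swapped-order predictions, and
`perturbation_contribution()` / `integrated_gradients()` quantify each
drug's share of a predicted score.

A command-line interface (`inst/cli/bridgesyn.R`) wraps the same
functions: `simulate`, `cluster`, `split`, `train`, `predict`, `eval`,
`attribute`, each writing its fully resolved YAML configuration beside
its outputs.

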