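# gonnmda

Predicting miRNA–disease associations on a heterogeneous biomolecular
graph with an ordered (gated) message-passing GNN.

MicroRNAs regulate gene expression post-transcriptionally, and their
dysregulation is implicated in many human diseases; screening candidate
miRNA–disease pairs computationally narrows the list that wet-lab work
must validate. `gonnmda` implements a complete pipeline for this task,
aimed at computational biologists who want a transparent, dependency-light
R implementation they can inspect, retrain and extend:

1. **Similarity layer** — disease semantic similarity over MeSH-style DAGs
   (decay variant: `dss1`; information-content variant: `dss2`), Gaussian
   interaction-profile kernels
   `exp(-σ‖IP(i)−IP(j)‖²)` with `σ = γ′ / ((1/N) Σ‖IP(k)‖²)`,
   signed miRNA functional similarity (cosine over signed disease semantic
   profiles), and Needleman–Wunsch sequence similarity with min–max
   normalisation.
2. **Fusion layer** — each entity's similarity matrices are stacked
   `(3n × n)` and denoised by truncated SVD, `S ≈ U_k Σ_k V_kᵀ`
   (default k = 150, clamped); per-entity features are the rows of
   `V_k Σ_k`, mapped by a trained linear layer.
3. **Heterograph + ordered GNN** — 8 node types, 16 mirrored relation
   types. Each layer gates between retention and the neighbour mean,
   `h⁽ᵏ⁾ = g̃⁽ᵏ⁾ ⊙ h⁽ᵏ⁻¹⁾ + (1−g̃⁽ᵏ⁾) ⊙ m⁽ᵏ⁾`, where the gate is a
   chunk-resolution softmax with right-to-left cumulative sum accumulated
   across layers by a soft OR — aligning hop distance with ordered neuron
   blocks and resisting over-smoothing at depth.
4. **Prediction** — an MLP scores `[h_m ‖ p_m ‖ h_d ‖ p_d]`; training is
   end-to-end binary cross-entropy with Adam (analytic gradients, verified
   against finite differences in the test suite), under stratified k-fold
   cross-validation with strict per-fold feature rebuilding so held-out
   pairs never leak into training features.

A planted-partition synthetic generator (`synthetic_spec()`,
`make_dataset()`) reproduces the *shapes* of the real corpora — bipartite
associations, DAG forests, 20–23 nt RNA strings, a 16-relation graph —
so everything runs and is tested without any database download.

## Worked example

```r
library(gonnmda)

data <- make_dataset(synthetic_spec())   # 60 miRNAs, 50 diseases, 4 groups
res  <- run_cv(data, k = 2, desk_config(), seed = 1)
res$summary
#>      metric      mean          sd
#> 1       auc 0.7830453 0.006998246
#> 2      aupr 0.7689860 0.005950282
#> 3  accuracy 0.7381130 0.024667536
#> 4 precision 0.7540513 0.032607721
#> 5    recall 0.7074953 0.012970208
#> 6        f1 0.7299752 0.022188322
```

Each fold retrains from scratch on its training positives only; the
summary is the mean ± sd over folds of ranking metrics (AUC, AUPR) and of
0.5-threshold confusion metrics. On this synthetic study the planted
structure imposes a Bayes-optimal AUC of ≈ 0.85 (edges are independent
coin flips given the latent groups), so ≈ 0.78 means the model extracts
most of the signal that exists; see the methods vignette
(`vignettes/methods.Rmd`) for that analysis. Ranking candidates for one
disease:

```r
model <- fit_gonnmda(data, res$dataset, desk_config(), seed = 1)
predict_ranked(model, "D001", top = 5)
#>  rank mirna     score
#>     1  M033 0.9822724
#>     2  M045 0.9655059
#>     3  M041 0.9409590
#>     4  M049 0.9082607
#>     5  M013 0.9044680
```

A thin command-line wrapper with `simulate` / `train` / `evaluate` /
`predict` subcommands lives at `inst/scripts/gonnmda.R`; configuration is
YAML (`load_config`), with every tunable defaulting to the published
operating point (`default_config()`).

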