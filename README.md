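# panfuse

Molecular-subtype discovery and prognosis for bulk transcriptomics, built
around three ideas:

1. **A voting "scoring network" for pseudo-labels.** No single clustering
   algorithm is trustworthy enough to define tumour subtypes on its own.
   panfuse runs five of them — k-means, full-covariance GMM, Ward
   agglomerative, CLARANS, and PAM — under a unified Euclidean metric,
   aligns their label spaces by optimal assignment, and assigns each
   sample the majority-vote consensus label, with a nearest-centroid
   tie-break. The number of subtypes comes from a silhouette scan over
   candidate k.
2. **A cross-attention classifier trained on those pseudo-labels.** One
   sample's expression vector over a frozen, variance-ordered gene panel
   is windowed into L tokens and read by two parallel branches — a
   three-layer 1-D CNN (spatial features F_c) and a bidirectional LSTM
   (temporal features F_g) — fused by scaled dot-product cross-attention

   F_cg = softmax(F_c F_g^T / sqrt(d)) (F_c + F_g),

   then mean-pooled through a fully connected softmax head, trained with
   cross-entropy and early stopping. The forward/backward passes are
   implemented in vectorised base R and validated against
   finite-difference gradients and a scalar-loop fusion oracle in the
   test suite.
3. **A screen → forest → risk-function prognostic chain.** A univariate
   Cox screen (Efron ties, p < 0.05) feeds a random survival forest
   (log-rank splitting, permutation importance, OOB error trajectory —
   implemented in C++ in this package); the forest's top genes enter a
   multivariable Cox fit defining the risk function

   f(t|x) = f0(t) · exp(coef_1·gene_1 + … + coef_m·gene_m),

   with Breslow baseline f0. Per-sample scores exp(lp) are stratified
   into high/low risk at the cutoff maximising the standardised log-rank
   statistic over all admissible cutpoints (maximally selected rank
   statistics), and evaluated by Kaplan-Meier curves and Harrell's
   C-index.

A synthetic-data generator plants known subtype structure (Gaussian
block mean-shifts) and linked exponential survival with calibrated
censoring, so every stage is testable without any external cohort.

Who it is for: computational biologists stratifying bulk expression
cohorts (the motivating application is programmed-cell-death-related
subtyping in gastric cancer) who want the full
clustering → classifier → prognosis chain reproducible from one seed.

## Worked example

```r
library(panfuse)

# a synthetic cohort: 120 samples x 80 genes, three planted subtypes
sim <- simulate_expression(sim_config(n_samples = 120, n_genes = 80,
                                      n_informative = 24, effect_size = 3,
                                      seed = 42))

# subtype discovery with silhouette-guided k
fit <- consensus_subtypes(sim$expr, k = NULL, k_candidates = 2:5, seed = 42)
summary(fit)
#> Consensus subtypes (five-voter scoring network)
#>   samples: 120, k = 3, genes used: 80
#>   mean silhouette: 0.139
#>   subtype sizes: 37 / 40 / 43
#>   mean voter agreement: 0.993
#>   per-algorithm mean silhouette:
#>     kmeans         0.139  (reference)
#>     gmm            0.139
#>     agglomerative  0.139
#>     clarans        0.133
#>     kmedoids       0.133
#>   silhouette scan:
#>     k = 2: 0.104
#>     k = 3: 0.139  (chosen)
#>     k = 4: 0.093
#>     k = 5: 0.074

adjusted_rand_index(fit$labels, sim$labels)
#> [1] 1
```

The scan picks the planted k = 3; all five voters agree on nearly every
sample (mean agreement 0.993) and the consensus recovers the planted
partition exactly (ARI = 1).

```r
# survival linked to three noise genes, then the prognostic chain
surv <- simulate_survival(sim$expr, c("g0078", "g0079", "g0080"),
                          rep(log(2), 3), baseline_rate = 0.001,
                          censor_rate = 0.3, seed = 42)
rm_ <- fit_risk_model(sim$expr, surv, n_trees = 300, top_m = 3, seed = 42)
rm_
#> Prognostic risk model: f(t|x) = f0(t) * exp(sum coef_i * gene_i)
#>   genes (3): g0080, g0078, g0079
#>   training C-index: 0.748;  cutoff: 1.954
#>   stratification log-rank p = 4.3e-17 (post-selection)
```

The screen-forest chain lands on exactly the three planted prognostic
genes; the training C-index of 0.75 reflects genuine (not memorised)
signal, and the maxstat cutoff splits the cohort into risk groups with
a strongly separated Kaplan-Meier pair — the p-value is labelled
post-selection because the cutoff was chosen to maximise that very
separation.

Classifier training and hub-gene selection follow the same pattern
(`crossfusion()`, `select_hub_genes()`); `run_pipeline()` wires all
stages behind one JSON config and one seed, and
`inst/cli/panfuse.R` exposes each stage as a shell command.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's reference workflow from scratch: it simulates
the 300-sample × 200-gene three-subtype world, runs consensus
clustering, trains the cross-fusion classifier against the consensus
pseudo-labels, selects hub genes, fits the prognostic model, logs the
headline numbers to stderr, and writes the results JSON to `--out`. The
`--seed` argument drives every source of randomness in the run.
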