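# comrank

Joint inference of **community** and **hierarchy** structure in directed
weighted networks, for researchers studying interacting systems — social
contact and nomination networks, animal dominance data, hyperlink graphs —
where it is not known *a priori* whether ties form because of group affinity
or because of rank.

## The model

Every node carries a latent binary type σᵢ ~ Bernoulli(μ): type 0 nodes
prefer community-based interactions, type 1 nodes hierarchy-based ones. Edge
counts are conditionally independent Poisson draws whose mean depends on the
types of the two endpoints:

- both endpoints type 0 (community): Aᵢⱼ ~ Pois(Mᵢⱼ), with the
  mixed-membership block-model rate Mᵢⱼ = Σₖₕ uᵢₖ vⱼₕ wₖₕ
  (out-memberships u, in-memberships v, affinity w);
- both endpoints type 1 (hierarchy): Aᵢⱼ ~ Pois(Sᵢⱼ), with the SpringRank
  rate Sᵢⱼ = c · exp[−β/2 (sᵢ − sⱼ − 1)²] (real scores s, density scale c,
  inverse temperature β) favouring edges towards nodes ranked just below;
- unlike endpoints (out-group): Aᵢⱼ ~ Pois(δ₀) at a small constant rate.

The posterior over node types is exactly an Ising model whose couplings
compare the per-pair evidence of the three Poisson branches; fitting uses
variational EM with a factorised Bernoulli posterior Q (mean-field tanh
fixed point) for the E-step, and closed-form or stationarity-based updates
for μ, δ₀, (u, v, w) and (s, c). Multiple restarts from complementary
initialisations are scored by the variational bound and the best kept.
Q̂ᵢ estimates P(σᵢ = 1 | A), so the fit simultaneously classifies nodes by
interaction mechanism, detects communities among the type-0 nodes, and ranks
the type-1 nodes.

## Worked example

```r
library(comrank)

# a synthetic benchmark network: 200 nodes, 3 communities, 3 score leagues,
# 30% of nodes preferring hierarchy
sim <- sample_comrank(comrank_config(N = 200, K = 3, mu_gt = 0.3, seed = 7))
fit <- comrank(sim$A, K = 3, beta = 5, n_init = 3, seed = 1)
fit
#> Community/hierarchy mixture model fit
#>   N = 200 nodes, K = 3 communities, beta = 5, lambda = 0
#>   variational bound: -7902.8355 (converged, best of 3 restarts; final phase 148 iterations)
#>   mean node-type posterior mean(Q) = 0.350 (mu = 0.350, delta0 = 0.01154, c = 2.095)

node_type_auc(fit$Q, sim$sigma)
#> [1] 0.9861111
community_cosine_similarity(fit$params$u, sim$u)
#> [1] 0.635135

# held-out edge prediction
cv <- comrank_cv(sim$A, K = 3, beta = 5, folds = 5, n_init = 3, seed = 1)
mean(cv$edge_auc)
#> [1] 0.8485559
```

The fitted type prior `mu = 0.350` tracks the realised fraction of
hierarchy-preferring nodes (0.36), and Q separates the two groups almost
perfectly (AUC 0.986). At this small size and mixed regime the community
cosine similarity is moderate (0.64); it rises above 0.85 in the
community-dominated regimes of the full-size study. Values of Qᵢ near 0.5
flag nodes whose mechanism the data leave ambiguous. `predict(fit)` returns
the posterior-expected adjacency used as the edge-prediction score, and
`plot(fit)` shows the objective trace and the Q distribution.

A command-line interface is installed with the package
(`exec/comrank`): subcommands `generate`, `fit`, `evaluate` and `benchmark`
chain the same functions over edge-list files.

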