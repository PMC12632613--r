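# tlscp: survival-based clustering of predictors, with transfer learning

`tlscp` answers a question that standard Cox regression does not: *which
predictors affect survival in the same way?* Given right-censored outcomes
and a set of covariates — the motivating case is recurrent germline
mutations of a cancer gene, with age at first diagnosis as the outcome —
the package estimates a Cox model whose coefficients are forced into
homogeneous clusters, so features sharing a coefficient value are grouped
and annotated together. It is aimed at biostatisticians analyzing cohorts
where per-feature sample sizes are too small for reliable individual
effect estimates.

## Method

For the Cox model $h_i(t) = h_0(t)e^{x_i^\top\beta}$ with log partial
likelihood $\ell(\beta)$, a preliminary unpenalized fit $\tilde\beta$
defines a rank mapping $\tau$, and the estimator solves the fusion-penalized
problem

$$\hat\beta = \arg\min_\beta\; -\tfrac1n\,\ell(\beta) +
\tfrac{\lambda}{2}\,\mathrm{dist}\bigl(D_\tau\beta,\ C\bigr)^2,\qquad
C = \{z : \|z\|_0 \le k\},$$

where $D_\tau$ differences rank-adjacent coefficients. Driving
$\lambda \to \infty$ along a proximal-distance schedule leaves at most $k$
nonzero differences — at most $k+1$ coefficient clusters — so the tuning
parameter is the integer cluster budget itself, selected by BIC from
`{1,...,5}` by default. Lasso/SCAD/MCP variants of the fusion penalty are
available as alternatives.

Small cohorts rank their coefficients poorly, which is the procedure's weak
point. The transfer-learning extension `tlscp()` merges the target's
coefficient ranking with that of a larger source cohort by weighted rank
averaging (weights default to sample-size ratios; per-feature carrier-count
weights are supported) and fits the penalized model on the target with the
merged ranking. Only ranks cross cohorts — never coefficient values — so a
summary-level source (coefficients or ranks) suffices.

The package also ships the seeded simulators for the three benchmark
scenarios (consistent ranking, covariate shift, partial ranking
inconsistency), the evaluation metrics (normalized mutual information,
relative squared error), a Cox-regression-plus-k-means baseline with
silhouette-selected k, a replicated benchmark driver, and a small CLI.

## Worked example

```r
library(tlscp)

cfg <- scenario_config(n_target = 200, n_source = 2000, p = 90, seed = 7)
tgt <- generate_target(cfg)              # small cohort, 3 true clusters
src <- generate_source(cfg, tgt$beta)    # large cohort, same coefficient ranking

fit_t  <- scp(tgt$data, k = 1:5)         # target only
fit_tl <- tlscp(tgt$data, src$data, k = 1:5)

c(scp = nmi(fit_t$labels, tgt$partition),
  tlscp = nmi(fit_tl$labels, tgt$partition))
#>       scp     tlscp
#> 0.5465544 0.6538722

fit_tl
#> Transfer-learning survival-based clustering of predictors
#> Call: tlscp(target = tgt$data, source = src$data, k = 1:5)
#>   n = 200 (140 events), p = 90 (90 penalized)
#>   penalty: k = 5; clusters found: 6
#>   log partial likelihood = -473.7870, BIC = 977.2239
#>   cluster centers: -0.6537, 0.1579, 0.5626, 1.0738, 1.8154, 1.3011
```

The NMI (normalized mutual information, 1 = perfect recovery) compares the
fitted partition of the 90 covariates with the true three-cluster
partition: with this target cohort alone the clustering is mediocre
(≈ 0.55), and borrowing the source cohort's coefficient ranking lifts it to
≈ 0.65 for this seed (the median gain across replicates is larger; see the
benchmark below). The fitted coefficients are exactly constant within each
cluster;
`summary(fit_tl)` lists the members and the BIC path, `plot(fit_tl)` draws
the clustered coefficient profile.

The same analyses run from a shell:

```sh
Rscript inst/cli/tlscp.R simulate --out-target target.csv --truth truth.json --seed 7
Rscript inst/cli/tlscp.R fit-scp --input target.csv --output fit.json --k 1:5
Rscript inst/cli/tlscp.R evaluate --fit fit.json --truth truth.json
```

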