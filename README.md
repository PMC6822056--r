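# scrselect

Bayesian model selection for **bilateral spatial capture–recapture (SCR)
data with partially identified individuals** — the setting of double-camera
trap surveys of naturally marked animals, where a passing animal may be
photographed on one flank, the other, or both, and one-sided histories
cannot be matched across cameras without a verified simultaneous capture.

The package is for statistical ecologists who need to (a) fit this class of
models by MCMC and (b) decide *which* of several competing model structures
the data support, using estimators that remain computable in the presence of
the high-dimensional latent variables these models carry.

## Models and estimators

Four competing models for zero-augmented detection arrays `Y1`, `Y2`
(dimension M × J × K) with latent activity centers `s_i`, inclusion
indicators `z_i ~ Bern(ψ)` (so `N = Σ z_i`), sexes `u_i ~ Bern(θ)`, and an
identity permutation **L** aligning detector-2 rows with detector-1 rows:

- **M1** — trap entry `η_j(s_i) = ω₀ exp(−d(s_i,x_j)²/2σ(u_i)²)` followed,
  given entry, by two conditionally independent detections with probability
  φ; sex-specific movement scales σ_m, σ_f. The per-cell distribution is a
  zero-inflated Bernoulli pair: mass `(1−η) + η(1−φ)²` on no detection,
  `ηφ(1−φ)` on each single-detector outcome, `ηφ²` on both.
- **M2** — single-stage detection `p_j = p₀ exp(−d²/2σ(u_i)²)` per detector,
  sex-specific σ.
- **M3** / **M4** — the sexless counterparts of M1 / M2.

Model-selection tools computed from one chain's retained draws (25 variants
in all):

- **Gelfand–Dey marginal-likelihood estimators** — the posterior mean of
  `g(µ)/(f(Y|µ)π(µ))` estimates `1/m(Y)` for any proper tuning density g.
  Two approximations handle the latent block: a **MAP** approximation
  (latents fixed at a coordinate-ascent posterior-mode estimate scanned
  across draws) and an **integrated-likelihood** approximation (z and
  missing sexes marginalized analytically, activity centers by a Riemann
  sum, conditioning on each draw's permutation). Nine tuning densities:
  multivariate normal, multivariate t (df 10–10000), truncated normal
  (confidence 0.90/0.95/0.99), all fitted on the logit-transformed scale.
- **Harmonic mean** estimator (g = prior).
- **DIC** with two effective-parameter forms (deviance at the MAP estimate).
- **WAIC** partitioned by augmented individual, with three penalty forms
  (Jensen gap, posterior variance, posterior mean absolute deviation).
- **Posterior predictive loss** `D∞`: squared deviation of the data from
  posterior-predictive cell means plus predictive cell variance, over the
  2MJK vectorized binary cells, one simulated replicate per retained draw.

A simulation harness reproduces the benchmark study design (10 × 16 trap
grid, K = 50, N = 100 with 40 males, M = 400, twelve ω₀/φ/σ scenarios) and
a scaled-down preset sized for one CPU, and computes true-model selection
proportions and average RMSE of N.

## Worked example

```r
library(scrselect)

## bundled miniature survey: 3 traps, 4 occasions, two fully identified
## individuals (verified simultaneous captures) and one unlinked partial
## history per detector
ex <- system.file("extdata", "bilateral_example", package = "scrselect")
loaded <- readCaptureDir(ex, K = 4, M = 5)
loaded$data
#> BilateralData: M = 5 augmented individuals, J = 3 traps, K = 4 occasions
#>   observed rows: 3 (detector 1), 3 (detector 2); detections: 13 + 9
loaded$identity
#> IdentityInfo: 2 known links, 1 free detector-1 rows, 1 free detector-2 rows

## simulate a scaled-down survey under the sex-specific entry/detection
## model (true N = 30, 12 male) and fit it
g   <- scaledDownGeometry()
sim <- simulateDataset(scaledDownScenario(9), g$traps, g$space, seed = 1)
sim$data
#> BilateralData: M = 100 augmented individuals, J = 49 traps, K = 15 occasions
#>   observed rows: 16 (detector 1), 17 (detector 2); detections: 64 + 70

fit <- runChain(sim$data, sim$identity, g$traps, g$space, "M1",
                chainConfig(nIter = 5000, burnIn = 1000, seed = 1))
fit
#> PosteriorDraws [M1]: 4000 retained draws, M = 100
#>   posterior median N = 45
#>   acceptance rates:
#>    psi  theta    phi omega0 sigmaM sigmaF      S      L
#>  0.392  0.383  0.388  0.379  0.370  0.384  0.499  0.976

## compare the generating model against the simplest competitor by the
## Gelfand-Dey evidence with MAP approximation
fit4 <- runChain(sim$data, sim$identity, g$traps, g$space, "M4",
                 chainConfig(nIter = 5000, burnIn = 1000, seed = 2))
ev <- list(logMarginalGDMap(fit,  sim$data, g$traps, g$space),
           logMarginalGDMap(fit4, sim$data, g$traps, g$space))
ev[[1]]; ev[[2]]
#> CriterionResult: gd_map for M1 = -617.5601
#> CriterionResult: gd_map for M4 = -701.2512
selectModel(ev)
#> [1] "M1"
```

The log marginal difference of ~84 log units is decisive evidence for the
entry/detection hierarchy with sex-specific movement over the single-stage
sexless model on this replicate; the posterior median N = 45 for a true
N = 30 reflects the wide abundance posterior a 33-captured-individual survey
gives (across ten seeded replicates the median lands within ±25% of truth in
eight — see the acceptance checks). `computeCriteria()` evaluates the full
25-variant battery, and `runExperiment()` repeats
simulate → fit → select across scenarios and replicates.

A thin command-line surface is available after installation:

```sh
exec/scrselect simulate --scenario 9 --seed 17 --out survey/
exec/scrselect criteria --data survey/ --model M1 --out criteria.csv
exec/scrselect experiment --config exp.yaml --out study/
```

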