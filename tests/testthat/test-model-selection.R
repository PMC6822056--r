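# Evidence estimators, information criteria, posterior predictive loss, and
# winner selection, pinned by closed forms and hand computations.

test_that("the Gelfand-Dey core is exact when g equals the posterior, and shift-equivariant", {
  set.seed(2)
  p <- rbeta(5000, 4, 3)
  ll <- 3 * log(p) + 2 * log(1 - p)
  lpi <- log(p * (1 - p))           # transformed-scale uniform prior
  # exact posterior density of t = logit(p): Beta(4,3) times Jacobian
  lgExact <- dbeta(p, 4, 3, log = TRUE) + log(p * (1 - p))
  v <- logMarginalGD(lgExact, ll, lpi)
  expect_equal(as.numeric(v), log(1 / 60), tolerance = 1e-12)
  # zero-variance identity: every summand equals -log m(Y)
  summand <- lgExact - ll - lpi
  expect_lt(var(summand), 1e-24)
  # adding c to all log-likelihoods shifts the estimate by exactly c
  g <- fitTuningDensity(matrix(qlogis(p), ncol = 1), "mvnormal")
  lg <- logDensity(g, matrix(qlogis(p), ncol = 1))
  v0 <- as.numeric(logMarginalGD(lg, ll, lpi))
  v7 <- as.numeric(logMarginalGD(lg, ll + 7, lpi))
  expect_equal(v7, v0 + 7, tolerance = 1e-10)
})

test_that("harmonic mean handles degenerate and hand-computed cases", {
  r <- logMarginalHM(rep(-3.25, 50))
  expect_equal(criterionValue(r), -3.25)
  # likelihoods 1 and 1/3: harmonic mean = 2 / (1 + 3) = 1/2
  r2 <- logMarginalHM(c(log(1), log(1 / 3)))
  expect_equal(criterionValue(r2), log(0.5), tolerance = 1e-12)
})

test_that("tuning densities fit, truncate and approach their normal limit", {
  set.seed(5)
  x <- matrix(rnorm(4000), ncol = 2)
  g <- fitTuningDensity(x, "mvnormal")
  expect_equal(as.numeric(g@location), c(0, 0), tolerance = 0.1)
  expect_equal(g@scaleMat, diag(2), tolerance = 0.12)
  # truncated: inside the ellipsoid the density is normal / conf; outside 0
  gt <- fitTuningDensity(x, "truncnormal", conf = 0.9)
  inside <- g@location
  expect_equal(logDensity(gt, inside), logDensity(g, inside) - log(0.9),
               tolerance = 1e-10)
  far <- g@location + c(50, 50)
  expect_equal(logDensity(gt, far), -Inf)
  # t with huge df matches the normal at the mode
  gtt <- fitTuningDensity(x, "mvt", df = 10000)
  expect_lt(abs(logDensity(gtt, inside) - logDensity(g, inside)), 1e-3)
  expect_error(fitTuningDensity(x[1:3, ], "mvnormal"), "draws")
})

test_that("DIC matches degenerate and hand-computed values and keeps p2 nonnegative", {
  d0 <- dic(rep(-5, 20), -5, variant = 1)
  expect_equal(d0@penalty, 0)
  expect_equal(criterionValue(d0), 10)
  expect_equal(dic(rep(-5, 20), -5, variant = 2)@penalty, 0)
  d1 <- dic(c(-10, -12), -10, variant = 1)
  d2 <- dic(c(-10, -12), -10, variant = 2)
  expect_equal(d1@penalty, 2)
  expect_equal(d2@penalty, 2)
  expect_equal(criterionValue(d1), 24)
  for (seed in 1:5) {
    set.seed(seed)
    ll <- rnorm(50, -100, 4)
    expect_gte(dic(ll, max(ll), variant = 2)@penalty, 0)
  }
})

test_that("WAIC matches degenerate and hand-computed values with ordered penalties", {
  m0 <- matrix(rep(c(-1, -2, -3), each = 10), nrow = 10)
  for (v in 1:3) {
    w <- waic(m0, variant = v)
    expect_equal(w@penalty, 0)
    expect_equal(criterionValue(w), -2 * (-6))
  }
  # single individual, draws log(0.2), log(0.4)
  m1 <- matrix(c(log(0.2), log(0.4)), ncol = 1)
  lppd <- log(0.3)
  mbar <- (log(0.2) + log(0.4)) / 2
  w1 <- waic(m1, variant = 1)
  expect_equal(w1@penalty, 2 * (lppd - mbar), tolerance = 1e-12)
  expect_equal(criterionValue(w1), -2 * lppd + 2 * w1@penalty,
               tolerance = 1e-12)
  dev <- c(log(0.2), log(0.4)) - mbar
  expect_equal(waic(m1, variant = 2)@penalty, mean(dev^2), tolerance = 1e-12)
  expect_equal(waic(m1, variant = 3)@penalty, 2 * mean(abs(dev)),
               tolerance = 1e-12)
  # Jensen gap nonnegative; per-individual MAD bounded by the SD
  set.seed(9)
  m <- matrix(rnorm(600, -20, 2), nrow = 100)
  expect_gte(waic(m, variant = 1)@penalty, 0)
  mads <- colMeans(abs(sweep(m, 2, colMeans(m), "-")))
  sds <- sqrt(colMeans(sweep(m, 2, colMeans(m), "-")^2))
  expect_true(all(mads <= sds + 1e-12))
})

test_that("MAP search finds the cross-combination a joint scan misses", {
  # data: one individual captured twice at the single trap by detector 1
  space <- unitSpace()
  traps <- trapArray(cbind(0.5, 0.5))
  Y1 <- array(0, c(2, 1, 2)); Y1[1, 1, ] <- 1
  data <- bilateralData(Y1, array(0, c(2, 1, 2)))
  # draw 1: good scalars, bad latents (empty slot included, center far away)
  # draw 2: bad scalars, good latents (tight fit at the trap)
  nat <- rbind(c(0.5, 0.9, 0.4, 0.3),
               c(0.5, 0.05, 0.02, 0.3))
  colnames(nat) <- paramNames("M3")
  z <- rbind(c(1L, 1L), c(1L, 0L))
  s <- array(0, c(2, 2, 2))
  s[1, , ] <- cbind(c(0.05, 0.9), c(0.05, 0.9)) # far corner
  s[2, , ] <- cbind(c(0.5, 0.2), c(0.5, 0.2))   # at the trap
  ctx <- scrselect:::chainData(data, traps, space, "M3", 10)
  tdFor <- function(natRow) {
    v <- natRow; v["sigma"] <- v["sigma"] / 10; qlogis(v)
  }
  lfFor <- function(dp, ds)
    sum(scrselect:::cpp_indiv_loglik(ctx, tdFor(nat[dp, ]), z[ds, ],
                                     c(0L, 0L),
                                     cbind(s[ds, , 1], s[ds, , 2]), 0:1))
  draws <- manualDraws("M3", nat, z, s,
                       loglik = c(lfFor(1, 1), lfFor(2, 2)))
  kernel <- function(dp, ds)
    lfFor(dp, ds) + scrselect:::zPriorLog(nat[dp, "psi"], sum(z[ds, ]), 2)
  combos <- outer(1:2, 1:2, Vectorize(kernel))
  # the fixture is only valid if the cross-combination dominates the joints
  expect_gt(combos[1, 2], combos[1, 1])
  expect_gt(combos[1, 2], combos[2, 2])
  res <- mapSearch(draws, data, traps, space)
  expect_equal(res$dScalar, 1L)
  expect_equal(res$dLatent, 2L)
  expect_equal(res$logPosteriorKernel, combos[1, 2], tolerance = 1e-10)
  expect_true(all(diff(res$kernelPath) > 0))
  # a chain of identical draws returns that draw after one sweep
  same <- manualDraws("M3", nat[c(1, 1), ], z[c(1, 1), ],
                      s[c(1, 1), , , drop = FALSE],
                      loglik = rep(lfFor(1, 1), 2))
  res1 <- mapSearch(same, data, traps, space)
  expect_equal(res1$logPosteriorKernel, combos[1, 1], tolerance = 1e-10)
})

test_that("posterior predictive loss vanishes on perfect replication and matches Bernoulli moments", {
  space <- unitSpace()
  traps <- trapArray(cbind(0.5, 0.5))
  # all-zero data, draws with z = 0: every replicate is identical to the data
  data0 <- bilateralData(array(0, c(2, 1, 1)), array(0, c(2, 1, 1)))
  nat <- matrix(rep(c(0.5, 0.3, 0.4), each = 12), ncol = 3)
  z0 <- matrix(0L, 12, 2)
  s0 <- array(0.5, c(12, 2, 2))
  d0 <- manualDraws("M4", nat, z0, s0)
  r0 <- posteriorPredictiveLoss(d0, data0, traps, space, seed = 2)
  expect_equal(criterionValue(r0), 0)
  expect_equal(r0@penalty, 0)
  # one real individual at the trap: each of the two cells is Bernoulli(p)
  Y1 <- array(1, c(1, 1, 1))
  data1 <- bilateralData(Y1, array(0, c(1, 1, 1)))
  n <- 10000
  p <- 0.35
  nat1 <- matrix(rep(c(0.5, p, 5), each = n), ncol = 3) # sigma huge: p at trap
  d1 <- manualDraws("M4", nat1, matrix(1L, n, 1), array(0.5, c(n, 1, 2)))
  r1 <- posteriorPredictiveLoss(d1, data1, traps, space, seed = 3)
  expected <- ((1 - p)^2 + p * (1 - p)) + (p^2 + p * (1 - p))
  se <- 3 * 4 * sqrt(p * (1 - p) / n) # generous bound on the MC error
  expect_lt(abs(criterionValue(r1) - expected), se)
  expect_gte(r1@penalty, 0)
})

test_that("winner selection respects direction, ties and mixed-method guards", {
  res <- function(method, model, value)
    new("CriterionResult", method = method, model = model, value = value,
        penalty = NA_real_, metadata = list())
  expect_equal(as.character(selectModel(list(res("hm", "M1", -100),
                                             res("hm", "M4", -98)))), "M4")
  expect_equal(as.character(selectModel(list(res("dic1", "M1", 500),
                                             res("dic1", "M4", 490)))), "M4")
  tie <- selectModel(list(res("dic1", "M1", 500), res("dic1", "M3", 500)))
  expect_equal(as.character(tie), "M3")
  expect_equal(attr(tie, "tie"), c("M1", "M3"))
  expect_error(selectModel(list(res("hm", "M1", -1), res("dic1", "M2", 3))),
               "mixed")
  # exhaustive argmin over a four-model fixture
  vals <- c(M1 = 412.2, M2 = 398.5, M3 = 407.1, M4 = 399.0)
  rs <- lapply(names(vals), function(m) res("waic2", m, vals[[m]]))
  expect_equal(as.character(selectModel(rs)), names(which.min(vals)))
  vals2 <- c(M1 = -812.5, M2 = -800.1, M3 = -805.3, M4 = -801.2)
  rs2 <- lapply(names(vals2), function(m) res("gd_map", m, vals2[[m]]))
  expect_equal(as.character(selectModel(rs2)), names(which.max(vals2)))
})

test_that("the integrated-likelihood evidence matches a quadrature oracle on a tiny instance", {
  # M = 2, J = 2, K = 1; psi and omega0 free, phi and sigma pinned, so the
  # marginal likelihood reduces to a 2-D integral crossed with the 2 possible
  # permutations
  space <- unitSpace()
  traps <- trapArray(cbind(c(0.3, 0.7), c(0.5, 0.5)))
  Y1 <- array(0, c(2, 2, 1)); Y2 <- array(0, c(2, 2, 1))
  Y1[1, 1, 1] <- 1; Y2[1, 2, 1] <- 1
  data <- bilateralData(Y1, Y2)
  ident <- findFullIdentities(matrix(integer(), ncol = 2), 1, 1)
  fixed <- c(phi = 0.7, sigma = 0.5)
  grid <- c(4L, 4L)
  cfg <- chainConfig(nIter = 52000, burnIn = 2000, thin = 5, seed = 12,
                     fixedParams = fixed)
  fit <- runChain(data, ident, traps, space, "M3", cfg)
  tun <- fitTuningDensity(fit@transformedDraws[, c("psi", "omega0")],
                          "mvnormal")
  # Gelfand-Dey over the free block: g and prior on (psi, omega0) only; the
  # pinned coordinates are constants of the model here
  lf <- vapply(seq_along(fit@loglik), function(d) {
    params <- untransformParams(fit@transformedDraws[d, ], "M3", fit@R)
    integratedLogLik(data, traps, space, params, fit@LDraws[d, ], grid = grid)
  }, numeric(1))
  td <- fit@transformedDraws[, c("psi", "omega0")]
  lg <- logDensity(tun, td)
  lpi <- scrselect:::transformedPriorRows(td)
  got <- as.numeric(logMarginalGD(lg, lf, lpi))
  # quadrature oracle: midpoint rule over (psi, omega0), permutations averaged
  qs <- (seq_len(80) - 0.5) / 80
  margL <- function(psi, om) {
    params <- scalarParams("M3", psi = psi, phi = 0.7, omega0 = om,
                           sigma = 0.5)
    ils <- vapply(list(1:2, 2:1), function(L)
      integratedLogLik(data, traps, space, params, L, grid = grid),
      numeric(1))
    scrselect:::logSumExp(ils) - log(2)
  }
  lvals <- outer(qs, qs, Vectorize(margL))
  want <- scrselect:::logSumExp(as.numeric(lvals)) - log(length(lvals))
  expect_equal(got, want, tolerance = 0.02 * abs(want))
})
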