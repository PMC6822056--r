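# Sampler construction, determinism, support invariants, conjugate checks,
# and identity-permutation updates.

scaledFit <- function(seed = 3, model = "M1", nIter = 1500, burnIn = 400) {
  g <- scaledDownGeometry()
  sim <- simulateDataset(scaledDownScenario(9), g$traps, g$space, seed = 42)
  fit <- runChain(sim$data, sim$identity, g$traps, g$space, model,
                  chainConfig(nIter = nIter, burnIn = burnIn, seed = seed))
  list(fit = fit, sim = sim, g = g)
}

test_that("initial states are link-consistent, data-consistent and reproducible", {
  g <- scaledDownGeometry()
  sim <- simulateDataset(scaledDownScenario(9), g$traps, g$space, seed = 42)
  a <- initState(sim$data, sim$identity, g$traps, g$space, "M1", seed = 5)
  b <- initState(sim$data, sim$identity, g$traps, g$space, "M1", seed = 5)
  expect_identical(a$latents@L, b$latents@L)
  expect_identical(paramValues(a$params), paramValues(b$params))
  kl <- knownLinks(sim$identity)
  expect_equal(a$latents@L[kl[, 2]], kl[, 1])
  # every slot holding observed data is included
  counts <- scrselect:::captureCounts(sim$data, a$latents@L)
  expect_true(all(a$latents@z[counts$yDotDot > 0] == 1L))
  # pinned scalars are honored
  c0 <- initState(sim$data, sim$identity, g$traps, g$space, "M3", seed = 5,
                  fixedParams = c(phi = 0.77))
  expect_equal(c0$params@phi, 0.77)
})

test_that("chains are bit-identical under a fixed seed", {
  f1 <- scaledFit(seed = 9)$fit
  f2 <- scaledFit(seed = 9)$fit
  expect_identical(f1@scalarDraws, f2@scalarDraws)
  expect_identical(f1@loglik, f2@loglik)
  expect_identical(f1@LDraws, f2@LDraws)
  f3 <- scaledFit(seed = 10)$fit
  expect_false(identical(f1@scalarDraws, f3@scalarDraws))
})

test_that("every retained draw satisfies the support constraints", {
  out <- scaledFit(seed = 4)
  fit <- out$fit; sim <- out$sim; g <- out$g
  sc <- fit@scalarDraws
  expect_true(all(sc[, c("psi", "theta", "phi", "omega0")] > 0 &
                  sc[, c("psi", "theta", "phi", "omega0")] < 1))
  expect_true(all(sc[, c("sigmaM", "sigmaF")] > 0 &
                  sc[, c("sigmaM", "sigmaF")] < fit@R))
  expect_true(all(fit@sDraws[, , 1] >= g$space@xMin &
                  fit@sDraws[, , 1] <= g$space@xMax))
  expect_true(all(fit@sDraws[, , 2] >= g$space@yMin &
                  fit@sDraws[, , 2] <= g$space@yMax))
  # permutations remain bijections respecting known links
  kl <- knownLinks(sim$identity)
  for (d in c(1L, nrow(fit@LDraws))) {
    expect_true(setequal(fit@LDraws[d, ], seq_len(ncol(fit@LDraws))))
    expect_equal(fit@LDraws[d, kl[, 2]], unname(kl[, 1]))
  }
  # slots with detections never have z = 0, under each draw's permutation
  for (d in seq(1L, nrow(fit@zDraws), by = 211L)) {
    counts <- scrselect:::captureCounts(sim$data, fit@LDraws[d, ])
    expect_true(all(fit@zDraws[d, counts$yDotDot > 0] == 1L))
  }
  expect_true(all(fit@NDraws >= sum(apply(sim$data@Y1, 1, sum) > 0)))
  # the recorded log-likelihood matches an independent recomputation
  d <- nrow(fit@zDraws)
  lat <- new("LatentState", z = fit@zDraws[d, ], u = fit@uDraws[d, ],
             S = cbind(fit@sDraws[d, , 1], fit@sDraws[d, , 2]),
             L = fit@LDraws[d, ])
  params <- untransformParams(fit@transformedDraws[d, ], "M1", fit@R)
  expect_equal(fit@loglik[d],
               completeDataLogLik(sim$data, g$traps, params, lat),
               tolerance = 1e-8)
})

test_that("frozen-chain theta draws match the conjugate Beta posterior", {
  # 10 observed individuals with known sexes (4 male), everything frozen
  # except theta: the full conditional is Beta(1 + 4, 1 + 6)
  M <- 10; J <- 1; K <- 2
  Y1 <- array(0, c(M, J, K)); Y2 <- array(0, c(M, J, K))
  Y1[, 1, 1] <- 1
  sex <- c(rep(1L, 4), rep(0L, 6))
  data <- bilateralData(Y1, Y2, sex1 = sex)
  ident <- findFullIdentities(matrix(integer(), ncol = 2), 10, 0)
  space <- unitSpace()
  traps <- trapArray(cbind(0.5, 0.5))
  cfg <- chainConfig(nIter = 22000, burnIn = 2000, seed = 77, adapt = TRUE,
                     fixedParams = c(psi = 0.9, phi = 0.5, omega0 = 0.3,
                                     sigmaM = 0.4, sigmaF = 0.4))
  fit <- runChain(data, ident, traps, space, "M1", cfg,
                  updates = character(0))
  th <- fit@scalarDraws[, "theta"]
  expect_equal(mean(th), 5 / 12, tolerance = 0.02)
  expect_equal(sd(th), sqrt(5 * 7 / (12^2 * 13)), tolerance = 0.02)
})

test_that("permutation sweeps preserve links and leave symmetric states unchanged in law", {
  g <- scaledDownGeometry()
  sim <- simulateDataset(scaledDownScenario(9), g$traps, g$space, seed = 8)
  st <- initState(sim$data, sim$identity, g$traps, g$space, "M3", seed = 2)
  set.seed(31)
  cur <- st$latents
  kl <- knownLinks(sim$identity)
  for (q in 1:5) {
    cur <- updateIdentityPermutation(cur, sim$data, sim$identity, g$traps,
                                     g$space, st$params)
    expect_true(setequal(cur@L, seq_along(cur@L)))
    expect_equal(cur@L[kl[, 2]], unname(kl[, 1]))
  }
  # proposals between two all-zero augmented rows change nothing in the
  # likelihood, so the sweep accepts them with probability one
  M <- 4
  data0 <- bilateralData(array(0, c(M, 1, 1)), array(0, c(M, 1, 1)))
  ident0 <- findFullIdentities(matrix(integer(), ncol = 2), 0, 0)
  ctx <- scrselect:::chainData(data0, trapArray(cbind(0.5, 0.5)), unitSpace(),
                               "M3", 10)
  p0 <- scalarParams("M3", psi = 0.5, phi = 0.5, omega0 = 0.3, sigma = 0.4)
  lat0 <- new("LatentState", z = rep(0L, M), u = rep(0L, M),
              S = matrix(0.5, M, 2), L = 1:M)
  set.seed(1)
  res <- scrselect:::cpp_perm_sweep(ctx, transformParams(p0), lat0@z, lat0@u,
                                    lat0@S, 0:(M - 1), 0:(M - 1), 0:(M - 1),
                                    200L)
  expect_equal(res$accepted, 200L)
})

test_that("latent stores can be disabled and thinning shapes the output", {
  g <- scaledDownGeometry()
  sim <- simulateDataset(scaledDownScenario(9), g$traps, g$space, seed = 42)
  fit <- runChain(sim$data, sim$identity, g$traps, g$space, "M4",
                  chainConfig(nIter = 900, burnIn = 300, thin = 3, seed = 1,
                              storeLatents = FALSE))
  expect_equal(length(fit@loglik), 200L)
  expect_equal(nrow(fit@zDraws), 0L)
  expect_equal(ncol(fit@scalarDraws), 3L)
})

test_that("draws export writes named scalar columns plus loglik and N", {
  out <- scaledFit(seed = 6, model = "M4", nIter = 400, burnIn = 100)
  f <- tempfile(fileext = ".csv")
  writeDraws(out$fit, f)
  df <- read.csv(f)
  expect_true(all(c("psi", "p0", "sigma", "loglik", "N") %in% names(df)))
  expect_equal(nrow(df), length(out$fit@loglik))
  unlink(c(f, paste0(f, ".meta.json")))
})
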