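# Detection kernels, parameter transforms, priors, complete-data and
# integrated likelihoods, with brute-force oracles on tiny instances.

test_that("half-normal kernels evaluate and order correctly", {
  expect_equal(trapEntryProb(0.3, 0.2, 0), 0.3)
  expect_equal(trapEntryProb(0.05, 0.3, 0.3), 0.05 * exp(-0.5),
               tolerance = 1e-12)
  d <- seq(0, 2, by = 0.1)
  expect_true(all(diff(trapEntryProb(0.5, 0.3, d)) < 0))
  expect_equal(trapEntryProb(0.5, 0.3, 50), 0)
  expect_equal(detectionProbRoyle(0.1, 0.2, 0.2), 0.1 * exp(-0.5),
               tolerance = 1e-12)
  expect_equal(detectionProbRoyle(0.1, 0.2, 0), 0.1)
  # larger sigma raises the probability at any fixed positive distance
  expect_gt(detectionProbRoyle(0.1, 0.4, 0.2), detectionProbRoyle(0.1, 0.2, 0.2))
})

test_that("parameter transforms round-trip and hit known anchors", {
  p <- scalarParams("M4", psi = 0.5, p0 = 0.3, sigma = 5, R = 10)
  t <- transformParams(p)
  expect_equal(unname(t[c("psi", "sigma")]), c(0, 0))
  for (seed in 1:10) {
    set.seed(seed)
    for (m in c("M1", "M2", "M3", "M4")) {
      nm <- paramNames(m)
      v <- runif(length(nm))
      names(v) <- nm
      v[nm %in% c("sigmaM", "sigmaF", "sigma")] <-
        v[nm %in% c("sigmaM", "sigmaF", "sigma")] * 10
      pp <- do.call(scalarParams, c(list(model = m, R = 10), as.list(v)))
      back <- untransformParams(transformParams(pp), m, R = 10)
      expect_equal(paramValues(back), paramValues(pp), tolerance = 1e-12)
    }
  }
  expect_error(untransformParams(c(Inf, 0, 0), "M4"), "finite")
})

test_that("the prior is flat uniforms with correct transformed-scale Jacobians", {
  p <- scalarParams("M4", psi = 0.3, p0 = 0.2, sigma = 4, R = 10)
  expect_equal(logPrior(p), -log(10))
  p1 <- scalarParams("M1", psi = 0.3, theta = 0.4, phi = 0.5, omega0 = 0.1,
                     sigmaM = 3, sigmaF = 2, R = 10)
  expect_equal(logPrior(p1), -2 * log(10))
  # boundary excluded
  expect_equal(logPrior(c(psi = 0.3, p0 = 0.2, sigma = 10), model = "M4",
                        R = 10), -Inf)
  # transformed density agrees with a finite-difference change of variables:
  # density(t) = density(x) * prod_k |dx_k/dt_k|
  t0 <- transformParams(p)
  h <- 1e-5
  logJacNum <- sum(vapply(seq_along(t0), function(k) {
    tp <- t0; tm <- t0
    tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
    xp <- paramValues(untransformParams(tp, "M4"))[k]
    xm <- paramValues(untransformParams(tm, "M4"))[k]
    log(abs((xp - xm) / (2 * h)))
  }, numeric(1)))
  expect_equal(logPrior(p, transformed = TRUE), logPrior(p) + logJacNum,
               tolerance = 1e-7)
})

singleCellData <- function(y1, y2, sex1 = NA_integer_) {
  Y1 <- array(y1, dim = c(1, 1, 1)); Y2 <- array(y2, dim = c(1, 1, 1))
  bilateralData(Y1, Y2, sex1 = sex1, sex2 = NA_integer_)
}

cellTrap <- trapArray(cbind(0.5, 0.5))
cellLat <- function(u = 1L) new("LatentState", z = 1L, u = u,
                                S = cbind(0.5, 0.5), L = 1L)

test_that("single-cell outcome distributions are proper for all four models", {
  set.seed(42)
  for (rep in 1:25) {
    draws <- list(
      scalarParams("M1", psi = runif(1), theta = runif(1), phi = runif(1),
                   omega0 = runif(1), sigmaM = runif(1, 0.05, 2),
                   sigmaF = runif(1, 0.05, 2)),
      scalarParams("M2", psi = runif(1), theta = runif(1), p0 = runif(1),
                   sigmaM = runif(1, 0.05, 2), sigmaF = runif(1, 0.05, 2)),
      scalarParams("M3", psi = runif(1), phi = runif(1), omega0 = runif(1),
                   sigma = runif(1, 0.05, 2)),
      scalarParams("M4", psi = runif(1), p0 = runif(1),
                   sigma = runif(1, 0.05, 2)))
    for (params in draws) {
      u <- rbinom(1, 1, 0.5)
      tot <- sum(vapply(list(c(0, 0), c(1, 0), c(0, 1), c(1, 1)), function(y) {
        exp(completeDataLogLik(singleCellData(y[1], y[2]), cellTrap, params,
                               cellLat(as.integer(u))))
      }, numeric(1)))
      sexFac <- if (params@model %in% c("M1", "M2")) {
        if (u == 1) params@theta else 1 - params@theta
      } else 1
      expect_equal(tot, sexFac, tolerance = 1e-9)
    }
  }
})

test_that("certain detection given entry forbids single-detector outcomes", {
  params <- scalarParams("M3", psi = 0.5, phi = 1, omega0 = 0.4, sigma = 0.5)
  expect_equal(completeDataLogLik(singleCellData(1, 0), cellTrap, params,
                                  cellLat()), -Inf)
  expect_gt(completeDataLogLik(singleCellData(1, 1), cellTrap, params,
                               cellLat()), -Inf)
})

test_that("the single-stage likelihood matches a naive cell-by-cell oracle", {
  set.seed(8)
  M <- 3; J <- 2; K <- 2
  data <- randomBilateral(M, J, K, seed = 8, density = 0.5)
  space <- unitSpace()
  traps <- trapArray(cbind(c(0.3, 0.7), c(0.5, 0.5)))
  lat <- randomLatents(M, space, seed = 9)
  lat@z <- rep(1L, M)
  params <- scalarParams("M4", psi = 0.4, p0 = 0.35, sigma = 0.45)
  Y2star <- reorderByPermutation(data@Y2, lat@L)
  oracle <- 0
  for (i in 1:M) for (j in 1:J) for (k in 1:K) {
    d <- sqrt(sum((lat@S[i, ] - trapCoords(traps)[j, ])^2))
    p <- detectionProbRoyle(0.35, 0.45, d)
    oracle <- oracle + dbinom(data@Y1[i, j, k], 1, p, log = TRUE) +
      dbinom(Y2star[i, j, k], 1, p, log = TRUE)
  }
  expect_equal(completeDataLogLik(data, traps, params, lat), oracle,
               tolerance = 1e-10)
})

test_that("individual factors sum to the total and match the C++ kernel", {
  space <- unitSpace()
  traps <- trapArray(cbind(c(0.3, 0.7), c(0.4, 0.6)))
  for (m in c("M1", "M2", "M3", "M4")) {
    data <- randomBilateral(4, 2, 3, seed = 21, density = 0.3, nObs = 3)
    lat <- randomLatents(4, space, seed = 22, zAll = FALSE)
    lat@z[1:3] <- 1L  # observed rows stay included
    lat@L <- c(2L, 1L, 3L, 4L)
    params <- switch(m,
      M1 = scalarParams("M1", psi = 0.5, theta = 0.4, phi = 0.6,
                        omega0 = 0.3, sigmaM = 0.5, sigmaF = 0.3),
      M2 = scalarParams("M2", psi = 0.5, theta = 0.4, p0 = 0.2,
                        sigmaM = 0.5, sigmaF = 0.3),
      M3 = scalarParams("M3", psi = 0.5, phi = 0.6, omega0 = 0.3,
                        sigma = 0.4),
      M4 = scalarParams("M4", psi = 0.5, p0 = 0.2, sigma = 0.4))
    tot <- completeDataLogLik(data, traps, params, lat)
    parts <- vapply(1:4, individualLogLik, numeric(1), data = data,
                    traps = traps, params = params, latents = lat)
    expect_equal(sum(parts), tot, tolerance = 1e-10)
    ctx <- scrselect:::chainData(data, traps, space, m, params@R)
    llC <- scrselect:::cpp_indiv_loglik(ctx, transformParams(params), lat@z,
                                        lat@u, lat@S,
                                        invertPermutation(lat@L) - 1L)
    expect_equal(as.numeric(parts), as.numeric(llC), tolerance = 1e-10)
    expect_error(individualLogLik(9, data, traps, params, lat), "range")
  }
})

test_that("augmented empty individuals contribute the documented factors", {
  space <- unitSpace()
  traps <- trapArray(cbind(0.5, 0.5))
  data <- bilateralData(array(0, c(2, 1, 2)), array(0, c(2, 1, 2)))
  params <- scalarParams("M3", psi = 0.5, phi = 0.6, omega0 = 0.3, sigma = 0.4)
  lat <- new("LatentState", z = c(0L, 1L), u = c(0L, 0L),
             S = cbind(c(0.5, 0.5), c(0.5, 0.5)), L = 1:2)
  # z = 0: exactly zero; z = 1: K occasions of the no-detection cell mass
  expect_equal(individualLogLik(1, data, traps, params, lat), 0)
  eta <- 0.3
  q0 <- (1 - eta) + eta * (1 - 0.6)^2
  expect_equal(individualLogLik(2, data, traps, params, lat), 2 * log(q0),
               tolerance = 1e-12)
})

test_that("sex-specific model with equal scales collapses to the sexless model", {
  space <- unitSpace()
  traps <- trapArray(cbind(c(0.3, 0.7), c(0.4, 0.6)))
  data <- randomBilateral(3, 2, 2, seed = 31, density = 0.4)
  lat <- randomLatents(3, space, seed = 32)
  p1 <- scalarParams("M1", psi = 0.5, theta = 0.37, phi = 0.6, omega0 = 0.3,
                     sigmaM = 0.4, sigmaF = 0.4)
  p3 <- scalarParams("M3", psi = 0.5, phi = 0.6, omega0 = 0.3, sigma = 0.4)
  ll1 <- scrselect:::indivLogLikAll(data, traps, p1, lat)
  ll3 <- scrselect:::indivLogLikAll(data, traps, p3, lat)
  sexFac <- ifelse(lat@u == 1, log(0.37), log(1 - 0.37))
  expect_equal(ll1, ll3 + sexFac, tolerance = 1e-12)
})

test_that("integrated likelihood equals exhaustive latent marginalization", {
  space <- unitSpace()
  traps <- trapArray(cbind(c(0.3, 0.7), c(0.5, 0.5)))
  grid <- c(2L, 2L)
  # one observed individual on each side (unlinked), one augmented slot
  Y1 <- array(0, c(2, 2, 1)); Y2 <- array(0, c(2, 2, 1))
  Y1[1, 1, 1] <- 1; Y2[1, 2, 1] <- 1
  for (m in c("M3", "M1")) {
    for (withSex in c(FALSE, TRUE)) {
      sex1 <- if (withSex && m == "M1") c(1L, NA) else c(NA_integer_, NA)
      data <- bilateralData(Y1, Y2, sex1 = sex1)
      params <- if (m == "M3")
        scalarParams("M3", psi = 0.4, phi = 0.7, omega0 = 0.3, sigma = 0.5)
      else
        scalarParams("M1", psi = 0.4, theta = 0.35, phi = 0.7, omega0 = 0.3,
                     sigmaM = 0.5, sigmaF = 0.25)
      for (L in list(1:2, 2:1)) {
        got <- integratedLogLik(data, traps, space, params, L, grid = grid)
        want <- ilOracle(data, traps, space, params, L, grid)
        expect_equal(got, want, tolerance = 1e-10)
      }
    }
  }
})

test_that("integrated likelihood degenerates and converges as documented", {
  space <- unitSpace()
  traps <- trapArray(cbind(0.5, 0.5))
  Y1 <- array(1, c(1, 1, 1)); Y2 <- array(1, c(1, 1, 1))
  data <- bilateralData(Y1, Y2)
  params <- scalarParams("M3", psi = 0.999999, phi = 0.7, omega0 = 0.3,
                         sigma = 0.5)
  got <- integratedLogLik(data, traps, space, params, 1L, grid = c(1L, 1L))
  lat <- new("LatentState", z = 1L, u = 0L, S = cbind(0.5, 0.5), L = 1L)
  want <- completeDataLogLik(data, traps, params, lat) + log(params@psi)
  expect_equal(got, want, tolerance = 1e-5)
  # all-zero augmented slot: factor strictly below 1
  data0 <- bilateralData(array(0, c(1, 1, 1)), array(0, c(1, 1, 1)))
  p0 <- scalarParams("M3", psi = 0.3, phi = 0.7, omega0 = 0.3, sigma = 0.5)
  f0 <- integratedLogLik(data0, traps, space, p0, 1L, grid = c(2L, 2L))
  expect_lt(f0, 0)
  expect_gt(f0, log(1 - 0.3))
  # Riemann refinement: successive grid doublings converge, with the
  # default-resolution error already small on the tiny fixture
  Yb1 <- array(0, c(2, 1, 1)); Yb2 <- array(0, c(2, 1, 1))
  Yb1[1, 1, 1] <- 1; Yb2[1, 1, 1] <- 1
  datab <- bilateralData(Yb1, Yb2)
  pb <- scalarParams("M3", psi = 0.4, phi = 0.7, omega0 = 0.3, sigma = 0.5)
  base <- scrselect:::defaultGrid(space)
  v1 <- integratedLogLik(datab, traps, space, pb, 1:2, grid = base)
  v2 <- integratedLogLik(datab, traps, space, pb, 1:2, grid = 2L * base)
  v4 <- integratedLogLik(datab, traps, space, pb, 1:2, grid = 4L * base)
  expect_lt(abs(v2 - v1), 5e-3)
  expect_lt(abs(v4 - v2), abs(v2 - v1))
})
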