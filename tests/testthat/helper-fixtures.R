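# Shared fixtures: the worked bilateral example (3 traps, 4 occasions, two
# fully identified individuals plus one unlinked partial history per side),
# random binary instances, and hand-built PosteriorDraws objects.

# detection histories of the worked example, as J x K matrices per individual
table3Histories <- function() {
  list(
    full1 = list(
      d1 = rbind(c(0, 1, 0, 1), c(1, 0, 0, 1), c(0, 0, 1, 1)),
      d2 = rbind(c(0, 0, 1, 0), c(0, 0, 0, 1), c(1, 0, 0, 0)),
      sim = cbind(trap = 2L, occ = 4L)),
    full2 = list(
      d1 = rbind(c(1, 0, 0, 0), c(0, 0, 0, 1), c(1, 1, 0, 0)),
      d2 = rbind(c(1, 1, 0, 0), c(0, 0, 0, 0), c(0, 0, 1, 0)),
      sim = cbind(trap = 1L, occ = 1L)),
    partial1 = list(
      d1 = rbind(c(1, 0, 0, 1), c(0, 0, 1, 0), c(0, 0, 0, 0)),
      d2 = NULL, sim = NULL),
    partial2 = list(
      d1 = NULL,
      d2 = rbind(c(0, 0, 1, 0), c(1, 0, 0, 0), c(0, 0, 1, 0)),
      sim = NULL))
}

# long-format capture events for loadCaptureData
table3Events <- function() {
  h <- table3Histories()
  rows <- list()
  emit <- function(id, mat, detector, sim) {
    if (is.null(mat)) return()
    w <- which(mat == 1, arr.ind = TRUE)
    for (q in seq_len(nrow(w))) {
      simFlag <- 0L
      if (!is.null(sim) &&
          any(sim[, 1] == w[q, 1] & sim[, 2] == w[q, 2])) simFlag <- 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        individual_id = id, detector = detector,
        trap_id = w[q, 1], occasion = w[q, 2], simultaneous = simFlag)
    }
  }
  emit("A", h$full1$d1, 1L, h$full1$sim); emit("A", h$full1$d2, 2L, h$full1$sim)
  emit("B", h$full2$d1, 1L, h$full2$sim); emit("B", h$full2$d2, 2L, h$full2$sim)
  emit("P1", h$partial1$d1, 1L, NULL)
  emit("P2", h$partial2$d2, 2L, NULL)
  do.call(rbind, rows)
}

table3Traps <- function()
  data.frame(trap_id = 1:3, x = c(1, 2, 3), y = c(1, 1.5, 1))

# random binary bilateral instance with identity permutation = identity
randomBilateral <- function(M, J, K, seed, density = 0.3, nObs = M) {
  set.seed(seed)
  Y1 <- array(rbinom(M * J * K, 1, density), dim = c(M, J, K))
  Y2 <- array(rbinom(M * J * K, 1, density), dim = c(M, J, K))
  if (nObs < M) {
    Y1[(nObs + 1):M, , ] <- 0
    Y2[(nObs + 1):M, , ] <- 0
  }
  # ensure the "observed rows first" convention holds
  ord1 <- order(apply(Y1, 1, sum) == 0)
  ord2 <- order(apply(Y2, 1, sum) == 0)
  bilateralData(Y1[ord1, , , drop = FALSE], Y2[ord2, , , drop = FALSE])
}

randomLatents <- function(M, space, seed, model = "M3", zAll = TRUE) {
  set.seed(seed)
  new("LatentState",
      z = if (zAll) rep(1L, M) else rbinom(M, 1L, 0.7),
      u = rbinom(M, 1L, 0.5),
      S = cbind(runif(M, space@xMin, space@xMax),
                runif(M, space@yMin, space@yMax)),
      L = sample(M))
}

# minimal PosteriorDraws built by hand (identity permutations, sexes zero)
manualDraws <- function(model, natDraws, zDraws, sDraws, R = 10,
                        loglik = NULL, indivLoglik = NULL, LDraws = NULL,
                        uDraws = NULL) {
  n <- nrow(natDraws); M <- ncol(zDraws)
  nm <- paramNames(model)
  colnames(natDraws) <- nm
  td <- natDraws
  sc <- nm %in% c("sigmaM", "sigmaF", "sigma")
  td[, sc] <- td[, sc] / R
  td <- qlogis(td)
  if (is.null(LDraws)) LDraws <- matrix(rep(seq_len(M), each = n), n, M)
  if (is.null(uDraws)) uDraws <- matrix(0L, n, M)
  if (is.null(loglik)) loglik <- numeric(n)
  if (is.null(indivLoglik)) indivLoglik <- matrix(0, n, M)
  new("PosteriorDraws", model = model, scalarDraws = natDraws,
      transformedDraws = td, loglik = loglik, indivLoglik = indivLoglik,
      NDraws = rowSums(zDraws), zDraws = zDraws, uDraws = uDraws,
      LDraws = LDraws, sDraws = sDraws, R = R,
      acceptance = numeric(), config = chainConfig())
}

unitSpace <- function() stateSpace(0, 1, 0, 1)

# exhaustive marginalization oracle for the integrated likelihood
ilOracle <- function(data, traps, space, params, L, grid) {
  M <- nAugmented(data)
  cells <- scrselect:::gridCenters(space, grid)
  G <- nrow(cells)
  sexed <- params@model %in% c("M1", "M2")
  uSets <- if (sexed) expand.grid(rep(list(0:1), M)) else
    as.data.frame(matrix(0L, 1, M))
  zSets <- expand.grid(rep(list(0:1), M))
  cellSets <- expand.grid(rep(list(seq_len(G)), M))
  terms <- c()
  for (zi in seq_len(nrow(zSets))) for (ui in seq_len(nrow(uSets))) {
    z <- as.integer(zSets[zi, ]); u <- as.integer(uSets[ui, ])
    for (ci in seq_len(nrow(cellSets))) {
      S <- cells[as.integer(cellSets[ci, ]), , drop = FALSE]
      lat <- new("LatentState", z = z, u = u, S = S, L = as.integer(L))
      ll <- completeDataLogLik(data, traps, params, lat) +
        sum(z * log(params@psi) + (1 - z) * log(1 - params@psi)) +
        M * log(1 / G)
      terms <- c(terms, ll)
    }
  }
  scrselect:::logSumExp(terms)
}

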