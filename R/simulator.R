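# Synthetic bilateral capture-recapture data under the entry/detection model
# with sex-specific movement, reproducing the twelve benchmark scenarios and
# the 10 x 16 trap design, plus a scaled-down preset sized for desk machines.

#' Build a regular trap grid inside a buffered state space
#'
#' Divides the buffered interior of the state space into `nx` by `ny` equal
#' cells and places one station at each cell centre. With a 5 x 7 space,
#' buffer 1 and a 10 x 16 array this yields spacings of 0.3 (x) and 0.3125
#' (y).
#'
#' @param nx,ny stations along each axis.
#' @param space a [StateSpace-class]; the buffer slot sets the inset.
#' @param buffer optional override of `space@buffer`.
#' @return a [TrapArray-class] with `nx * ny` stations.
#' @examples
#' sp <- stateSpace(0, 5, 0, 7, buffer = 1)
#' tr <- buildTrapGrid(10, 16, sp)
#' nTraps(tr)  # 160
#' @export
buildTrapGrid <- function(nx, ny, space, buffer = space@buffer) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  stopifnot(nx >= 1L, ny >= 1L)
  w <- (space@xMax - space@xMin) - 2 * buffer
  h <- (space@yMax - space@yMin) - 2 * buffer
  if (w <= 0 || h <= 0) stop("buffer too large for the state space")
  dx <- w / nx; dy <- h / ny
  xs <- space@xMin + buffer + (seq_len(nx) - 0.5) * dx
  ys <- space@yMin + buffer + (seq_len(ny) - 0.5) * dy
  coords <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  trapArray(coords, space = space)
}

# omega0, phi rows of the benchmark table; sigma pairs alternate by block
SCENARIO_TABLE <- data.frame(
  id = 1:12,
  omega0 = c(0.01, 0.01, 0.01, 0.01, 0.03, 0.03, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05),
  phi    = c(0.30, 0.90, 0.30, 0.90, 0.80, 0.80, 0.30, 0.50, 0.90, 0.30, 0.50, 0.90),
  sigmaM = c(0.30, 0.30, 0.40, 0.40, 0.30, 0.40, 0.30, 0.30, 0.30, 0.40, 0.40, 0.40),
  sigmaF = c(0.15, 0.15, 0.20, 0.20, 0.15, 0.20, 0.15, 0.15, 0.15, 0.20, 0.20, 0.20))

#' Benchmark simulation scenarios
#'
#' The twelve data-generating parameter sets of the simulation study: all use
#' N = 100 individuals (40 male), augmentation bound M = 400 and K = 50
#' occasions, and vary the baseline trap-entry probability, conditional
#' detection probability and the sex-specific movement scales.
#'
#' @param scenarioId integer in 1..12.
#' @return a [Scenario-class].
#' @examples
#' scenarioParams(5)  # omega0 = 0.03, phi = 0.8, sigmaM = 0.3, sigmaF = 0.15
#' @export
scenarioParams <- function(scenarioId) {
  scenarioId <- as.integer(scenarioId)
  if (length(scenarioId) != 1L || is.na(scenarioId) ||
      scenarioId < 1L || scenarioId > 12L)
    stop("unknown scenario id (must be 1..12)")
  r <- SCENARIO_TABLE[scenarioId, ]
  new("Scenario", omega0 = r$omega0, phi = r$phi, sigmaM = r$sigmaM,
      sigmaF = r$sigmaF, N = 100L, NMale = 40L, M = 400L, K = 50L)
}

#' Scaled-down analogue of a benchmark scenario
#'
#' Same entry/detection/movement parameters as the full-scale scenario, with
#' the study size reduced so that one replicate fits in minutes on one CPU:
#' N = 30 (12 male), M = 100, K = 15, intended for the 7 x 7 trap geometry of
#' [scaledDownGeometry()].
#'
#' @inheritParams scenarioParams
#' @return a [Scenario-class].
#' @export
scaledDownScenario <- function(scenarioId) {
  s <- scenarioParams(scenarioId)
  initialize(s, N = 30L, NMale = 12L, M = 100L, K = 15L)
}

#' Study geometries
#'
#' `fullGeometry()` is the benchmark design: a 5 x 7 state space with buffer 1
#' and a 10 x 16 trap grid (J = 160, spacings 0.3 and 0.3125).
#' `scaledDownGeometry()` is calibrated so that the scaled design keeps the
#' benchmark's per-individual information content despite the shorter survey:
#' expected per-individual trap-entry counts scale as K / spacing^2, so with
#' K = 15 instead of 50 the 7 x 7 grid uses spacing 0.165 (vs 0.3) to match
#' K/s^2, with a buffer of 0.65 (about two male movement scales) on a
#' 2.46 x 2.46 space.
#'
#' @return list with elements `space` and `traps`.
#' @export
fullGeometry <- function() {
  space <- stateSpace(0, 5, 0, 7, buffer = 1)
  list(space = space, traps = buildTrapGrid(10, 16, space))
}

#' @rdname fullGeometry
#' @export
scaledDownGeometry <- function() {
  space <- stateSpace(0, 2.455, 0, 2.455, buffer = 0.65)
  list(space = space, traps = buildTrapGrid(7, 7, space))
}

#' Simulate a bilateral capture-recapture data set
#'
#' Generates data under the entry/detection model: activity centers uniform on
#' the state space, exactly `NMale` males, and for every individual, trap and
#' occasion an entry indicator `w ~ Bernoulli(eta_j(s_i, u_i))` followed,
#' given entry, by two conditionally independent detections with probability
#' `phi` each. Individuals with at least one simultaneous capture (both
#' detectors, same trap and occasion) are fully identified; the rest
#' contribute unlinked single-detector rows, with the true correspondence
#' recorded in the [TruthRecord-class] but hidden from the
#' [IdentityInfo-class]. Sex is recorded for every captured individual
#' (attached to the detector-1 row when the pair is linked).
#'
#' @param scenario a [Scenario-class].
#' @param traps a [TrapArray-class].
#' @param space a [StateSpace-class].
#' @param seed integer seed.
#' @param model data-generating model (`"M1"` default; `"M2"`/`"M4"` use
#'   `phi * omega0`-matched single-stage baselines via `p0 = omega0 * phi`,
#'   `"M3"` ignores sex and uses `sigmaM` for everyone).
#' @return list with elements `data`, `identity`, `truth`.
#' @export
simulateDataset <- function(scenario, traps, space, seed, model = "M1") {
  set.seed(as.integer(seed))
  N <- scenario@N; M <- scenario@M; K <- scenario@K
  J <- nTraps(traps)
  S <- cbind(runif(N, space@xMin, space@xMax),
             runif(N, space@yMin, space@yMax))
  u <- sample(c(rep(1L, scenario@NMale), rep(0L, N - scenario@NMale)))
  sig <- switch(model,
    M3 = rep(scenario@sigmaM, N),
    M4 = rep(scenario@sigmaM, N),
    ifelse(u == 1L, scenario@sigmaM, scenario@sigmaF))
  D2 <- squaredDistances(S, traps)
  twoStage <- model %in% c("M1", "M3")
  cellP <- if (twoStage) scenario@omega0 * exp(-D2 / (2 * sig^2))
           else (scenario@omega0 * scenario@phi) * exp(-D2 / (2 * sig^2))
  Y1full <- array(0L, dim = c(N, J, K))
  Y2full <- array(0L, dim = c(N, J, K))
  for (k in seq_len(K)) {
    if (twoStage) {
      w <- matrix(runif(N * J) < cellP, N, J)
      Y1full[, , k] <- w & (matrix(runif(N * J), N, J) < scenario@phi)
      Y2full[, , k] <- w & (matrix(runif(N * J), N, J) < scenario@phi)
    } else {
      Y1full[, , k] <- matrix(runif(N * J) < cellP, N, J)
      Y2full[, , k] <- matrix(runif(N * J) < cellP, N, J)
    }
  }
  truthScenario <- scenario
  split <- splitObserved(Y1full, Y2full, u, M)
  truth <- new("TruthRecord", sTrue = S, uTrue = u,
               linkTrue = split$linkTrue, scenario = truthScenario)
  list(data = split$data, identity = split$identity, truth = truth)
}

#' Split complete histories into observed bilateral lists
#'
#' Turns per-individual paired histories into the observation surface the
#' models see: detector-1 observed rows first, detector-2 observed rows in a
#' randomized order, known links only for individuals with at least one
#' simultaneous capture, all-zero individuals dropped, and zero-augmentation
#' up to M rows.
#'
#' @param Y1full,Y2full N x J x K binary arrays of complete paired histories.
#' @param u integer(N) true sexes.
#' @param M augmented size.
#' @return list with `data`, `identity`, `linkTrue` (per observed detector-2
#'   row, its detector-1 observed row or NA).
#' @export
splitObserved <- function(Y1full, Y2full, u, M) {
  N <- dim(Y1full)[1L]; J <- dim(Y1full)[2L]; K <- dim(Y1full)[3L]
  seen1 <- apply(Y1full, 1L, sum) > 0
  seen2 <- apply(Y2full, 1L, sum) > 0
  simult <- vapply(seq_len(N), function(i)
    any(Y1full[i, , ] * Y2full[i, , ] > 0), logical(1L))
  obs1 <- which(seen1)
  obs2 <- which(seen2)
  if (M < max(length(obs1), length(obs2)))
    stop("capacity error: M smaller than the number of observed individuals")
  # detector-2 observed rows in randomized order so row order leaks no identity
  obs2 <- obs2[sample.int(length(obs2))]
  Y1 <- array(0, dim = c(M, J, K)); Y2 <- array(0, dim = c(M, J, K))
  if (length(obs1)) Y1[seq_along(obs1), , ] <- Y1full[obs1, , ]
  if (length(obs2)) Y2[seq_along(obs2), , ] <- Y2full[obs2, , ]
  sex1 <- rep(NA_integer_, M); sex2 <- rep(NA_integer_, M)
  sex1[seq_along(obs1)] <- u[obs1]
  linked <- which(simult)
  pairs <- cbind(match(linked, obs1), match(linked, obs2))
  linkTrue <- match(obs2, obs1)  # NA for detector-2-only individuals
  unlinked2 <- setdiff(seq_along(obs2), pairs[, 2L])
  sex2[unlinked2] <- u[obs2[unlinked2]]
  identity <- findFullIdentities(pairs, length(obs1), length(obs2))
  list(data = bilateralData(Y1, Y2, sex1 = sex1, sex2 = sex2),
       identity = identity, linkTrue = linkTrue)
}
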