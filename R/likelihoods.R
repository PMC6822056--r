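# Complete-data and integrated likelihoods for the four competing bilateral
# SCR models.
#
# Model structure (per augmented individual i, given the identity permutation):
#   M1/M3 separate trap entry (probability eta, half-normal in distance from
#   the activity center) from detection conditional on entry (phi, each
#   detector independently). The per-trap-occasion cell is then a zero-inflated
#   pair of Bernoullis: no entry, or entry with two conditionally independent
#   detections.
#   M2/M4 collapse the hierarchy: each detector fires independently with a
#   half-normal detection probability p.
#   M1/M2 carry a sex covariate u driving the movement scale (sigmaM/sigmaF)
#   with P(male) = theta; M3/M4 are sexless with a single sigma.
# The inclusion indicator z_i multiplies the detection factor; a z=0 slot is
# structurally constrained to an all-zero history.

# 0*log(0) = 0; positive count against zero probability is a structural zero
# (-Inf); interior log arguments are floored at 1e-300.
xlogy <- function(x, y) {
  r <- x * log(pmax(y, 1e-300))
  r[x == 0] <- 0
  if (any(bad <- (x > 0 & y <= 0))) r[bad] <- -Inf
  r
}

logSumExp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

colLogMeanExp <- function(m) {
  mx <- apply(m, 2L, max)
  out <- mx + log(colMeans(exp(sweep(m, 2L, mx, "-"))))
  out[!is.finite(mx)] <- -Inf
  out
}

squaredDistances <- function(S, traps) {
  co <- trapCoords(traps)
  outer(S[, 1L], co[, 1L], "-")^2 + outer(S[, 2L], co[, 2L], "-")^2
}

#' Half-normal trap-entry probability
#'
#' Probability that an individual with activity center at distance `distance`
#' from a station passes through it on one occasion:
#' `omega0 * exp(-distance^2 / (2 * sigma^2))`.
#'
#' @param omega0 baseline trap-entry probability (distance 0).
#' @param sigma movement scale.
#' @param distance Euclidean distance(s) from activity center to station.
#' @return entry probabilities, same shape as `distance`.
#' @examples
#' trapEntryProb(0.05, 0.3, 0.3)  # 0.05 * exp(-0.5)
#' @export
trapEntryProb <- function(omega0, sigma, distance) {
  stopifnot(omega0 >= 0, omega0 <= 1, sigma > 0, all(distance >= 0))
  omega0 * exp(-distance^2 / (2 * sigma^2))
}

#' Half-normal baseline detection probability
#'
#' Single-stage counterpart used by the collapsed models: probability that a
#' detector records the individual, `p0 * exp(-distance^2 / (2 * sigma^2))`.
#'
#' @param p0 baseline detection probability.
#' @inheritParams trapEntryProb
#' @return detection probabilities, same shape as `distance`.
#' @export
detectionProbRoyle <- function(p0, sigma, distance) {
  stopifnot(p0 >= 0, p0 <= 1, sigma > 0, all(distance >= 0))
  p0 * exp(-distance^2 / (2 * sigma^2))
}

#' Map scalar parameters to the unconstrained scale and back
#'
#' Probability parameters map by logit; movement scales by logit(sigma/R). The
#' transformed space is all of Euclidean space, which both the random-walk
#' sampler and the Gelfand-Dey tuning densities rely on.
#'
#' @param params a [ScalarParams-class].
#' @return `transformParams()`: named numeric vector.
#' @export
transformParams <- function(params) {
  v <- paramValues(params)
  sc <- names(v) %in% c("sigmaM", "sigmaF", "sigma")
  v[sc] <- v[sc] / params@R
  out <- qlogis(v)
  if (any(!is.finite(out))) stop("parameters must be interior to their support")
  out
}

#' @rdname transformParams
#' @param vec named or ordered numeric vector on the transformed scale.
#' @param model model id.
#' @param R movement-scale prior bound.
#' @return `untransformParams()`: a [ScalarParams-class].
#' @export
untransformParams <- function(vec, model, R = 10) {
  if (any(!is.finite(vec))) stop("transformed parameters must be finite")
  nm <- paramNames(model)
  if (!is.null(names(vec))) vec <- vec[nm]
  v <- plogis(as.numeric(vec))
  names(v) <- nm
  sc <- nm %in% c("sigmaM", "sigmaF", "sigma")
  v[sc] <- v[sc] * R
  do.call(scalarParams, c(list(model = model, R = R), as.list(v)))
}

#' Log prior density of the scalar parameters
#'
#' Independent uniforms: Uniform(0,1) for every probability parameter and
#' Uniform(0,R) for every movement scale. On the transformed scale the
#' log-Jacobian of each logit map is included, so the density is positive on
#' all of Euclidean space.
#'
#' @param params a [ScalarParams-class], or a named numeric vector of
#'   parameter values (natural scale) accompanied by `model` and `R`.
#' @param transformed evaluate the density of the transformed parameters.
#' @param model,R required when `params` is a plain vector.
#' @return log prior density (scalar; `-Inf` outside the support).
#' @export
logPrior <- function(params, transformed = FALSE, model = NULL, R = NULL) {
  if (is(params, "ScalarParams")) {
    v <- paramValues(params); model <- params@model; R <- params@R
  } else v <- params[paramNames(model)]
  nm <- paramNames(model)
  sc <- nm %in% c("sigmaM", "sigmaF", "sigma")
  frac <- v
  frac[sc] <- frac[sc] / R
  if (any(frac <= 0 | frac >= 1)) return(-Inf)
  if (!transformed) return(-sum(sc) * log(R))
  sum(log(frac * (1 - frac)))
}

# sigma per individual given model and sex vector u
sigmaPerIndividual <- function(params, u) {
  if (params@model %in% c("M1", "M2"))
    ifelse(u == 1L, params@sigmaM, params@sigmaF)
  else rep(params@sigma, length(u))
}

# observed sex per slot: detector-1 row label, else the label carried by the
# assigned detector-2 row
observedSexPerSlot <- function(data, assignment) {
  s <- data@sex1
  fill <- is.na(s)
  s[fill] <- data@sex2[assignment[fill]]
  s
}

# slots where both sides carry a recorded sex and they disagree (such an
# assignment of a detector-2 row to a detector-1 row is impossible)
sexConflictPerSlot <- function(data, assignment) {
  s1 <- data@sex1
  s2 <- data@sex2[assignment]
  !is.na(s1) & !is.na(s2) & s1 != s2
}

#' Complete-data log-likelihood
#'
#' Evaluates the joint log-density of the bilateral histories (and recorded
#' sexes, for the sex-structured models) given scalar parameters and the full
#' latent state, with detector-2 rows aligned by the latent permutation. A
#' latent state in which a slot with observed detections has `z = 0`, or in
#' which a sex indicator contradicts a recorded sex, has log-density `-Inf`.
#'
#' @param data a [BilateralData-class].
#' @param traps a [TrapArray-class].
#' @param params a [ScalarParams-class].
#' @param latents a [LatentState-class].
#' @return scalar log-likelihood.
#' @seealso [individualLogLik()], [integratedLogLik()]
#' @export
completeDataLogLik <- function(data, traps, params, latents) {
  sum(indivLogLikAll(data, traps, params, latents))
}

#' Per-individual log-likelihood factors
#'
#' The i-th factor of [completeDataLogLik()]; the factors sum exactly to the
#' complete-data log-likelihood. These are the "data points" over which WAIC
#' partitions the data.
#'
#' @inheritParams completeDataLogLik
#' @param i individual (slot) index in 1..M.
#' @return scalar log-likelihood contribution of individual `i`.
#' @export
individualLogLik <- function(i, data, traps, params, latents) {
  M <- nAugmented(data)
  if (i < 1L || i > M) stop("individual index out of range")
  indivLogLikAll(data, traps, params, latents)[i]
}

# vectorized core: M-vector of per-individual log factors
indivLogLikAll <- function(data, traps, params, latents) {
  K <- nOccasions(data)
  counts <- captureCounts(data, latents@L)
  z <- latents@z; u <- latents@u
  D2 <- squaredDistances(latents@S, traps)
  sig <- sigmaPerIndividual(params, u)
  if (params@model %in% c("M1", "M3")) {
    eta <- params@omega0 * exp(-D2 / (2 * sig^2))
    q0 <- (1 - eta) + eta * (1 - params@phi)^2
    det <- xlogy(counts$yDotDot, params@phi) +
      xlogy(2 * counts$nDot - counts$yDotDot, 1 - params@phi) +
      rowSums(xlogy(counts$nij, eta) + xlogy(K - counts$nij, q0))
  } else {
    p <- params@p0 * exp(-D2 / (2 * sig^2))
    det <- rowSums(xlogy(counts$yijDot, p) +
                   xlogy(2 * K - counts$yijDot, 1 - p))
  }
  hasData <- counts$yDotDot > 0
  ll <- ifelse(z == 1L, det, ifelse(hasData, -Inf, 0))
  if (params@model %in% c("M1", "M2")) {
    ll <- ll + xlogy(u, params@theta) + xlogy(1 - u, 1 - params@theta)
    s2 <- data@sex2[counts$assignment]
    ll[(!is.na(data@sex1) & data@sex1 != u) | (!is.na(s2) & s2 != u)] <- -Inf
  }
  ll
}

# default integration grid: square cells of side ~0.1 spatial unit
defaultGrid <- function(space, cell = 0.1) {
  c(max(1L, round((space@xMax - space@xMin) / cell)),
    max(1L, round((space@yMax - space@yMin) / cell)))
}

gridCenters <- function(space, grid) {
  gx <- grid[1L]; gy <- grid[2L]
  dx <- (space@xMax - space@xMin) / gx
  dy <- (space@yMax - space@yMin) / gy
  xc <- space@xMin + (seq_len(gx) - 0.5) * dx
  yc <- space@yMin + (seq_len(gy) - 0.5) * dy
  cbind(x = rep(xc, times = gy), y = rep(yc, each = gx))
}

#' Integrated likelihood given the identity permutation
#'
#' Marginalizes the latent inclusion indicators and missing sexes analytically
#' and the activity centers by a Riemann sum over a regular grid on the state
#' space, leaving only the scalar parameters and the permutation. Per slot i
#' (rows aligned by `L`):
#' \deqn{f_i = \sum_{u} P(u\mid\theta)\,[(1-\psi)\,1\{\mathrm{all\ zero}\} +
#'   \psi\, \mathrm{mean}_{g}\, f_i(Y_i \mid s_g, u)]}
#' with the u-sum collapsing to the recorded sex where one is available, and
#' dropped entirely for the sexless models.
#'
#' @inheritParams completeDataLogLik
#' @param space the [StateSpace-class] over which activity centers are uniform.
#' @param L integer identity permutation.
#' @param grid integer c(gx, gy) Riemann resolution; default: square cells of
#'   side 0.1 unit.
#' @param perIndividual return the M per-slot log factors instead of their sum.
#' @return scalar integrated log-likelihood (or M-vector).
#' @export
integratedLogLik <- function(data, traps, space, params, L, grid = NULL,
                             perIndividual = FALSE) {
  if (is.null(grid)) grid <- defaultGrid(space)
  K <- nOccasions(data)
  counts <- captureCounts(data, L)
  cells <- gridCenters(space, grid)
  cellD2 <- squaredDistances(cells, traps)
  psi <- params@psi
  sexed <- params@model %in% c("M1", "M2")
  hasData <- counts$yDotDot > 0

  # log mean over grid cells of the detection factor, per slot, for one sigma
  lmeFor <- function(sigma) {
    if (params@model %in% c("M1", "M3")) {
      eta <- params@omega0 * exp(-cellD2 / (2 * sigma^2))
      A <- log(pmax(eta, 1e-300))
      B <- log(pmax((1 - eta) + eta * (1 - params@phi)^2, 1e-300))
      const <- xlogy(counts$yDotDot, params@phi) +
        xlogy(2 * counts$nDot - counts$yDotDot, 1 - params@phi)
      lc <- A %*% t(counts$nij) + B %*% t(K - counts$nij)
    } else {
      p <- params@p0 * exp(-cellD2 / (2 * sigma^2))
      A <- log(pmax(p, 1e-300))
      B <- log(pmax(1 - p, 1e-300))
      const <- 0
      lc <- A %*% t(counts$yijDot) + B %*% t(2 * K - counts$yijDot)
    }
    colLogMeanExp(lc) + const
  }

  inner <- function(lme) {
    # log[(1-psi) 1{all zero} + psi * mean_g f]
    withZero <- log1p(-psi) # only valid for all-zero slots
    term1 <- ifelse(hasData, -Inf, withZero)
    apply(cbind(term1, log(psi) + lme), 1L, logSumExp)
  }

  if (!sexed) {
    lli <- inner(lmeFor(params@sigma))
  } else {
    lmeM <- lmeFor(params@sigmaM)
    lmeF <- lmeFor(params@sigmaF)
    innM <- log(params@theta) + inner(lmeM)
    innF <- log1p(-params@theta) + inner(lmeF)
    hi <- pmax(innM, innF); lo <- pmin(innM, innF)
    both <- ifelse(is.finite(hi), hi + log1p(exp(lo - hi)), hi)
    sObs <- observedSexPerSlot(data, counts$assignment)
    lli <- ifelse(is.na(sObs), both, ifelse(sObs == 1L, innM, innF))
    lli[sexConflictPerSlot(data, counts$assignment)] <- -Inf
  }
  if (perIndividual) lli else sum(lli)
}
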