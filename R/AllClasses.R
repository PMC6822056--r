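#' @useDynLib scrselect, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats cov qchisq qlogis plogis rnorm runif rbinom sd var cor
#'   median quantile setNames
#' @importFrom utils read.csv write.csv
NULL

MODEL_IDS <- c("M1", "M2", "M3", "M4")

#' Rectangular state space
#'
#' A bounded rectangular region within which all activity centers live, together
#' with the buffer width separating the trap array from the boundary.
#' Coordinates are in arbitrary planar units (the same units as trap
#' coordinates and movement scales).
#'
#' @slot xMin,xMax,yMin,yMax numeric(1) rectangle bounds.
#' @slot buffer numeric(1) nonnegative distance between the rectangle boundary
#'   and the region available to the trap array.
#'
#' @seealso [stateSpace()], [buildTrapGrid()]
#' @export
setClass("StateSpace",
  representation(xMin = "numeric", xMax = "numeric",
                 yMin = "numeric", yMax = "numeric", buffer = "numeric"))

setValidity("StateSpace", function(object) {
  msg <- character()
  if (length(object@xMin) != 1L || length(object@xMax) != 1L ||
      length(object@yMin) != 1L || length(object@yMax) != 1L ||
      length(object@buffer) != 1L)
    msg <- c(msg, "all slots must be scalars")
  else {
    if (!(object@xMax > object@xMin)) msg <- c(msg, "xMax must exceed xMin")
    if (!(object@yMax > object@yMin)) msg <- c(msg, "yMax must exceed yMin")
    if (object@buffer < 0) msg <- c(msg, "buffer must be nonnegative")
  }
  if (length(msg)) msg else TRUE
})

#' Array of paired-detector trap stations
#'
#' Coordinates of the J trap stations. Each station carries two collocated
#' detectors (e.g. two opposed camera traps photographing both flanks).
#'
#' @slot coords J x 2 numeric matrix of station coordinates.
#' @slot trapIds integer station labels (unique, 1-based by convention).
#' @export
setClass("TrapArray",
  representation(coords = "matrix", trapIds = "integer"))

setValidity("TrapArray", function(object) {
  msg <- character()
  if (!is.numeric(object@coords) || ncol(object@coords) != 2L)
    msg <- c(msg, "coords must be a numeric J x 2 matrix")
  if (nrow(object@coords) < 1L) msg <- c(msg, "at least one trap is required")
  if (length(object@trapIds) != nrow(object@coords))
    msg <- c(msg, "trapIds length must match the number of rows of coords")
  if (anyDuplicated(object@trapIds)) msg <- c(msg, "trapIds must be unique")
  if (length(msg)) msg else TRUE
})

#' Zero-augmented bilateral capture histories
#'
#' Binary detection arrays from the two detectors after augmentation with
#' all-zero histories up to M pseudo-individuals. Row i of `Y1` is the i-th
#' detector-1 history (the row order of detector 1 defines the "true"
#' individual index); row r of `Y2` is the r-th detector-2 history, whose
#' correspondence to detector-1 rows is in general unknown.
#'
#' @slot Y1,Y2 binary arrays of dimension M x J x K.
#' @slot nObs1,nObs2 integer(1) number of non-all-zero (observed) rows in each
#'   array; observed rows come first.
#' @slot sex1 integer(M), sex recorded for each detector-1 row (1 male,
#'   0 female, NA unknown/uncaptured).
#' @slot sex2 integer(M), sex recorded for each detector-2 row; used for
#'   unlinked detector-2-only histories.
#' @seealso [bilateralData()], [loadCaptureData()], [simulateDataset()]
#' @export
setClass("BilateralData",
  representation(Y1 = "array", Y2 = "array",
                 nObs1 = "integer", nObs2 = "integer",
                 sex1 = "integer", sex2 = "integer"))

setValidity("BilateralData", function(object) {
  msg <- character()
  d1 <- dim(object@Y1); d2 <- dim(object@Y2)
  if (length(d1) != 3L || length(d2) != 3L || !all(d1 == d2))
    return("Y1 and Y2 must be arrays of identical M x J x K dimension")
  if (!all(object@Y1 %in% c(0, 1)) || !all(object@Y2 %in% c(0, 1)))
    msg <- c(msg, "entries must be binary")
  M <- d1[1L]
  if (object@nObs1 > M || object@nObs2 > M)
    msg <- c(msg, "augmented size M must be at least the number of observed rows")
  rs1 <- apply(object@Y1, 1L, sum); rs2 <- apply(object@Y2, 1L, sum)
  if (object@nObs1 < M && any(rs1[(object@nObs1 + 1L):M] > 0))
    msg <- c(msg, "rows beyond nObs1 must be all-zero")
  if (object@nObs2 < M && any(rs2[(object@nObs2 + 1L):M] > 0))
    msg <- c(msg, "rows beyond nObs2 must be all-zero")
  if (length(object@sex1) != M || length(object@sex2) != M)
    msg <- c(msg, "sex1 and sex2 must have length M")
  if (length(msg)) msg else TRUE
})

#' Known identity links between the two detector lists
#'
#' Pairs of rows fixed by verified simultaneous captures (both detectors fire
#' at the same station on the same occasion, with metadata confirming
#' simultaneity). Rows not covered by a link are "free": their correspondence
#' is latent and sampled through the identity permutation.
#'
#' @slot knownLinks integer matrix with columns `det1` and `det2`; row pairs
#'   fixed by simultaneous capture. May have zero rows.
#' @slot free1,free2 integer vectors of unlinked observed row indices on each
#'   side.
#' @export
setClass("IdentityInfo",
  representation(knownLinks = "matrix", free1 = "integer", free2 = "integer"))

setValidity("IdentityInfo", function(object) {
  msg <- character()
  kl <- object@knownLinks
  if (ncol(kl) != 2L) return("knownLinks must have two columns (det1, det2)")
  if (nrow(kl)) {
    if (anyDuplicated(kl[, 1L]) || anyDuplicated(kl[, 2L]))
      msg <- c(msg, "a row may appear in at most one link")
    if (any(object@free1 %in% kl[, 1L]) || any(object@free2 %in% kl[, 2L]))
      msg <- c(msg, "free rows must be disjoint from linked rows")
  }
  if (length(msg)) msg else TRUE
})

#' Per-individual detection count summaries
#'
#' Counts entering the bilateral likelihoods for a single individual: total
#' detections on each detector, the combined total, the per-trap number of
#' occasions with at least one detection (either detector), and the per-trap
#' combined detection totals.
#'
#' @slot y1Total,y2Total,yDotDot,nDot numeric(1) totals.
#' @slot nij,yijDot numeric(J) per-trap counts.
#' @export
setClass("SummaryCounts",
  representation(y1Total = "numeric", y2Total = "numeric",
                 yDotDot = "numeric", nij = "numeric",
                 nDot = "numeric", yijDot = "numeric"))

setValidity("SummaryCounts", function(object) {
  if (object@yDotDot < object@nDot || object@yDotDot > 2 * object@nDot)
    return("must satisfy nDot <= yDotDot <= 2*nDot")
  TRUE
})

#' Scalar parameters of a bilateral SCR model
#'
#' The low-dimensional parameter block: inclusion probability `psi`, male
#' probability `theta` (sex-structured models only), conditional detection
#' probability `phi` and baseline trap-entry probability `omega0` (two-stage
#' models), baseline detection probability `p0` (single-stage models), and the
#' movement scales (`sigmaM`/`sigmaF` for sex-specific models, `sigma`
#' otherwise). `R` is the upper bound of the uniform prior on each movement
#' scale. Irrelevant slots are `NA`.
#'
#' @slot model one of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @slot psi,theta,phi,omega0,p0,sigmaM,sigmaF,sigma numeric(1) parameter
#'   values (NA when not part of the model).
#' @slot R numeric(1) prior upper bound for movement scales.
#' @seealso [scalarParams()], [paramNames()], [transformParams()]
#' @export
setClass("ScalarParams",
  representation(model = "character", psi = "numeric", theta = "numeric",
                 phi = "numeric", omega0 = "numeric", p0 = "numeric",
                 sigmaM = "numeric", sigmaF = "numeric", sigma = "numeric",
                 R = "numeric"))

setValidity("ScalarParams", function(object) {
  if (!object@model %in% MODEL_IDS) return("model must be one of M1..M4")
  if (!(object@R > 0)) return("R must be positive")
  v <- paramValues(object)
  if (anyNA(v)) return("required parameters for this model are missing (NA)")
  probs <- setdiff(names(v), c("sigmaM", "sigmaF", "sigma"))
  if (any(v[probs] <= 0 | v[probs] > 1))
    return("probability parameters must lie in (0,1] (interior for sampling; the boundary only for degenerate checks)")
  sc <- intersect(names(v), c("sigmaM", "sigmaF", "sigma"))
  if (any(v[sc] <= 0 | v[sc] >= object@R))
    return("movement scales must lie strictly in (0,R)")
  TRUE
})

#' Latent state of the augmented model
#'
#' High-dimensional latent block: inclusion indicators `z`, sex indicators `u`
#' (sex-structured models), activity centers `S`, and the identity permutation
#' `L` mapping each detector-2 row to its true individual index (detector-1 row
#' order).
#'
#' @slot z integer(M) inclusion indicators.
#' @slot u integer(M) sex indicators (1 male / 0 female; all zero when the
#'   model carries no sex structure).
#' @slot S M x 2 numeric matrix of activity centers.
#' @slot L integer(M) permutation; `L[r]` is the true index (slot) of
#'   detector-2 row r.
#' @export
setClass("LatentState",
  representation(z = "integer", u = "integer", S = "matrix", L = "integer"))

setValidity("LatentState", function(object) {
  M <- length(object@z)
  msg <- character()
  if (!all(object@z %in% 0:1)) msg <- c(msg, "z entries must be 0/1")
  if (length(object@u) != M || !all(object@u %in% 0:1))
    msg <- c(msg, "u must be 0/1 of length M")
  if (nrow(object@S) != M || ncol(object@S) != 2L)
    msg <- c(msg, "S must be an M x 2 matrix")
  if (length(object@L) != M || !setequal(object@L, seq_len(M)))
    msg <- c(msg, "L must be a permutation of 1..M")
  if (length(msg)) msg else TRUE
})

#' Sampler configuration
#'
#' @slot nIter total number of sweeps.
#' @slot burnIn sweeps discarded before retention.
#' @slot thin retention stride.
#' @slot seed integer seed for the chain.
#' @slot proposalScales named numeric of random-walk standard deviations on the
#'   transformed scale (a single unnamed value recycles to all scalars).
#' @slot sProposalScale numeric(1) activity-center random-walk step.
#' @slot storeLatents logical(1); retain latent snapshots (needed by the MAP
#'   search, GD estimators and posterior predictive loss).
#' @slot fixedParams named numeric of scalar parameters frozen at their initial
#'   values (on the natural scale); empty for a full fit.
#' @slot adapt logical(1); Robbins-Monro adaptation of the proposal scales
#'   during burn-in, targeting ~35% acceptance (on by default; fully
#'   reproducible under a fixed seed).
#' @seealso [chainConfig()], [runChain()]
#' @export
setClass("ChainConfig",
  representation(nIter = "integer", burnIn = "integer", thin = "integer",
                 seed = "integer", proposalScales = "numeric",
                 sProposalScale = "numeric", storeLatents = "logical",
                 fixedParams = "numeric", adapt = "logical"))

setValidity("ChainConfig", function(object) {
  msg <- character()
  if (object@burnIn < 0L || object@burnIn >= object@nIter)
    msg <- c(msg, "need 0 <= burnIn < nIter")
  if (object@thin < 1L) msg <- c(msg, "thin must be >= 1")
  if (any(object@proposalScales <= 0) || object@sProposalScale <= 0)
    msg <- c(msg, "proposal scales must be positive")
  if (length(msg)) msg else TRUE
})

#' Retained posterior draws
#'
#' Output of [runChain()]: retained scalar draws on both scales, per-draw
#' complete-data log-likelihoods, the per-individual log-likelihood matrix, the
#' per-draw population size, and (optionally) thinned latent snapshots.
#'
#' @slot model model identifier.
#' @slot scalarDraws,transformedDraws numeric matrices (n retained x p) with
#'   named columns.
#' @slot loglik numeric(n) complete-data log-likelihood of each retained draw.
#' @slot indivLoglik n x M matrix of per-individual log-likelihood factors.
#' @slot NDraws numeric(n) population size (sum of z) per draw.
#' @slot zDraws,uDraws,LDraws integer matrices (n x M) of latent snapshots
#'   (zero rows if latents are not stored).
#' @slot sDraws numeric array n x M x 2 of activity-center snapshots.
#' @slot R numeric(1) movement-scale prior bound used for the fit.
#' @slot acceptance named numeric of acceptance rates.
#' @slot config the [ChainConfig-class] used.
#' @export
setClass("PosteriorDraws",
  representation(model = "character", scalarDraws = "matrix",
                 transformedDraws = "matrix", loglik = "numeric",
                 indivLoglik = "matrix", NDraws = "numeric",
                 zDraws = "matrix", uDraws = "matrix", LDraws = "matrix",
                 sDraws = "array", R = "numeric", acceptance = "numeric",
                 config = "ChainConfig"))

#' Tuning density for the Gelfand-Dey estimator
#'
#' A density g on the transformed (unconstrained) parameter scale, fitted to
#' posterior draws: multivariate normal, multivariate t (variance-matched), or
#' a normal truncated to a Mahalanobis confidence ellipsoid and renormalized.
#'
#' @slot kind `"mvnormal"`, `"mvt"` or `"truncnormal"`.
#' @slot df degrees of freedom (mvt only, NA otherwise).
#' @slot conf confidence coefficient of the truncation ellipsoid (truncnormal
#'   only).
#' @slot location numeric(p) fitted location.
#' @slot scaleMat p x p positive-definite scale matrix.
#' @seealso [fitTuningDensity()], [logDensity()]
#' @export
setClass("TuningDensity",
  representation(kind = "character", df = "numeric", conf = "numeric",
                 location = "numeric", scaleMat = "matrix"))

setValidity("TuningDensity", function(object) {
  if (!object@kind %in% c("mvnormal", "mvt", "truncnormal"))
    return("kind must be mvnormal, mvt or truncnormal")
  if (object@kind == "mvt" && !(is.finite(object@df) && object@df > 2))
    return("mvt requires df > 2 (variance-matched scale)")
  if (object@kind == "truncnormal" &&
      !(is.finite(object@conf) && object@conf > 0 && object@conf < 1))
    return("truncnormal requires conf in (0,1)")
  ev <- tryCatch(eigen(object@scaleMat, symmetric = TRUE,
                       only.values = TRUE)$values, error = function(e) NA)
  if (anyNA(ev) || any(ev <= 0))
    return("scaleMat must be symmetric positive definite")
  TRUE
})

#' One model-selection score
#'
#' @slot method identifier (`"gd_map"`, `"gd_il"`, `"hm"`, `"dic1"`, `"dic2"`,
#'   `"waic1"`, `"waic2"`, `"waic3"`, `"ppl"`).
#' @slot model model identifier the score belongs to.
#' @slot value the criterion value (log marginal likelihood for evidence
#'   methods; criterion value otherwise).
#' @slot penalty effective-parameter or variance penalty where defined, NA
#'   otherwise.
#' @slot metadata list of method-specific details (tuning kind, grid
#'   resolution, dropped-summand counts, ...).
#' @export
setClass("CriterionResult",
  representation(method = "character", model = "character", value = "numeric",
                 penalty = "numeric", metadata = "list"))

#' Simulation scenario
#'
#' Data-generating parameter set: baseline trap-entry probability, conditional
#' detection probability, sex-specific movement scales, true abundance and sex
#' split, augmentation bound and number of occasions.
#'
#' @slot omega0,phi,sigmaM,sigmaF numeric(1) generating parameters.
#' @slot N,NMale,M,K integer(1) design constants.
#' @seealso [scenarioParams()], [simulateDataset()]
#' @export
setClass("Scenario",
  representation(omega0 = "numeric", phi = "numeric", sigmaM = "numeric",
                 sigmaF = "numeric", N = "integer", NMale = "integer",
                 M = "integer", K = "integer"))

setValidity("Scenario", function(object) {
  msg <- character()
  if (object@omega0 < 0 || object@omega0 >= 1 ||
      object@phi <= 0 || object@phi > 1)
    msg <- c(msg, "need omega0 in [0,1) and phi in (0,1] (degenerate bounds allowed for checks)")
  if (object@sigmaM <= 0 || object@sigmaF <= 0)
    msg <- c(msg, "movement scales must be positive")
  if (object@NMale < 0L || object@NMale > object@N || object@N > object@M)
    msg <- c(msg, "need 0 <= NMale <= N <= M")
  if (object@K < 1L) msg <- c(msg, "K must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated data set
#'
#' @slot sTrue N x 2 matrix of true activity centers.
#' @slot uTrue integer(N) true sex indicators.
#' @slot linkTrue integer(nObs2) true detector-1 row index of each observed
#'   detector-2 row (NA when the individual was never captured by detector 1).
#' @slot scenario the generating [Scenario-class].
#' @export
setClass("TruthRecord",
  representation(sTrue = "matrix", uTrue = "integer", linkTrue = "integer",
                 scenario = "Scenario"))

#' Simulation-study configuration
#'
#' @slot scenarios integer scenario ids (1..12).
#' @slot nSim integer(1) replicates per scenario.
#' @slot models character subset of M1..M4 to fit.
#' @slot methods character criterion identifiers to evaluate.
#' @slot preset `"scaled_down"` or `"full"` study geometry.
#' @slot seed integer(1) master seed (per-replicate seeds derive from it).
#' @slot chainConfig the [ChainConfig-class] template used for every fit.
#' @export
setClass("ExperimentConfig",
  representation(scenarios = "integer", nSim = "integer", models = "character",
                 methods = "character", preset = "character", seed = "integer",
                 chainConfig = "ChainConfig"))

setValidity("ExperimentConfig", function(object) {
  msg <- character()
  if (object@nSim < 1L) msg <- c(msg, "nSim must be >= 1")
  if (!all(object@models %in% MODEL_IDS)) msg <- c(msg, "unknown model id")
  if (!object@preset %in% c("scaled_down", "full"))
    msg <- c(msg, "preset must be scaled_down or full")
  if (length(msg)) msg else TRUE
})
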