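# Constructors, accessors and show methods for the core classes.

#' Create a rectangular state space
#'
#' @param xMin,xMax,yMin,yMax rectangle bounds.
#' @param buffer nonnegative inset between the boundary and the trap array.
#' @return a [StateSpace-class].
#' @examples
#' sp <- stateSpace(0, 5, 0, 7, buffer = 1)
#' spaceArea(sp)
#' @export
stateSpace <- function(xMin, xMax, yMin, yMax, buffer = 0) {
  new("StateSpace", xMin = as.numeric(xMin), xMax = as.numeric(xMax),
      yMin = as.numeric(yMin), yMax = as.numeric(yMax),
      buffer = as.numeric(buffer))
}

#' @rdname scrselect-generics
setMethod("spaceArea", "StateSpace", function(x)
  (x@xMax - x@xMin) * (x@yMax - x@yMin))

setMethod("show", "StateSpace", function(object) {
  cat(sprintf("StateSpace: [%g, %g] x [%g, %g] (area %g), buffer %g\n",
              object@xMin, object@xMax, object@yMin, object@yMax,
              spaceArea(object), object@buffer))
})

#' Create a trap array
#'
#' @param coords J x 2 matrix of station coordinates.
#' @param space optional [StateSpace-class]; when supplied, all stations must
#'   lie strictly inside it.
#' @param trapIds integer labels (defaults to 1..J).
#' @return a [TrapArray-class].
#' @export
trapArray <- function(coords, space = NULL, trapIds = seq_len(nrow(coords))) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y")
  if (!is.null(space)) {
    inside <- coords[, 1L] > space@xMin & coords[, 1L] < space@xMax &
      coords[, 2L] > space@yMin & coords[, 2L] < space@yMax
    if (!all(inside))
      stop("all trap coordinates must lie strictly inside the state space")
  }
  new("TrapArray", coords = coords, trapIds = as.integer(trapIds))
}

#' @rdname scrselect-generics
setMethod("nTraps", "TrapArray", function(x) nrow(x@coords))

#' @rdname scrselect-generics
setMethod("trapCoords", "TrapArray", function(x) x@coords)

setMethod("show", "TrapArray", function(object) {
  cat(sprintf("TrapArray with %d stations; x in [%g, %g], y in [%g, %g]\n",
              nTraps(object), min(object@coords[, 1]), max(object@coords[, 1]),
              min(object@coords[, 2]), max(object@coords[, 2])))
})

#' Create a bilateral data object
#'
#' Wraps two binary M x J x K arrays, reordering rows so that observed
#' (non-all-zero) histories come first on each side.
#'
#' @param Y1,Y2 binary arrays of dimension M x J x K.
#' @param sex1,sex2 optional integer vectors of recorded sex per row (1 male,
#'   0 female, NA unknown).
#' @return a [BilateralData-class].
#' @export
bilateralData <- function(Y1, Y2, sex1 = NULL, sex2 = NULL) {
  stopifnot(length(dim(Y1)) == 3L, all(dim(Y1) == dim(Y2)))
  M <- dim(Y1)[1L]
  if (is.null(sex1)) sex1 <- rep(NA_integer_, M)
  if (is.null(sex2)) sex2 <- rep(NA_integer_, M)
  n1 <- sum(apply(Y1, 1L, sum) > 0)
  n2 <- sum(apply(Y2, 1L, sum) > 0)
  new("BilateralData", Y1 = Y1, Y2 = Y2,
      nObs1 = as.integer(n1), nObs2 = as.integer(n2),
      sex1 = as.integer(sex1), sex2 = as.integer(sex2))
}

#' @rdname scrselect-generics
setMethod("nAugmented", "BilateralData", function(x) dim(x@Y1)[1L])

#' @rdname scrselect-generics
setMethod("nTraps", "BilateralData", function(x) dim(x@Y1)[2L])

#' @rdname scrselect-generics
setMethod("nOccasions", "BilateralData", function(x) dim(x@Y1)[3L])

#' @rdname scrselect-generics
setMethod("nObserved", "BilateralData", function(x)
  c(det1 = x@nObs1, det2 = x@nObs2))

setMethod("show", "BilateralData", function(object) {
  cat(sprintf(paste0("BilateralData: M = %d augmented individuals, J = %d traps,",
                     " K = %d occasions\n  observed rows: %d (detector 1),",
                     " %d (detector 2); detections: %d + %d\n"),
              nAugmented(object), nTraps(object), nOccasions(object),
              object@nObs1, object@nObs2, sum(object@Y1), sum(object@Y2)))
})

#' Create an identity-link object
#'
#' @param knownLinks two-column matrix (det1 row, det2 row) of verified links;
#'   may be empty.
#' @param free1,free2 unlinked observed row indices on each side.
#' @return an [IdentityInfo-class].
#' @export
identityInfo <- function(knownLinks = matrix(integer(), ncol = 2L),
                         free1 = integer(), free2 = integer()) {
  knownLinks <- matrix(as.integer(knownLinks), ncol = 2L,
                       dimnames = list(NULL, c("det1", "det2")))
  new("IdentityInfo", knownLinks = knownLinks,
      free1 = as.integer(free1), free2 = as.integer(free2))
}

#' @rdname scrselect-generics
setMethod("knownLinks", "IdentityInfo", function(x) x@knownLinks)

setMethod("show", "IdentityInfo", function(object) {
  cat(sprintf("IdentityInfo: %d known links, %d free detector-1 rows, %d free detector-2 rows\n",
              nrow(object@knownLinks), length(object@free1), length(object@free2)))
})

#' Scalar parameter sets for the four competing models
#'
#' `paramNames()` lists the scalar parameters of each model, in the canonical
#' order used throughout (transformed vectors, draw matrices, proposal scales).
#'
#' @param model one of `"M1"`..`"M4"`.
#' @return `paramNames()`: character vector.
#' @export
paramNames <- function(model) {
  switch(model,
    M1 = c("psi", "theta", "phi", "omega0", "sigmaM", "sigmaF"),
    M2 = c("psi", "theta", "p0", "sigmaM", "sigmaF"),
    M3 = c("psi", "phi", "omega0", "sigma"),
    M4 = c("psi", "p0", "sigma"),
    stop("unknown model id: ", model))
}

#' @rdname paramNames
#' @param object a [ScalarParams-class].
#' @return `paramValues()`: named numeric of the model's parameters.
#' @export
paramValues <- function(object) {
  nm <- paramNames(object@model)
  vapply(nm, function(p) slot(object, p), numeric(1L))
}

#' Create a scalar parameter set
#'
#' @param model model id (`"M1"`..`"M4"`).
#' @param ... named parameter values; exactly those in `paramNames(model)`.
#' @param R upper bound of the uniform prior on movement scales.
#' @return a [ScalarParams-class].
#' @examples
#' scalarParams("M4", psi = 0.3, p0 = 0.1, sigma = 0.4)
#' @export
scalarParams <- function(model, ..., R = 10) {
  vals <- list(...)
  nm <- paramNames(model)
  missing <- setdiff(nm, names(vals))
  if (length(missing))
    stop("missing parameters for ", model, ": ", paste(missing, collapse = ", "))
  extra <- setdiff(names(vals), nm)
  if (length(extra))
    stop("parameters not in ", model, ": ", paste(extra, collapse = ", "))
  full <- list(psi = NA_real_, theta = NA_real_, phi = NA_real_,
               omega0 = NA_real_, p0 = NA_real_, sigmaM = NA_real_,
               sigmaF = NA_real_, sigma = NA_real_)
  for (p in nm) full[[p]] <- as.numeric(vals[[p]])
  do.call(new, c(list("ScalarParams", model = model, R = as.numeric(R)), full))
}

setMethod("show", "ScalarParams", function(object) {
  v <- paramValues(object)
  cat(sprintf("ScalarParams [%s] (R = %g):\n", object@model, object@R))
  print(round(v, 5))
})

setMethod("show", "CriterionResult", function(object) {
  cat(sprintf("CriterionResult: %s for %s = %.4f", object@method,
              object@model, object@value))
  if (is.finite(object@penalty)) cat(sprintf(" (penalty %.4f)", object@penalty))
  cat("\n")
})

#' @rdname scrselect-generics
setMethod("criterionValue", "CriterionResult", function(x) x@value)

#' Create a sampler configuration
#'
#' Defaults follow the package's scaled-down study preset; see the methods
#' vignette for the reasoning behind each value.
#'
#' @param nIter,burnIn,thin chain length controls.
#' @param seed integer chain seed.
#' @param proposalScales random-walk sd on the transformed scale; either a
#'   single value recycled to all scalars or a named vector.
#' @param sProposalScale activity-center random-walk step (spatial units).
#' @param storeLatents retain latent snapshots (default TRUE).
#' @param fixedParams named numeric of scalars to freeze (natural scale).
#' @param adapt Robbins-Monro proposal-scale adaptation during burn-in
#'   (deterministic given the seed).
#' @return a [ChainConfig-class].
#' @export
chainConfig <- function(nIter = 5000L, burnIn = 1000L, thin = 1L, seed = 1L,
                        proposalScales = 0.1, sProposalScale = 0.25,
                        storeLatents = TRUE, fixedParams = numeric(),
                        adapt = TRUE) {
  new("ChainConfig", nIter = as.integer(nIter), burnIn = as.integer(burnIn),
      thin = as.integer(thin), seed = as.integer(seed),
      proposalScales = proposalScales, sProposalScale = sProposalScale,
      storeLatents = storeLatents, fixedParams = fixedParams, adapt = adapt)
}

setMethod("show", "ChainConfig", function(object) {
  cat(sprintf("ChainConfig: %d iterations (burn-in %d, thin %d), seed %d\n",
              object@nIter, object@burnIn, object@thin, object@seed))
})

#' @rdname scrselect-generics
setMethod("populationSizeDraws", "PosteriorDraws", function(x) x@NDraws)

setMethod("show", "PosteriorDraws", function(object) {
  n <- length(object@loglik)
  cat(sprintf("PosteriorDraws [%s]: %d retained draws, M = %d\n",
              object@model, n, ncol(object@indivLoglik)))
  if (n) {
    cat(sprintf("  posterior median N = %g\n", stats::median(object@NDraws)))
    cat("  acceptance rates:\n")
    print(round(object@acceptance, 3))
  }
})

setMethod("show", "TuningDensity", function(object) {
  lab <- switch(object@kind,
    mvnormal = "multivariate normal",
    mvt = sprintf("multivariate t (df = %g)", object@df),
    truncnormal = sprintf("truncated normal (conf = %g)", object@conf))
  cat(sprintf("TuningDensity: %s in %d dimensions\n", lab,
              length(object@location)))
})

setMethod("show", "Scenario", function(object) {
  cat(sprintf(paste0("Scenario: omega0 = %g, phi = %g, sigmaM = %g, sigmaF = %g;",
                     " N = %d (%d male), M = %d, K = %d\n"),
              object@omega0, object@phi, object@sigmaM, object@sigmaF,
              object@N, object@NMale, object@M, object@K))
})
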