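# Metropolis-within-Gibbs posterior sampling with data augmentation and
# latent identity-permutation updates. The sweep kernel lives in C++
# (src/scr_kernels.cpp); this file handles state construction, configuration
# plumbing, and the PosteriorDraws container.

modelCode <- function(model) match(model, MODEL_IDS)

# assemble the immutable data context handed to the C++ kernels
chainData <- function(data, traps, space, model, R = 10) {
  M <- nAugmented(data); J <- nTraps(data); K <- nOccasions(data)
  C1 <- apply(data@Y1, c(1L, 2L), sum)
  C2 <- apply(data@Y2, c(1L, 2L), sum)
  obs1 <- which(rowSums(C1) > 0)
  obs2 <- which(rowSums(C2) > 0)
  oi1 <- rep(-1L, M); oi1[obs1] <- seq_along(obs1) - 1L
  oi2 <- rep(-1L, M); oi2[obs2] <- seq_along(obs2) - 1L
  n1o <- max(1L, length(obs1)); n2o <- max(1L, length(obs2))
  ov <- array(0, dim = c(n1o, n2o, J))
  if (length(obs1) && length(obs2))
    for (j in seq_len(J)) {
      m1 <- matrix(data@Y1[obs1, j, ], length(obs1), K)
      m2 <- matrix(data@Y2[obs2, j, ], length(obs2), K)
      ov[seq_along(obs1), seq_along(obs2), j] <- m1 %*% t(m2)
    }
  sexNA <- function(s) { s[is.na(s)] <- -1L; as.integer(s) }
  list(M = M, J = J, K = K, model = modelCode(model), R = R,
       C1 = C1, C2 = C2, obsIdx1 = oi1, obsIdx2 = oi2, ov = ov,
       traps = trapCoords(traps),
       bounds = c(space@xMin, space@xMax, space@yMin, space@yMax),
       sex1 = sexNA(data@sex1), sex2 = sexNA(data@sex2))
}

# initial permutation consistent with known links: linked rows pinned to their
# slots, free observed detector-2 rows parked on augmented slots first, then
# on sex-compatible free observed slots
initPermutation <- function(data, identity) {
  M <- nAugmented(data)
  kl <- knownLinks(identity)
  L <- rep(NA_integer_, M)
  if (nrow(kl)) L[kl[, 2L]] <- kl[, 1L]
  freeRowsObs <- setdiff(seq_len(data@nObs2), kl[, 2L])
  augRows <- setdiff(seq_len(M), c(kl[, 2L], freeRowsObs))
  freeSlotsAug <- setdiff(seq(data@nObs1 + 1L, length.out = M - data@nObs1),
                          kl[, 1L])
  freeSlotsObs <- setdiff(seq_len(data@nObs1), kl[, 1L])
  pool <- c(freeSlotsAug, freeSlotsObs)
  for (r in freeRowsObs) {
    ok <- vapply(pool, function(i) {
      is.na(data@sex2[r]) || is.na(data@sex1[i]) ||
        data@sex1[i] == data@sex2[r]
    }, logical(1L))
    if (!any(ok))
      stop("identity-conflict error: no permutation consistent with known links")
    pick <- pool[which(ok)[1L]]
    L[r] <- pick
    pool <- setdiff(pool, pick)
  }
  L[augRows] <- sample(pool)
  if (anyNA(L) || !setequal(L, seq_len(M)))
    stop("identity-conflict error: no permutation consistent with known links")
  L
}

#' Initialize the sampler state
#'
#' Scalars are drawn from their priors; inclusion is set for every slot that
#' carries observed detections (on either side, after the initial
#' link-consistent permutation); activity centers start at each individual's
#' mean capture location (uniform for uncaptured slots); missing sexes draw
#' from their prior given theta.
#'
#' @param data a [BilateralData-class].
#' @param identity an [IdentityInfo-class].
#' @param traps a [TrapArray-class].
#' @param space a [StateSpace-class].
#' @param model model id.
#' @param seed integer seed.
#' @param R movement-scale prior bound.
#' @param fixedParams named numeric of scalar values to pin (natural scale).
#' @return list with elements `params` ([ScalarParams-class]) and `latents`
#'   ([LatentState-class]).
#' @export
initState <- function(data, identity, traps, space, model, seed, R = 10,
                      fixedParams = numeric()) {
  set.seed(as.integer(seed))
  M <- nAugmented(data)
  nm <- paramNames(model)
  v <- runif(length(nm))
  names(v) <- nm
  sc <- nm %in% c("sigmaM", "sigmaF", "sigma")
  v[sc] <- v[sc] * R
  if (length(fixedParams)) {
    bad <- setdiff(names(fixedParams), nm)
    if (length(bad)) stop("fixedParams not in model: ", paste(bad, collapse = ", "))
    v[names(fixedParams)] <- fixedParams
  }
  params <- do.call(scalarParams, c(list(model = model, R = R), as.list(v)))
  L <- initPermutation(data, identity)
  a <- invertPermutation(L)
  C1 <- apply(data@Y1, c(1L, 2L), sum)
  C2 <- apply(data@Y2, c(1L, 2L), sum)[a, , drop = FALSE]
  hasData <- rowSums(C1) + rowSums(C2) > 0
  z <- as.integer(hasData)
  u <- integer(M)
  if (model %in% c("M1", "M2")) {
    u <- ifelse(!is.na(data@sex1), data@sex1,
                ifelse(!is.na(data@sex2[a]), data@sex2[a],
                       rbinom(M, 1L, if ("theta" %in% names(v)) v[["theta"]] else 0.5)))
  }
  co <- trapCoords(traps)
  S <- cbind(runif(M, space@xMin, space@xMax),
             runif(M, space@yMin, space@yMax))
  tot <- C1 + C2
  cap <- which(rowSums(tot) > 0)
  if (length(cap)) {
    S[cap, 1L] <- (tot[cap, , drop = FALSE] %*% co[, 1L]) / rowSums(tot)[cap]
    S[cap, 2L] <- (tot[cap, , drop = FALSE] %*% co[, 2L]) / rowSums(tot)[cap]
  }
  latents <- new("LatentState", z = z, u = as.integer(u), S = S,
                 L = as.integer(L))
  list(params = params, latents = latents)
}

freeSets <- function(data, identity) {
  M <- nAugmented(data)
  kl <- knownLinks(identity)
  list(freeRows = setdiff(seq_len(M), kl[, 2L]) - 1L,
       freeSlots = setdiff(seq_len(M), kl[, 1L]) - 1L)
}

#' One sweep of identity-permutation updates
#'
#' Proposes `nProposals` swaps, each choosing one free detector-2 row and one
#' free target slot uniformly (known links are never disturbed) and accepting
#' by the Metropolis ratio of the complete-data likelihood factors of the two
#' affected slots. This is the same kernel [runChain()] applies once per
#' sweep.
#'
#' @inheritParams initState
#' @param params a [ScalarParams-class].
#' @param latents current [LatentState-class].
#' @param nProposals number of proposals (default M).
#' @return the updated [LatentState-class].
#' @export
updateIdentityPermutation <- function(latents, data, identity, traps, space,
                                      params, nProposals = nAugmented(data)) {
  ctx <- chainData(data, traps, space, params@model, params@R)
  fs <- freeSets(data, identity)
  res <- cpp_perm_sweep(ctx, transformParams(params), latents@z, latents@u,
                        latents@S, invertPermutation(latents@L) - 1L,
                        fs$freeRows, fs$freeSlots, as.integer(nProposals))
  a <- res$arow + 1L
  initialize(latents, L = invertPermutation(a))
}

scalesVector <- function(config, model) {
  nm <- paramNames(model)
  ps <- config@proposalScales
  if (is.null(names(ps)) || !length(names(ps))) {
    out <- rep(ps[[1L]], length(nm))
  } else {
    out <- rep(0.1, length(nm))
    names(out) <- nm
    out[intersect(names(ps), nm)] <- ps[intersect(names(ps), nm)]
  }
  as.numeric(out)
}

#' Run one posterior chain
#'
#' Metropolis-within-Gibbs: random-walk updates of each transformed scalar,
#' random-walk activity-center moves with reflection at the state-space
#' boundary (prior refresh for empty z=0 slots), Gibbs inclusion updates for
#' all-zero slots, two-point Gibbs updates for missing sexes, and one
#' identity-permutation sweep per iteration. Fixed seed implies bit-identical
#' output.
#'
#' @inheritParams initState
#' @param config a [ChainConfig-class].
#' @param updates character subset of `c("S", "z", "u", "L")`; latent blocks
#'   to update (all by default; mainly for degenerate-chain diagnostics).
#' @param init optional list(params, latents) overriding [initState()].
#' @return a [PosteriorDraws-class].
#' @export
runChain <- function(data, identity, traps, space, model, config,
                     R = 10, updates = c("S", "z", "u", "L"), init = NULL) {
  ctx <- chainData(data, traps, space, model, R)
  if (is.null(init))
    init <- initState(data, identity, traps, space, model, config@seed,
                      R = R, fixedParams = config@fixedParams)
  else set.seed(config@seed)
  params <- init$params; latents <- init$latents
  nm <- paramNames(model)
  fixed <- as.integer(nm %in% names(config@fixedParams))
  fs <- freeSets(data, identity)
  cinit <- list(tp = transformParams(params), z = latents@z, u = latents@u,
                S = latents@S, arow = invertPermutation(latents@L) - 1L)
  conf <- list(nIter = config@nIter, burnIn = config@burnIn,
               thin = config@thin, scales = scalesVector(config, model),
               sScale = config@sProposalScale, fixed = fixed,
               adapt = config@adapt, storeLatents = config@storeLatents,
               updateS = "S" %in% updates, updateZ = "z" %in% updates,
               updateU = "u" %in% updates, updateL = "L" %in% updates,
               nPerm = nAugmented(data), freeRows = fs$freeRows,
               freeSlots = fs$freeSlots)
  res <- cpp_run_chain(ctx, cinit, conf)
  if (is.null(dim(res$sDraws)))
    res$sDraws <- array(numeric(), dim = c(0L, nAugmented(data), 2L))
  sc <- res$npDraws; colnames(sc) <- nm
  td <- res$tDraws; colnames(td) <- nm
  acc <- res$acceptance
  names(acc) <- c(nm, "S", "L")
  LD <- res$LDraws
  new("PosteriorDraws", model = model, scalarDraws = sc,
      transformedDraws = td, loglik = as.numeric(res$loglik),
      indivLoglik = res$indivLoglik, NDraws = as.numeric(res$NDraws),
      zDraws = res$zDraws, uDraws = res$uDraws, LDraws = LD,
      sDraws = res$sDraws, R = R, acceptance = acc, config = config)
}

#' Export retained draws
#'
#' Writes one row per retained iteration with named scalar columns plus the
#' complete-data log-likelihood and the population size, and a JSON metadata
#' sidecar (model, seed, configuration). Latent snapshots, when stored, go to
#' an RDS sidecar.
#'
#' @param draws a [PosteriorDraws-class].
#' @param file path of the CSV to write.
#' @param latentSidecar write `<file>.latents.rds` with the latent snapshots.
#' @return `file`, invisibly.
#' @export
writeDraws <- function(draws, file, latentSidecar = FALSE) {
  df <- as.data.frame(draws@scalarDraws)
  df$loglik <- draws@loglik
  df$N <- draws@NDraws
  write.csv(df, file, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- list(model = draws@model, seed = draws@config@seed,
                 nIter = draws@config@nIter, burnIn = draws@config@burnIn,
                 thin = draws@config@thin, R = draws@R,
                 acceptance = as.list(round(draws@acceptance, 4)))
    jsonlite::write_json(meta, paste0(file, ".meta.json"), auto_unbox = TRUE)
  }
  if (latentSidecar)
    saveRDS(list(z = draws@zDraws, u = draws@uDraws, L = draws@LDraws,
                 S = draws@sDraws), paste0(file, ".latents.rds"))
  invisible(file)
}
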