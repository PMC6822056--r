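# Bayesian model-selection estimators computed from retained posterior draws:
# Gelfand-Dey marginal-likelihood estimators (MAP and integrated-likelihood
# approximations) over a family of tuning densities, the harmonic mean
# estimator, DIC (two penalty forms), WAIC (three penalty forms), the
# posterior predictive loss criterion, and winner selection.

nScalarParams <- function(model) length(paramNames(model))

zPriorLog <- function(psi, N, M) N * log(psi) + (M - N) * log1p(-psi)

arowMatrix <- function(LDraws) {
  t(apply(LDraws, 1L, invertPermutation)) - 1L
}

latentStateFromDraw <- function(draws, d) {
  new("LatentState", z = as.integer(draws@zDraws[d, ]),
      u = as.integer(draws@uDraws[d, ]),
      S = cbind(draws@sDraws[d, , 1L], draws@sDraws[d, , 2L]),
      L = as.integer(draws@LDraws[d, ]))
}

#' Iterative MAP search over retained draws
#'
#' Estimates the posterior mode of (scalar block, latent block) from the MCMC
#' output. Starting from the draw with the largest joint posterior kernel
#' f(Y|mu) pi(mu), the algorithm alternates: fix the latent block and scan all
#' draws' scalar blocks for an improvement, then fix the scalar block and scan
#' all draws' latent blocks, accepting only improvements, until a full sweep
#' yields none (or `maxSweeps` is hit). The kernel sequence is monotone
#' non-decreasing and the final value is at least the best joint-draw value.
#'
#' @param draws a [PosteriorDraws-class] with stored latents.
#' @param data,traps,space the data surfaces the chain was fitted to.
#' @param maxSweeps iteration cap on full coordinate sweeps.
#' @return list with `params` ([ScalarParams-class]), `latents`
#'   ([LatentState-class]), `logPosteriorKernel`, `loglik` (complete-data
#'   log-likelihood at the mode), `kernelPath` (value per accepted step), and
#'   the selected draw indices `dScalar`, `dLatent`.
#' @export
mapSearch <- function(draws, data, traps, space, maxSweeps = 20L) {
  n <- length(draws@loglik)
  if (!nrow(draws@zDraws)) stop("mapSearch needs stored latent draws")
  ctx <- chainData(data, traps, space, draws@model, draws@R)
  M <- nAugmented(data)
  psi <- draws@scalarDraws[, "psi"]
  Nd <- draws@NDraws
  joint <- draws@loglik + zPriorLog(psi, Nd, M)
  d0 <- which.max(joint)
  dScalar <- d0; dLatent <- d0
  cur <- joint[d0]
  path <- cur
  arows <- arowMatrix(draws@LDraws)
  for (sweep in seq_len(maxSweeps)) {
    improved <- FALSE
    # scan scalar draws against the fixed latent block
    lf <- cpp_scalar_scan(ctx, draws@transformedDraws,
                          draws@zDraws[dLatent, ], draws@uDraws[dLatent, ],
                          cbind(draws@sDraws[dLatent, , 1L],
                                draws@sDraws[dLatent, , 2L]),
                          arows[dLatent, ])
    cand <- lf + zPriorLog(psi, Nd[dLatent], M)
    b <- which.max(cand)
    if (cand[b] > cur) {
      dScalar <- b; cur <- cand[b]; path <- c(path, cur); improved <- TRUE
    }
    # scan latent draws against the fixed scalar block
    lf2 <- cpp_latent_scan(ctx, draws@transformedDraws[dScalar, ],
                           draws@zDraws, draws@uDraws, arows, draws@sDraws)
    cand2 <- lf2 + zPriorLog(psi[dScalar], Nd, M)
    b2 <- which.max(cand2)
    if (cand2[b2] > cur) {
      dLatent <- b2; cur <- cand2[b2]; path <- c(path, cur); improved <- TRUE
    }
    if (!improved) break
  }
  latents <- latentStateFromDraw(draws, dLatent)
  params <- untransformParams(draws@transformedDraws[dScalar, ], draws@model,
                              draws@R)
  loglikAtMode <- sum(cpp_indiv_loglik(ctx, draws@transformedDraws[dScalar, ],
                                       latents@z, latents@u, latents@S,
                                       invertPermutation(latents@L) - 1L))
  list(params = params, latents = latents, logPosteriorKernel = cur,
       loglik = loglikAtMode, kernelPath = path,
       dScalar = dScalar, dLatent = dLatent)
}

#' Generic Gelfand-Dey evidence estimator
#'
#' Core identity: the posterior expectation of g(mu) / (f(Y|mu) pi(mu)) equals
#' 1/m(Y) for any proper density g. The estimator is the negative log of the
#' average of those ratios over retained draws, computed in log space.
#' Non-finite summands are dropped with their count reported.
#'
#' @param logg log tuning density at each draw.
#' @param loglik log-likelihood at each draw.
#' @param logprior log prior density at each draw (same parameterization as
#'   `logg`).
#' @return log marginal-likelihood estimate; attribute `nDropped` counts
#'   excluded summands.
#' @export
logMarginalGD <- function(logg, loglik, logprior) {
  summand <- logg - loglik - logprior
  # -Inf summands are legitimate zero ratios (e.g. a truncated tuning density
  # vanishing at a draw) and stay in the average; NaN/+Inf are failed
  # evaluations and are excluded with their count reported
  keep <- !(is.nan(summand) | summand == Inf)
  if (!any(keep) || all(summand[keep] == -Inf))
    stop("estimation failure: no usable Gelfand-Dey summands")
  v <- -(logSumExp(summand[keep]) - log(sum(keep)))
  attr(v, "nDropped") <- sum(!keep)
  v
}

#' Harmonic mean evidence estimator
#'
#' The Gelfand-Dey estimator with g equal to the prior: minus the log of the
#' average inverse likelihood over retained draws.
#'
#' @param loglik numeric vector of complete-data log-likelihoods at retained
#'   draws, or a [PosteriorDraws-class].
#' @param model optional model label for the result.
#' @return a [CriterionResult-class] with the log marginal estimate.
#' @export
logMarginalHM <- function(loglik, model = NA_character_) {
  if (is(loglik, "PosteriorDraws")) {
    model <- loglik@model; loglik <- loglik@loglik
  }
  keep <- is.finite(loglik)
  if (!any(keep)) stop("estimation failure: no finite log-likelihood draws")
  v <- -(logSumExp(-loglik[keep]) - log(sum(keep)))
  new("CriterionResult", method = "hm", model = model, value = v,
      penalty = NA_real_, metadata = list(nDropped = sum(!keep)))
}

transformedPriorRows <- function(tDraws) {
  l <- plogis(tDraws)
  rowSums(log(l) + log1p(-l))
}

#' Gelfand-Dey estimator with MAP approximation
#'
#' Fixes the latent block at its MAP estimate from [mapSearch()] and applies
#' the Gelfand-Dey identity to the scalar block alone, on the transformed
#' scale (the tuning density is fitted there and the prior carries the logit
#' Jacobians).
#'
#' @inheritParams mapSearch
#' @param tuning a [TuningDensity-class], or NULL to fit a multivariate
#'   normal.
#' @param map optional precomputed [mapSearch()] result (reused across the
#'   tuning family).
#' @return a [CriterionResult-class] (`value` = log marginal estimate).
#' @export
logMarginalGDMap <- function(draws, data, traps, space, tuning = NULL,
                             map = NULL) {
  if (is.null(map)) map <- mapSearch(draws, data, traps, space)
  if (is.null(tuning)) tuning <- fitTuningDensity(draws, "mvnormal")
  ctx <- chainData(data, traps, space, draws@model, draws@R)
  lat <- map$latents
  lf <- cpp_scalar_scan(ctx, draws@transformedDraws, lat@z, lat@u, lat@S,
                        invertPermutation(lat@L) - 1L)
  lg <- logDensity(tuning, draws@transformedDraws)
  lpi <- transformedPriorRows(draws@transformedDraws)
  v <- logMarginalGD(lg, lf, lpi)
  new("CriterionResult", method = "gd_map", model = draws@model,
      value = as.numeric(v), penalty = NA_real_,
      metadata = list(tuning = tuning@kind, df = tuning@df,
                      conf = tuning@conf, nDropped = attr(v, "nDropped"),
                      mapKernel = map$logPosteriorKernel))
}

#' Gelfand-Dey estimator with integrated-likelihood approximation
#'
#' Replaces the complete-data likelihood by the integrated likelihood (z and
#' missing sexes marginalized analytically, activity centers by a Riemann
#' sum), conditioning on each draw's identity permutation. The permutation's
#' uniform prior (1/M!) cancels against the matching factor in the tuning
#' density on the joint space, leaving the scalar-block expression.
#'
#' @inheritParams logMarginalGDMap
#' @param grid Riemann grid `c(gx, gy)` (default: 0.1-unit cells).
#' @param drawIndices optional subset of retained draws to evaluate (the
#'   integrated likelihood is the expensive term); default all draws.
#' @return a [CriterionResult-class].
#' @export
logMarginalGDIL <- function(draws, data, traps, space, tuning = NULL,
                            grid = NULL, drawIndices = NULL) {
  if (!nrow(draws@LDraws)) stop("gd_il needs stored permutation draws")
  if (is.null(tuning)) tuning <- fitTuningDensity(draws, "mvnormal")
  if (is.null(drawIndices)) drawIndices <- seq_along(draws@loglik)
  if (is.null(grid)) grid <- defaultGrid(space)
  lf <- vapply(drawIndices, function(d) {
    params <- untransformParams(draws@transformedDraws[d, ], draws@model,
                                draws@R)
    integratedLogLik(data, traps, space, params, draws@LDraws[d, ],
                     grid = grid)
  }, numeric(1L))
  td <- draws@transformedDraws[drawIndices, , drop = FALSE]
  lg <- logDensity(tuning, td)
  lpi <- transformedPriorRows(td)
  v <- logMarginalGD(lg, lf, lpi)
  new("CriterionResult", method = "gd_il", model = draws@model,
      value = as.numeric(v), penalty = NA_real_,
      metadata = list(tuning = tuning@kind, df = tuning@df,
                      conf = tuning@conf, grid = grid,
                      nDraws = length(drawIndices),
                      nDropped = attr(v, "nDropped")))
}

#' Deviance information criterion
#'
#' `DIC = D(mu_hat) + 2 p_DIC` with `D(mu_hat) = -2 log f(Y|mu_hat)` at the
#' MAP estimate. Variant 1 penalizes by twice the gap between the MAP
#' log-likelihood and the posterior mean log-likelihood; variant 2 by twice
#' the posterior variance of the log-likelihood (denominator N, always
#' nonnegative).
#'
#' @param loglik numeric vector of per-draw log-likelihoods, or a
#'   [PosteriorDraws-class].
#' @param loglikAtMap log-likelihood at the MAP estimate (e.g.
#'   `mapSearch(...)$loglik`).
#' @param variant 1 or 2.
#' @param model optional model label.
#' @return a [CriterionResult-class] (`value` = DIC, `penalty` = p_DIC).
#' @export
dic <- function(loglik, loglikAtMap, variant = 1L, model = NA_character_) {
  if (is(loglik, "PosteriorDraws")) {
    model <- loglik@model; loglik <- loglik@loglik
  }
  stopifnot(variant %in% 1:2, all(is.finite(loglik)), is.finite(loglikAtMap))
  n <- length(loglik)
  p <- if (variant == 1L) 2 * (loglikAtMap - mean(loglik))
       else 2 * mean((loglik - mean(loglik))^2)
  new("CriterionResult", method = paste0("dic", variant), model = model,
      value = -2 * loglikAtMap + 2 * p, penalty = p,
      metadata = list(devianceAtMap = -2 * loglikAtMap))
}

#' Watanabe-Akaike information criterion
#'
#' Partitions the data by augmented individual. `WAIC = -2 sum_i lppd_i +
#' 2 p_WAIC`, with `lppd_i` the log posterior-mean individual likelihood.
#' Penalty variants: (1) twice the Jensen gap between lppd and the mean
#' individual log-likelihood, (2) the summed posterior variance of the
#' individual log-likelihoods, (3) twice the summed posterior mean absolute
#' deviation (absolute-error analogue of variant 2).
#'
#' @param indivLoglik draws x M matrix of per-individual log-likelihoods, or a
#'   [PosteriorDraws-class].
#' @param variant 1, 2 or 3.
#' @param model optional model label.
#' @return a [CriterionResult-class] (`value` = WAIC, `penalty` = p_WAIC).
#' @export
waic <- function(indivLoglik, variant = 1L, model = NA_character_) {
  if (is(indivLoglik, "PosteriorDraws")) {
    model <- indivLoglik@model; indivLoglik <- indivLoglik@indivLoglik
  }
  stopifnot(variant %in% 1:3, all(is.finite(indivLoglik)))
  lppd <- apply(indivLoglik, 2L, function(v) logSumExp(v) - log(length(v)))
  mi <- colMeans(indivLoglik)
  p <- switch(variant,
    `1` = 2 * sum(lppd - mi),
    `2` = sum(colMeans(sweep(indivLoglik, 2L, mi, "-")^2)),
    `3` = 2 * sum(colMeans(abs(sweep(indivLoglik, 2L, mi, "-")))))
  new("CriterionResult", method = paste0("waic", variant), model = model,
      value = -2 * sum(lppd) + 2 * p, penalty = p,
      metadata = list(lppd = sum(lppd)))
}

#' Posterior predictive loss criterion
#'
#' For each used draw, one replicate data set is simulated from the fitted
#' model at that draw's parameters and latents; over the 2MJK vectorized
#' binary cells the criterion sums squared deviation of the observed data
#' from the posterior-predictive cell means (goodness of fit) plus the
#' posterior-predictive cell variances (complexity penalty).
#'
#' @inheritParams mapSearch
#' @param drawIndices subset of retained draws to use (default all).
#' @param seed integer seed for replicate simulation.
#' @return a [CriterionResult-class] (`value` = total criterion, `penalty` =
#'   variance term; `metadata$gof` = goodness-of-fit term).
#' @export
posteriorPredictiveLoss <- function(draws, data, traps, space,
                                    drawIndices = NULL, seed = 1L) {
  if (!nrow(draws@zDraws)) stop("posterior predictive loss needs stored latents")
  if (is.null(drawIndices)) drawIndices <- seq_along(draws@loglik)
  if (length(drawIndices) < 10L)
    warning("fewer than 10 draws; posterior predictive loss will be noisy")
  ctx <- chainData(data, traps, space, draws@model, draws@R)
  set.seed(as.integer(seed))
  res <- cpp_ppl(ctx, draws@transformedDraws, draws@zDraws, draws@uDraws,
                 draws@LDraws, draws@sDraws,
                 as.numeric(data@Y1), as.numeric(data@Y2),
                 as.integer(drawIndices))
  new("CriterionResult", method = "ppl", model = draws@model,
      value = res$value, penalty = res$penalty,
      metadata = list(gof = res$gof, nDraws = res$nDraws))
}

#' Select the preferred model from per-model criterion results
#'
#' Evidence methods (Gelfand-Dey, harmonic mean) prefer the largest log
#' marginal; DIC, WAIC and posterior predictive loss prefer the smallest
#' value. Exact ties break toward the model with fewer scalar parameters and
#' are reported in the `tie` attribute.
#'
#' @param results list of [CriterionResult-class] objects, one per model, all
#'   from the same method.
#' @return the selected model id (character); attribute `tie` lists tied
#'   models (if any).
#' @export
selectModel <- function(results) {
  methods <- vapply(results, function(r) r@method, character(1L))
  if (length(unique(methods)) != 1L)
    stop("mixed methods: all results must come from the same criterion")
  vals <- vapply(results, criterionValue, numeric(1L))
  models <- vapply(results, function(r) r@model, character(1L))
  evidence <- methods[1L] %in% c("gd_map", "gd_il", "hm")
  score <- if (evidence) vals else -vals
  best <- which(score == max(score))
  tie <- NULL
  if (length(best) > 1L) {
    tie <- models[best]
    best <- best[which.min(vapply(models[best], nScalarParams, numeric(1L)))]
  } else best <- best[1L]
  out <- models[best]
  attr(out, "tie") <- tie
  out
}

#' Compute a batch of model-selection criteria for one fitted model
#'
#' Computes the requested criterion variants from one chain's retained draws:
#' both Gelfand-Dey approximations across the full tuning family (or a
#' subset), the harmonic mean, both DICs, the three WAICs and the posterior
#' predictive loss; 25 variants in all.
#'
#' @inheritParams mapSearch
#' @param methods character vector of method identifiers (default all).
#' @param tunings data frame as [tuningFamily()] (rows restrict the family).
#' @param ilDrawIndices,ilGrid evaluation controls for the
#'   integrated-likelihood approximation.
#' @param pplDrawIndices,pplSeed controls for the posterior predictive loss.
#' @return list of [CriterionResult-class] objects, named
#'   `method[.tuning]`.
#' @export
computeCriteria <- function(draws, data, traps, space,
                            methods = c("gd_map", "gd_il", "hm", "dic1",
                                        "dic2", "waic1", "waic2", "waic3",
                                        "ppl"),
                            tunings = tuningFamily(),
                            ilDrawIndices = NULL, ilGrid = NULL,
                            pplDrawIndices = NULL, pplSeed = 1L) {
  out <- list()
  needMap <- any(c("gd_map", "dic1", "dic2") %in% methods)
  map <- if (needMap) mapSearch(draws, data, traps, space) else NULL
  fitFam <- function() {
    lapply(seq_len(nrow(tunings)), function(q)
      fitTuningDensity(draws, tunings$kind[q], df = tunings$df[q],
                       conf = tunings$conf[q]))
  }
  if (any(c("gd_map", "gd_il") %in% methods)) fam <- fitFam()
  if ("gd_map" %in% methods)
    for (q in seq_len(nrow(tunings)))
      out[[paste0("gd_map.", tunings$label[q])]] <-
        logMarginalGDMap(draws, data, traps, space, tuning = fam[[q]],
                         map = map)
  if ("gd_il" %in% methods)
    for (q in seq_len(nrow(tunings)))
      out[[paste0("gd_il.", tunings$label[q])]] <-
        logMarginalGDIL(draws, data, traps, space, tuning = fam[[q]],
                        grid = ilGrid, drawIndices = ilDrawIndices)
  if ("hm" %in% methods) out$hm <- logMarginalHM(draws)
  if ("dic1" %in% methods) out$dic1 <- dic(draws, map$loglik, 1L)
  if ("dic2" %in% methods) out$dic2 <- dic(draws, map$loglik, 2L)
  for (v in 1:3)
    if (paste0("waic", v) %in% methods)
      out[[paste0("waic", v)]] <- waic(draws, v)
  if ("ppl" %in% methods)
    out$ppl <- posteriorPredictiveLoss(draws, data, traps, space,
                                       drawIndices = pplDrawIndices,
                                       seed = pplSeed)
  out
}

#' Flatten criterion results to a data frame
#'
#' @param results list of [CriterionResult-class] (possibly nested by model).
#' @return data frame with columns `model`, `method`, `variant`, `value`,
#'   `penalty`.
#' @export
criteriaTable <- function(results) {
  rows <- lapply(names(results), function(nmm) {
    r <- results[[nmm]]
    data.frame(model = r@model, method = r@method,
               variant = nmm, value = r@value, penalty = r@penalty)
  })
  do.call(rbind, rows)
}
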