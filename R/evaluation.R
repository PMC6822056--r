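# Simulation-study orchestration and the study's performance measures:
# true-model selection proportions, average RMSE, and posterior pairwise
# correlations.

#' Empirical model-selection proportions
#'
#' Frequencies with which each model is selected across replicates. A t-way
#' tie contributes 1/t to each tied model.
#'
#' @param winners list (or character vector) of per-replicate winners; a
#'   replicate with a tie is a character vector of the tied models.
#' @param models model universe (columns of the result).
#' @return named numeric of proportions summing to 1.
#' @export
selectionProportions <- function(winners, models = MODEL_IDS) {
  if (!is.list(winners)) winners <- as.list(winners)
  out <- setNames(numeric(length(models)), models)
  for (w in winners) {
    tie <- attr(w, "tie")
    picks <- if (!is.null(tie)) tie else w
    out[picks] <- out[picks] + 1 / length(picks)
  }
  out / length(winners)
}

#' Average root mean square error across replicates
#'
#' Per replicate, the MSE of the retained draws about the true value; the
#' criterion is the square root of the mean of those MSEs.
#'
#' @param drawsPerSim list of numeric draw vectors, one per replicate.
#' @param trueValue the generating value.
#' @return scalar average RMSE.
#' @examples
#' averageRMSE(list(c(90, 110)), 100)  # 10
#' @export
averageRMSE <- function(drawsPerSim, trueValue) {
  stopifnot(length(drawsPerSim) >= 1L, all(lengths(drawsPerSim) > 0L))
  mses <- vapply(drawsPerSim, function(v) mean((v - trueValue)^2), numeric(1L))
  sqrt(mean(mses))
}

#' Posterior pairwise correlation
#'
#' Pearson correlation between two retained-draw vectors (scalar parameters
#' by name, or `"N"` for the population size).
#'
#' @param draws a [PosteriorDraws-class].
#' @param paramA,paramB parameter names.
#' @return correlation in \[-1, 1\], or NA (with a message) when either vector
#'   is degenerate.
#' @export
posteriorPairwiseCorrelation <- function(draws, paramA, paramB) {
  pull <- function(p) {
    if (p == "N") draws@NDraws
    else if (p %in% colnames(draws@scalarDraws)) draws@scalarDraws[, p]
    else stop("unknown parameter: ", p)
  }
  a <- pull(paramA); b <- pull(paramB)
  if (length(a) < 2L) stop("need at least two draws")
  if (sd(a) == 0 || sd(b) == 0) {
    message("zero-variance draw vector; correlation undefined")
    return(NA_real_)
  }
  cor(a, b)
}

# deterministic per-replicate seed, kept well below 2^31
replicateSeed <- function(seed, scenarioId, t) {
  (as.integer(seed) * 997L + scenarioId * 131L + t * 7L) %% 2000000000L
}

#' Create an experiment configuration
#'
#' @param scenarios integer scenario ids (1..12).
#' @param nSim replicates per scenario.
#' @param models models to fit to every replicate.
#' @param methods criterion identifiers to evaluate.
#' @param preset `"scaled_down"` (7 x 7 traps, K = 15, N = 30, M = 100) or
#'   `"full"` (10 x 16 traps, K = 50, N = 100, M = 400).
#' @param seed master seed.
#' @param config [ChainConfig-class] template (its seed slot is overridden
#'   per replicate and model).
#' @return an [ExperimentConfig-class].
#' @export
experimentConfig <- function(scenarios = 9L, nSim = 5L, models = MODEL_IDS,
                             methods = c("gd_map", "hm", "dic1", "dic2",
                                         "waic1", "waic2", "waic3", "ppl"),
                             preset = "scaled_down", seed = 1L,
                             config = chainConfig()) {
  new("ExperimentConfig", scenarios = as.integer(scenarios),
      nSim = as.integer(nSim), models = models, methods = methods,
      preset = preset, seed = as.integer(seed), chainConfig = config)
}

# true scalar values implied by a scenario (for RMSE of estimable parameters)
scenarioTruth <- function(scenario) {
  c(psi = scenario@N / scenario@M, theta = scenario@NMale / scenario@N,
    phi = scenario@phi, omega0 = scenario@omega0,
    sigmaM = scenario@sigmaM, sigmaF = scenario@sigmaF)
}

#' Run the simulation-and-evaluation study
#'
#' For every scenario and replicate: simulate bilateral data under the
#' two-stage sex-specific model, fit each competing model by MCMC, evaluate
#' the requested model-selection criteria, and record winners and draws of N.
#' Everything is seeded deterministically from the master seed; reruns are
#' bit-identical. When `outDir` is given, per-replicate criterion tables are
#' written as JSON artifacts.
#'
#' @param config an [ExperimentConfig-class].
#' @param outDir optional artifact directory.
#' @param tunings tuning-density subset for the Gelfand-Dey methods (default:
#'   the multivariate normal only; pass [tuningFamily()] for all nine).
#' @param ilDrawFraction fraction of retained draws used by the
#'   integrated-likelihood approximation (its per-draw Riemann sum dominates
#'   cost).
#' @param verbose print per-stage progress.
#' @return list with `selection` (data frame of per-scenario, per-method
#'   selection proportions), `rmse` (average RMSE of N and of estimable
#'   scalars per model), `correlations` (posterior correlations with N),
#'   `values` (raw per-replicate criterion values), `winners`, `failures`.
#' @export
runExperiment <- function(config, outDir = NULL,
                          tunings = tuningFamily()[1, , drop = FALSE],
                          ilDrawFraction = 0.1, verbose = FALSE) {
  geom <- if (config@preset == "full") fullGeometry() else scaledDownGeometry()
  scen <- function(id) if (config@preset == "full") scenarioParams(id)
                       else scaledDownScenario(id)
  methods <- config@methods
  selRows <- list(); rmseRows <- list(); corRows <- list()
  winnersAll <- list(); failures <- list(); valueRows <- list()
  for (sid in config@scenarios) {
    sc <- scen(sid)
    truth <- scenarioTruth(sc)
    winners <- setNames(vector("list", length(methods)), methods)
    NDrawsPerModel <- setNames(vector("list", length(config@models)),
                               config@models)
    scalarDrawsPerModel <- setNames(vector("list", length(config@models)),
                                    config@models)
    corAcc <- list()
    for (t in seq_len(config@nSim)) {
      repSeed <- replicateSeed(config@seed, sid, t)
      repFile <- if (!is.null(outDir))
        file.path(outDir, sprintf("scenario%02d_rep%02d.json", sid, t))
      else NULL
      sim <- simulateDataset(sc, geom$traps, geom$space, seed = repSeed)
      repResults <- list()
      failed <- FALSE
      for (m in config@models) {
        cc <- config@chainConfig
        cc@seed <- as.integer((repSeed + 13L * modelCode(m)) %% 2000000000L)
        fit <- tryCatch(
          runChain(sim$data, sim$identity, geom$traps, geom$space, m, cc),
          error = function(e) e)
        if (inherits(fit, "error")) {
          failures[[length(failures) + 1L]] <-
            list(scenario = sid, rep = t, model = m,
                 message = conditionMessage(fit))
          failed <- TRUE
          break
        }
        nRet <- length(fit@loglik)
        ilIdx <- unique(round(seq(1L, nRet,
                                  length.out = max(25L, ceiling(nRet * ilDrawFraction)))))
        crit <- computeCriteria(fit, sim$data, geom$traps, geom$space,
                                methods = methods, tunings = tunings,
                                ilDrawIndices = ilIdx,
                                pplSeed = cc@seed)
        repResults[[m]] <- crit
        vt <- criteriaTable(crit)
        vt$scenario <- sid; vt$rep <- t
        valueRows[[length(valueRows) + 1L]] <- vt
        NDrawsPerModel[[m]] <- c(NDrawsPerModel[[m]],
                                 list(populationSizeDraws(fit)))
        scalarDrawsPerModel[[m]] <- c(scalarDrawsPerModel[[m]],
                                      list(fit@scalarDraws))
        for (pp in colnames(fit@scalarDraws)) {
          r <- posteriorPairwiseCorrelation(fit, "N", pp)
          corAcc[[paste(m, pp)]] <- c(corAcc[[paste(m, pp)]], r)
        }
        if (verbose)
          message(sprintf("scenario %d rep %d model %s: median N = %g",
                          sid, t, m, median(populationSizeDraws(fit))))
      }
      if (failed) next
      for (meth in methods) {
        pickOne <- function(crit, meth) {
          nms <- names(crit)
          hit <- nms[nms == meth | startsWith(nms, paste0(meth, "."))][1L]
          crit[[hit]]
        }
        res <- lapply(repResults, pickOne, meth = meth)
        winners[[meth]] <- c(winners[[meth]], list(selectModel(res)))
      }
      if (!is.null(repFile) && requireNamespace("jsonlite", quietly = TRUE)) {
        dir.create(dirname(repFile), showWarnings = FALSE, recursive = TRUE)
        tab <- do.call(rbind, lapply(repResults, criteriaTable))
        jsonlite::write_json(tab, repFile, dataframe = "rows")
      }
    }
    for (meth in methods) {
      if (!length(winners[[meth]])) next
      props <- selectionProportions(winners[[meth]], MODEL_IDS)
      selRows[[length(selRows) + 1L]] <-
        data.frame(scenario = sid, method = meth, model = names(props),
                   proportion = as.numeric(props),
                   nReplicates = length(winners[[meth]]))
    }
    for (m in config@models) {
      if (!length(NDrawsPerModel[[m]])) next
      rmseRows[[length(rmseRows) + 1L]] <-
        data.frame(scenario = sid, model = m, parameter = "N",
                   rmse = averageRMSE(NDrawsPerModel[[m]], sc@N))
      shared <- intersect(paramNames(m), names(truth))
      # sexless sigma and single-stage p0 have no generating value
      if (m %in% c("M3", "M4")) shared <- setdiff(shared, c("sigma", "p0"))
      for (pp in shared) {
        dl <- lapply(scalarDrawsPerModel[[m]], function(mat) mat[, pp])
        rmseRows[[length(rmseRows) + 1L]] <-
          data.frame(scenario = sid, model = m, parameter = pp,
                     rmse = averageRMSE(dl, truth[[pp]]))
      }
    }
    for (key in names(corAcc)) {
      parts <- strsplit(key, " ")[[1L]]
      corRows[[length(corRows) + 1L]] <-
        data.frame(scenario = sid, model = parts[1L], parameter = parts[2L],
                   corWithN = mean(corAcc[[key]], na.rm = TRUE))
    }
    winnersAll[[as.character(sid)]] <- winners
  }
  list(selection = do.call(rbind, selRows),
       rmse = do.call(rbind, rmseRows),
       correlations = do.call(rbind, corRows),
       values = do.call(rbind, valueRows),
       winners = winnersAll, failures = failures)
}
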