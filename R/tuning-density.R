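# Tuning densities g for the Gelfand-Dey estimator, fitted on the transformed
# (unconstrained) parameter scale. Multivariate normal/t densities are coded
# directly (chol-based); the truncated variant restricts the normal to the
# Mahalanobis ellipsoid of a given confidence coefficient and renormalizes.

#' Fit a Gelfand-Dey tuning density to posterior draws
#'
#' Location is the sample mean and the scale matrix derives from the sample
#' covariance of the transformed draws: used directly for the normal and
#' truncated-normal kinds, and shrunk by (df-2)/df for the t kind so that the
#' fitted t has the same variance as the draws.
#'
#' @param draws a [PosteriorDraws-class] or a numeric matrix of transformed
#'   draws (rows = draws).
#' @param kind `"mvnormal"`, `"mvt"` or `"truncnormal"`.
#' @param df degrees of freedom for `"mvt"` (10, 100, 500, 1000, 10000 in the
#'   standard family).
#' @param conf confidence coefficient for `"truncnormal"` (0.90, 0.95, 0.99).
#' @return a [TuningDensity-class].
#' @export
fitTuningDensity <- function(draws, kind = "mvnormal", df = NA_real_,
                             conf = NA_real_) {
  x <- if (is(draws, "PosteriorDraws")) draws@transformedDraws else as.matrix(draws)
  p <- ncol(x)
  if (nrow(x) < p + 2L)
    stop("need at least p + 2 draws to fit a ", p, "-dimensional tuning density")
  loc <- colMeans(x)
  V <- cov(x)
  if (!all(is.finite(V)) || rcond(V) < 1e-12) {
    warning("near-singular draw covariance; adding ridge 1e-8")
    V <- V + diag(1e-8, p)
  }
  if (kind == "mvt") V <- V * (df - 2) / df
  new("TuningDensity", kind = kind, df = as.numeric(df),
      conf = as.numeric(conf), location = loc, scaleMat = V)
}

#' @rdname logDensity
setMethod("logDensity", "TuningDensity", function(object, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  p <- length(object@location)
  U <- chol(object@scaleMat)
  logDet <- 2 * sum(log(diag(U)))
  centered <- sweep(x, 2L, object@location, "-")
  w <- backsolve(U, t(centered), transpose = TRUE)
  m2 <- colSums(w^2)
  if (object@kind == "mvt") {
    nu <- object@df
    lgamma((nu + p) / 2) - lgamma(nu / 2) -
      0.5 * (p * log(nu * pi) + logDet) -
      (nu + p) / 2 * log1p(m2 / nu)
  } else {
    ld <- -0.5 * (p * log(2 * pi) + logDet + m2)
    if (object@kind == "truncnormal") {
      ld <- ld - log(object@conf)
      ld[m2 > qchisq(object@conf, df = p)] <- -Inf
    }
    ld
  }
})

#' The standard tuning-density family
#'
#' The nine variants evaluated throughout: multivariate normal, multivariate t
#' with df in (10, 100, 500, 1000, 10000), and truncated normal with
#' confidence coefficients (0.90, 0.95, 0.99).
#'
#' @return data frame with columns `kind`, `df`, `conf`, `label`.
#' @export
tuningFamily <- function() {
  data.frame(
    kind = c("mvnormal", rep("mvt", 5L), rep("truncnormal", 3L)),
    df = c(NA, 10, 100, 500, 1000, 10000, NA, NA, NA),
    conf = c(NA, NA, NA, NA, NA, NA, 0.90, 0.95, 0.99),
    label = c("mvnormal", paste0("mvt", c(10, 100, 500, 1000, 10000)),
              paste0("truncnormal", c(90, 95, 99))))
}
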