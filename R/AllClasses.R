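#' @import methods
#' @importFrom stats approx coef confint density dnorm lm loess loess.control
#'   median model.matrix na.omit pnorm predict qnorm quantile rbinom rgamma
#'   rlnorm rnorm rpois runif sd setNames splinefun uniroot var vcov
#'   complete.cases rWishart acf
#' @importFrom utils head read.csv tail write.csv modifyList
NULL

#' Sex-specific BCCG growth standard
#'
#' A growth standard stores the three LMS curves of a Box-Cox Cole-Green
#' (BCCG) growth reference -- the Box-Cox power \eqn{L(t)}, the median
#' \eqn{M(t)} (kg) and the coefficient of variation \eqn{S(t)} -- evaluated
#' on a grid of ages (weeks). Smoothing and interpolation operate on
#' transformed age \eqn{x = t^{p}} with transform power \eqn{p} (0.1 by
#' default), the scale on which the curves were fitted.
#'
#' @slot sex Character scalar, \code{"M"} or \code{"F"}.
#' @slot ageGridWeeks Strictly increasing positive numeric vector of ages.
#' @slot L Numeric vector of Box-Cox powers \eqn{\nu} per grid age.
#' @slot M Positive numeric vector of medians (kg) per grid age.
#' @slot S Positive numeric vector of coefficients of variation per grid age.
#' @slot transformPower Positive numeric scalar; age enters the smoothers as
#'   \code{age^transformPower}.
#' @slot fitInfo List of fitting metadata (deviance trace, effective df,
#'   convergence flag); empty for standards constructed directly.
#'
#' @seealso [fitGrowthModel()], [extractCentiles()], [toZScores()]
#' @export
setClass("GrowthStandard",
  representation(
    sex = "character",
    ageGridWeeks = "numeric",
    L = "numeric",
    M = "numeric",
    S = "numeric",
    transformPower = "numeric",
    fitInfo = "list"
  ),
  prototype(transformPower = 0.1, fitInfo = list())
)

setValidity("GrowthStandard", function(object) {
  msg <- character()
  if (length(object@sex) != 1L || !object@sex %in% c("M", "F"))
    msg <- c(msg, "sex must be a single \"M\" or \"F\"")
  n <- length(object@ageGridWeeks)
  if (n < 2L)
    msg <- c(msg, "age grid needs at least 2 points")
  if (any(diff(object@ageGridWeeks) <= 0) || any(object@ageGridWeeks <= 0))
    msg <- c(msg, "ageGridWeeks must be strictly increasing and positive")
  if (length(object@L) != n || length(object@M) != n || length(object@S) != n)
    msg <- c(msg, "L, M, S must match the age grid in length")
  if (any(object@M <= 0)) msg <- c(msg, "M must be positive everywhere")
  if (any(object@S <= 0)) msg <- c(msg, "S must be positive everywhere")
  if (length(object@transformPower) != 1L || object@transformPower <= 0)
    msg <- c(msg, "transformPower must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a growth standard from LMS curves
#'
#' @param sex "M" or "F".
#' @param ageGridWeeks Strictly increasing ages in weeks.
#' @param L,M,S LMS curve values at the grid ages.
#' @param transformPower Age-transform power (default 0.1).
#' @param fitInfo Optional list of fitting metadata.
#' @return A [GrowthStandard-class] object.
#' @examples
#' gs <- GrowthStandard("F", c(5, 20, 52, 78), L = rep(1, 4),
#'                      M = c(0.6, 2.0, 3.2, 3.5), S = rep(0.1, 4))
#' ageGrid(gs)
#' @export
GrowthStandard <- function(sex, ageGridWeeks, L, M, S,
                           transformPower = 0.1, fitInfo = list()) {
  new("GrowthStandard", sex = as.character(sex),
      ageGridWeeks = as.numeric(ageGridWeeks),
      L = as.numeric(L), M = as.numeric(M), S = as.numeric(S),
      transformPower = as.numeric(transformPower), fitInfo = fitInfo)
}

#' @describeIn GrowthStandard-class age grid accessor
#' @param object,x A \code{GrowthStandard}.
#' @export
setGeneric("ageGrid", function(object) standardGeneric("ageGrid"))

#' @rdname GrowthStandard-class
#' @export
setMethod("ageGrid", "GrowthStandard", function(object) object@ageGridWeeks)

#' @describeIn GrowthStandard-class LMS curves as a data.frame
#' @export
setGeneric("lmsTable", function(object) standardGeneric("lmsTable"))

#' @rdname GrowthStandard-class
#' @export
setMethod("lmsTable", "GrowthStandard", function(object) {
  data.frame(age_weeks = object@ageGridWeeks,
             L = object@L, M = object@M, S = object@S)
})

setMethod("show", "GrowthStandard", function(object) {
  rng <- range(object@ageGridWeeks)
  cat("GrowthStandard (BCCG/LMS) for sex", object@sex, "\n")
  cat(sprintf("  ages %.1f-%.1f weeks on %d grid points; x = age^%g\n",
              rng[1], rng[2], length(object@ageGridWeeks),
              object@transformPower))
  cat(sprintf("  M range %.2f-%.2f kg; S range %.3f-%.3f; L range %.2f-%.2f\n",
              min(object@M), max(object@M), min(object@S), max(object@S),
              min(object@L), max(object@L)))
  if (length(object@fitInfo))
    cat(sprintf("  fitted: converged=%s, iterations=%d\n",
                isTRUE(object@fitInfo$converged),
                as.integer(object@fitInfo$iterations %||% NA_integer_)))
  invisible(NULL)
})

#' Median z-score trajectory of a neuter-group cohort
#'
#' Holds the median and interquartile bodyweight centiles of a cohort's
#' fitted BCCG trajectory model, expressed as z-scores of a reference
#' growth standard on an age grid.
#'
#' @slot sex "M" or "F".
#' @slot groupIndex Integer 1-4 (neuter-age quartile group).
#' @slot lowerAgeYears,upperAgeYears Neuter-age window bounds in years
#'   (\code{Inf} allowed for the last group).
#' @slot medianNeuterAgeWeeks Median observed neuter age of the cohort.
#' @slot ageGridWeeks Numeric age grid.
#' @slot zMedian,zQ25,zQ75 z-scores of the cohort's 50th/25th/75th centile
#'   curves under the reference standard.
#' @slot nCats,nRows Cohort sizes.
#' @export
setClass("ZTrajectory",
  representation(
    sex = "character", groupIndex = "integer",
    lowerAgeYears = "numeric", upperAgeYears = "numeric",
    medianNeuterAgeWeeks = "numeric",
    ageGridWeeks = "numeric",
    zMedian = "numeric", zQ25 = "numeric", zQ75 = "numeric",
    nCats = "integer", nRows = "integer"
  )
)

setValidity("ZTrajectory", function(object) {
  n <- length(object@ageGridWeeks)
  if (length(object@zMedian) != n || length(object@zQ25) != n ||
      length(object@zQ75) != n)
    return("z curves must match the age grid in length")
  ok <- stats::complete.cases(object@zQ25, object@zMedian, object@zQ75)
  if (any(object@zQ25[ok] > object@zMedian[ok] + 1e-8) ||
      any(object@zMedian[ok] > object@zQ75[ok] + 1e-8))
    return("centile z curves must be ordered q25 <= median <= q75")
  TRUE
})

setMethod("show", "ZTrajectory", function(object) {
  cat(sprintf("ZTrajectory: sex %s, neuter group %d (%.2f-%s y)\n",
              object@sex, object@groupIndex, object@lowerAgeYears,
              ifelse(is.infinite(object@upperAgeYears), "Inf",
                     sprintf("%.2f", object@upperAgeYears))))
  cat(sprintf("  %d cats, %d rows; median neuter age %.1f wk\n",
              object@nCats, object@nRows, object@medianNeuterAgeWeeks))
  cat(sprintf("  final z (median centile) at %.0f wk: %.3f\n",
              max(object@ageGridWeeks), object@zMedian[length(object@zMedian)]))
  invisible(NULL)
})

#' @describeIn ZTrajectory-class trajectory as a data.frame (age, z_median,
#'   z_q25, z_q75)
#' @param object A \code{ZTrajectory}.
#' @export
setGeneric("trajectoryTable", function(object) standardGeneric("trajectoryTable"))

#' @rdname ZTrajectory-class
#' @export
setMethod("trajectoryTable", "ZTrajectory", function(object) {
  data.frame(sex = object@sex, group_index = object@groupIndex,
             age_weeks = object@ageGridWeeks, z_median = object@zMedian,
             z_q25 = object@zQ25, z_q75 = object@zQ75)
})

#' Posterior of the multivariate mixed model for trial morphometrics
#'
#' Container for retained MCMC draws from the Bayesian multivariate mixed
#' model of log-standardized trial measures: per-measure fixed effects for
#' group, week and their interaction, litter-level and cat-level 11x11
#' covariance matrices, per-measure residual SDs, imputed missing values,
#' and sampler diagnostics.
#'
#' @slot measures Character vector of measure names (model order).
#' @slot weeks Integer vector of measurement weeks.
#' @slot groups Character vector of group labels (reference first).
#' @slot beta Array draws x coefficients x measures of fixed effects on the
#'   standardized scale.
#' @slot coefNames Column names of the fixed-effect design.
#' @slot sigmaLitter,sigmaCat Arrays draws x m x m of covariance draws.
#' @slot sigmaResid Matrix draws x measures of residual SDs.
#' @slot imputed Matrix draws x n_missing of imputed standardized values
#'   (0 columns when the data are complete).
#' @slot missingIndex Data frame locating each imputed value (row, measure).
#' @slot standardization Data frame of per-measure log-scale means and SDs
#'   used for standardization.
#' @slot schedule List with chains, iterations, warmup, thin.
#' @slot diagnostics Data frame of split-Rhat and effective sample size for
#'   the fixed effects.
#' @slot chainId Integer vector mapping each retained draw to its chain.
#' @export
setClass("MVMMPosterior",
  representation(
    measures = "character", weeks = "integer", groups = "character",
    beta = "array", coefNames = "character",
    sigmaLitter = "array", sigmaCat = "array",
    sigmaResid = "matrix", imputed = "matrix",
    missingIndex = "data.frame",
    standardization = "data.frame",
    schedule = "list", diagnostics = "data.frame",
    chainId = "integer"
  )
)

setValidity("MVMMPosterior", function(object) {
  nd <- dim(object@beta)[1]
  sch <- object@schedule
  expected <- with(sch, chains * (iterations - warmup) %/% thin)
  if (nd != expected)
    return(sprintf("retained draws (%d) do not match schedule (%d)",
                   nd, expected))
  if (dim(object@sigmaLitter)[1] != nd || dim(object@sigmaCat)[1] != nd)
    return("covariance draw count does not match beta draw count")
  TRUE
})

#' @describeIn MVMMPosterior-class number of retained posterior draws
#' @param object An \code{MVMMPosterior}.
#' @export
setGeneric("nDraws", function(object) standardGeneric("nDraws"))

#' @rdname MVMMPosterior-class
#' @export
setMethod("nDraws", "MVMMPosterior", function(object) dim(object@beta)[1])

setMethod("show", "MVMMPosterior", function(object) {
  sch <- object@schedule
  cat("MVMMPosterior: Bayesian multivariate mixed model\n")
  cat(sprintf("  %d measures x %d weeks x %d groups\n",
              length(object@measures), length(object@weeks),
              length(object@groups)))
  cat(sprintf("  %d retained draws (%d chains x (%d - %d)/%d)\n",
              nDraws(object), sch$chains, sch$iterations, sch$warmup,
              sch$thin))
  if (nrow(object@diagnostics)) {
    cat(sprintf("  max split-Rhat %.3f, min bulk ESS %.0f\n",
                max(object@diagnostics$rhat, na.rm = TRUE),
                min(object@diagnostics$ess, na.rm = TRUE)))
  }
  if (ncol(object@imputed))
    cat(sprintf("  %d missing values imputed during fitting\n",
                ncol(object@imputed)))
  invisible(NULL)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
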