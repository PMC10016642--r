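# Box-Cox Cole-Green (BCCG / LMS) distribution: z-scores, centiles, density.
#
# Parametrization follows the LMS convention: mu > 0 is the median, sigma > 0
# the coefficient of variation, nu the Box-Cox power. For nu != 0,
#   z = ((y/mu)^nu - 1) / (nu * sigma),
# and for nu = 0, z = log(y/mu) / sigma. The density on y > 0 carries the
# positive-support truncation normalizer Phi(1/(sigma*|nu|)).

checkBCCGParams <- function(mu, sigma) {
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("BCCG parameter mu must be finite and positive", call. = FALSE)
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("BCCG parameter sigma must be finite and positive", call. = FALSE)
}

#' BCCG z-score of a bodyweight
#'
#' Converts a positive measurement to its z-score under a BCCG (LMS)
#' distribution with median \code{mu}, coefficient of variation \code{sigma}
#' and Box-Cox power \code{nu}. The map is continuous in \code{nu} at 0,
#' where it reduces to the lognormal case \eqn{z = \log(y/\mu)/\sigma}.
#'
#' @param y Positive numeric vector of measurements (kg).
#' @param mu,sigma,nu BCCG parameters, recycled against \code{y}.
#' @return Numeric vector of z-scores.
#' @examples
#' bccgZScore(4.4, mu = 4, sigma = 0.1, nu = 1)  # (1.1 - 1)/0.1 = 1
#' @export
bccgZScore <- function(y, mu, sigma, nu) {
  if (any(!is.finite(y)) || any(y <= 0))
    stop("bccgZScore: y must be finite and positive", call. = FALSE)
  checkBCCGParams(mu, sigma)
  n <- max(length(y), length(mu), length(sigma), length(nu))
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  u <- log(y / mu)
  z <- u / sigma
  nz <- nu != 0
  # expm1 keeps the nu != 0 branch accurate down to tiny |nu|
  z[nz] <- expm1(nu[nz] * u[nz]) / (nu[nz] * sigma[nz])
  z
}

#' BCCG centile (quantile) of a probability
#'
#' Inverse of [bccgZScore()]: the measurement at cumulative probability
#' \code{p} under the BCCG distribution, \eqn{y = \mu(1+\nu\sigma z_p)^{1/\nu}}
#' (\eqn{y = \mu e^{\sigma z_p}} at \eqn{\nu = 0}) with
#' \eqn{z_p = \Phi^{-1}(p)}.
#'
#' @param p Probabilities in (0, 1).
#' @param mu,sigma,nu BCCG parameters, recycled against \code{p}.
#' @return Numeric vector of measurements.
#' @examples
#' bccgCentile(0.5, mu = 4, sigma = 0.1, nu = 0.5)  # the median: 4
#' @export
bccgCentile <- function(p, mu, sigma, nu) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("bccgCentile: p must lie strictly inside (0, 1)", call. = FALSE)
  checkBCCGParams(mu, sigma)
  n <- max(length(p), length(mu), length(sigma), length(nu))
  p <- rep_len(p, n); mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  zp <- qnorm(p)
  arg <- 1 + nu * sigma * zp
  nz <- nu != 0
  if (any(arg[nz] <= 0)) {
    bad <- which(nz & arg <= 0)[1]
    stop(sprintf(paste0("bccgCentile: requested centile lies beyond the ",
                        "positive-support truncation bound z = %.4f ",
                        "(1 + nu*sigma*z must stay positive)"),
                 -1 / (nu[bad] * sigma[bad])), call. = FALSE)
  }
  y <- mu * exp(sigma * zp)
  # log1p keeps the nu != 0 branch accurate down to tiny |nu|
  y[nz] <- mu[nz] * exp(log1p(nu[nz] * sigma[nz] * zp[nz]) / nu[nz])
  y
}

#' BCCG log-density
#'
#' Log density of the BCCG distribution on \eqn{y > 0}, including the
#' positive-support truncation normalizer \eqn{\Phi(1/(\sigma|\nu|))} of the
#' Cole-Green construction. At \eqn{\nu = 0} this is exactly the
#' lognormal(\eqn{\log\mu}, \eqn{\sigma}) log-density.
#'
#' @param y Positive numeric vector.
#' @param mu,sigma,nu BCCG parameters, recycled against \code{y}.
#' @return Numeric vector of log-density values.
#' @export
bccgLogPdf <- function(y, mu, sigma, nu) {
  if (any(!is.finite(y)) || any(y <= 0))
    stop("bccgLogPdf: y must be finite and positive", call. = FALSE)
  checkBCCGParams(mu, sigma)
  n <- max(length(y), length(mu), length(sigma), length(nu))
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  z <- bccgZScore(y, mu, sigma, nu)
  lp <- (nu - 1) * log(y) - nu * log(mu) - log(sigma) -
    0.5 * log(2 * pi) - z^2 / 2
  nz <- nu != 0
  lp[nz] <- lp[nz] - pnorm(1 / (sigma[nz] * abs(nu[nz])), log.p = TRUE)
  lp
}

#' Interpolate LMS parameters of a growth standard at arbitrary ages
#'
#' L, M and S are interpolated on the transformed-age scale
#' \eqn{x = t^{p}} using monotonicity-preserving (Fritsch-Carlson) cubic
#' Hermite splines, so interpolated M inherits the fitted curve's shape and
#' centiles remain non-crossing between grid nodes.
#'
#' @param standard A [GrowthStandard-class].
#' @param ageWeeks Numeric vector of ages (weeks).
#' @param extrapolate If \code{FALSE} (default) ages outside the grid yield
#'   \code{NA} parameters; if \code{TRUE}, spline extrapolation is allowed.
#' @return data.frame with columns \code{age_weeks}, \code{L}, \code{M},
#'   \code{S} (rows with \code{NA} for out-of-range ages unless
#'   \code{extrapolate}).
#' @export
lmsAt <- function(standard, ageWeeks, extrapolate = FALSE) {
  stopifnot(is(standard, "GrowthStandard"))
  x <- ageWeeks^standard@transformPower
  xg <- standard@ageGridWeeks^standard@transformPower
  fL <- splinefun(xg, standard@L, method = "monoH.FC")
  fM <- splinefun(xg, standard@M, method = "monoH.FC")
  fS <- splinefun(xg, standard@S, method = "monoH.FC")
  out <- data.frame(age_weeks = ageWeeks,
                    L = fL(x), M = fM(x), S = fS(x))
  if (!extrapolate) {
    outside <- ageWeeks < min(standard@ageGridWeeks) |
      ageWeeks > max(standard@ageGridWeeks)
    out$L[outside] <- NA_real_
    out$M[outside] <- NA_real_
    out$S[outside] <- NA_real_
  }
  out
}

#' Extract centile curves from a growth standard
#'
#' @param standard A [GrowthStandard-class].
#' @param ageWeeks Ages at which to evaluate (default: the standard's grid).
#' @param probs Centile probabilities in (0, 1).
#' @param extrapolate Allow evaluation outside the grid (default
#'   \code{FALSE}, which raises an error for out-of-range ages).
#' @return data.frame with columns \code{age_weeks}, \code{p},
#'   \code{weight_kg}; weights are strictly increasing in \code{p} at every
#'   age.
#' @examples
#' gs <- GrowthStandard("M", c(5, 20, 52, 78), L = rep(0.5, 4),
#'                      M = c(0.7, 2.3, 3.9, 4.3), S = rep(0.1, 4))
#' extractCentiles(gs, probs = c(0.25, 0.5, 0.75))
#' @export
extractCentiles <- function(standard, ageWeeks = ageGrid(standard),
                            probs = c(0.25, 0.5, 0.75),
                            extrapolate = FALSE) {
  stopifnot(is(standard, "GrowthStandard"))
  if (any(probs <= 0) || any(probs >= 1))
    stop("extractCentiles: probs must lie strictly inside (0, 1)",
         call. = FALSE)
  if (!extrapolate) {
    rng <- range(standard@ageGridWeeks)
    if (any(ageWeeks < rng[1] | ageWeeks > rng[2]))
      stop(sprintf(paste0("extractCentiles: ages outside the standard's ",
                          "grid [%.2f, %.2f] weeks; set extrapolate = TRUE ",
                          "to allow"), rng[1], rng[2]), call. = FALSE)
  }
  lms <- lmsAt(standard, ageWeeks, extrapolate = TRUE)
  out <- do.call(rbind, lapply(sort(probs), function(p) {
    data.frame(age_weeks = ageWeeks, p = p,
               weight_kg = bccgCentile(p, lms$M, lms$S, lms$L))
  }))
  rownames(out) <- NULL
  out
}

#' Convert visit bodyweights to z-scores under a growth standard
#'
#' @param standard A [GrowthStandard-class].
#' @param visits data.frame with columns \code{age_weeks} and
#'   \code{bodyweight_kg} (a visits table as returned by [readVisits()] or
#'   [simulateClinic()]).
#' @return The visits data.frame with an added numeric column \code{z};
#'   rows whose age falls outside the standard's grid get \code{NA} z and
#'   are kept, not dropped.
#' @export
toZScores <- function(standard, visits) {
  stopifnot(is(standard, "GrowthStandard"),
            all(c("age_weeks", "bodyweight_kg") %in% names(visits)))
  lms <- lmsAt(standard, visits$age_weeks, extrapolate = FALSE)
  z <- rep(NA_real_, nrow(visits))
  ok <- !is.na(lms$M)
  if (any(ok))
    z[ok] <- bccgZScore(visits$bodyweight_kg[ok], lms$M[ok], lms$S[ok],
                        lms$L[ok])
  visits$z <- z
  visits
}
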