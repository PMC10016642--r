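# Study 2: Bayesian multivariate mixed model for 11 log-standardized
# measures with litter- and cat-level correlated random effects, latent
# missing-value imputation, fold-change-ratio contrasts and simultaneous
# (sup-t) credible intervals.

#' Log-standardize trial measures
#'
#' Each measure is natural-log transformed and z-standardized using the
#' observed-data mean and SD of its log values; the constants are retained
#' for exact back-transformation. The panel is completed to the full
#' cats x weeks x measures grid, with absent or NA cells flagged missing.
#'
#' @param observations Trial observation data.frame (long format).
#' @return List of class \code{"standardizedPanel"}: \code{data} (long,
#'   with \code{y_std} and \code{missing}), \code{constants} (per-measure
#'   \code{mean_log}, \code{sd_log}), \code{cats} (cat/litter/group
#'   lookup), \code{weeks}, \code{measures}.
#' @export
standardizeMeasures <- function(observations) {
  obs <- observations
  bad <- which(!is.na(obs$value) & obs$value <= 0)
  if (length(bad))
    stop(sprintf("standardizeMeasures: non-positive value at row %d (%s, cat %s, week %d)",
                 bad[1], obs$measure[bad[1]], obs$cat_id[bad[1]],
                 obs$week[bad[1]]), call. = FALSE)
  measures <- intersect(trialMeasures, unique(obs$measure))
  weeks <- sort(unique(obs$week))
  cats <- unique(obs[, c("litter_id", "cat_id", "group")])
  cats <- cats[order(cats$litter_id, cats$group), ]

  grid <- expand.grid(cat_id = cats$cat_id, week = weeks,
                      measure = measures, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- merge(grid, cats, by = "cat_id", sort = FALSE)
  key <- function(d) paste(d$cat_id, d$week, d$measure)
  grid$value <- obs$value[match(key(grid), key(obs))]
  grid$missing <- is.na(grid$value)

  constants <- do.call(rbind, lapply(measures, function(m) {
    v <- grid$value[grid$measure == m & !grid$missing]
    s <- sd(log(v))
    if (!is.finite(s) || s == 0)
      stop(sprintf("standardizeMeasures: measure %s is constant on the log scale; jitter or exclude it",
                   m), call. = FALSE)
    data.frame(measure = m, mean_log = mean(log(v)), sd_log = s,
               stringsAsFactors = FALSE)
  }))
  mi <- match(grid$measure, constants$measure)
  grid$y_std <- (log(grid$value) - constants$mean_log[mi]) /
    constants$sd_log[mi]
  structure(list(data = grid, constants = constants, cats = cats,
                 weeks = weeks, measures = measures),
            class = c("standardizedPanel", "list"))
}

#' Back-transform standardized values to the raw scale
#' @param panel A \code{standardizedPanel}.
#' @param measure Measure name (scalar).
#' @param yStd Standardized values.
#' @return Raw-scale values.
#' @export
unstandardize <- function(panel, measure, yStd) {
  k <- match(measure, panel$constants$measure)
  exp(panel$constants$mean_log[k] + panel$constants$sd_log[k] * yStd)
}

mvmmDesign <- function(group, week, weeks) {
  g <- factor(group, levels = c("intact", "neutered"))
  w <- factor(week, levels = weeks)
  model.matrix(~ g * w)
}

splitRhat <- function(mat) {
  # mat: iterations x chains (already split-ready); split each chain in half
  half <- floor(nrow(mat) / 2)
  if (half < 2) return(NA_real_)
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[seq_len(half) + half, , drop = FALSE])
  m <- ncol(sub); n <- nrow(sub)
  mu <- colMeans(sub); s2 <- apply(sub, 2, var)
  B <- n * var(mu); W <- mean(s2)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

essBulk <- function(mat) {
  # crude bulk ESS: chain-merged autocorrelation with Geyer truncation
  n <- nrow(mat); m <- ncol(mat)
  if (n < 4) return(NA_real_)
  ac <- rowMeans(apply(mat, 2, function(x) {
    a <- stats::acf(x, lag.max = min(n - 2, 100), plot = FALSE)$acf[-1]
    if (anyNA(a)) a[] <- 0
    a
  }))
  s <- 0
  for (t in seq(1, length(ac) - 1, by = 2)) {
    pair <- ac[t] + ac[t + 1]
    if (is.na(pair) || pair < 0) break
    s <- s + pair
  }
  max(m * n / (1 + 2 * s), 1)
}

#' Fit the Bayesian multivariate mixed model by Gibbs sampling
#'
#' Model per cat \eqn{c} (in litter \eqn{l}), week \eqn{w}, measure
#' \eqn{m}, on the standardized scale:
#' \deqn{y = x_{g,w}'\beta_m + u_{l,m} + v_{c,m} + \epsilon_{m},}
#' with group, week and their interaction as fixed effects
#' (\eqn{\beta \sim N(0, 4^2)} per the analysis convention), litter- and
#' cat-level random effects correlated across the 11 measures
#' (inverse-Wishart priors on both covariance matrices), independent
#' residuals per measure (inverse-gamma prior on each variance), and
#' missing responses treated as latent parameters sampled jointly. The
#' conjugate structure admits an exact blocked Gibbs sampler, which is run
#' for \code{chains} chains of \code{iterations} sweeps; post-warm-up
#' draws are thinned to 1 in \code{thin}.
#'
#' @param panel A \code{standardizedPanel} from [standardizeMeasures()].
#' @param priors List: \code{beta_sd}, \code{residual_shape},
#'   \code{residual_rate}, \code{wishart_extra_df}, \code{wishart_scale}
#'   (see [analysisConfig()]).
#' @param schedule List with \code{chains}, \code{iterations},
#'   \code{warmup}, \code{thin}; the default analysis schedule retains
#'   exactly chains x (iterations - warmup) / thin draws.
#' @param seed Integer seed (per-chain streams are derived from it).
#' @param failOnDiagnostics If TRUE (default), split-Rhat above
#'   \code{rhatLimit} on any fixed effect raises an error naming the
#'   offending parameters.
#' @param rhatLimit Split-Rhat threshold (default 1.05).
#' @return An [MVMMPosterior-class].
#' @export
fitMVMM <- function(panel, priors = analysisConfig()$priors,
                    schedule = analysisConfig()$mcmc, seed = 1,
                    failOnDiagnostics = TRUE, rhatLimit = 1.05) {
  stopifnot(inherits(panel, "standardizedPanel"))
  stopifnot(schedule$warmup < schedule$iterations, schedule$thin >= 1)
  d <- panel$data
  measures <- panel$measures; weeks <- panel$weeks
  M <- length(measures); W <- length(weeks)
  cats <- panel$cats
  C <- nrow(cats); L <- length(unique(cats$litter_id))
  litterOf <- match(cats$litter_id, unique(cats$litter_id))

  # response array: (cat x week) rows, measure columns
  rowKey <- paste(rep(cats$cat_id, times = W),
                  rep(weeks, each = C))
  Y <- matrix(NA_real_, C * W, M)
  dk <- paste(d$cat_id, d$week)
  for (j in seq_len(M)) {
    sub <- d[d$measure == measures[j], ]
    Y[match(paste(sub$cat_id, sub$week), rowKey), j] <- sub$y_std
  }
  missMask <- is.na(Y)
  missingIndex <- which(missMask, arr.ind = TRUE)
  X <- mvmmDesign(rep(cats$group, times = W), rep(weeks, each = C), weeks)
  p <- ncol(X)
  XtX <- crossprod(X)
  catRow <- rep(seq_len(C), times = W)      # cat of each row
  litRow <- litterOf[catRow]

  betaPrec <- 1 / priors$beta_sd^2
  df0 <- M + priors$wishart_extra_df
  S0 <- diag(priors$wishart_scale, M)
  a0 <- priors$residual_shape; b0 <- priors$residual_rate

  keepPerChain <- (schedule$iterations - schedule$warmup) %/% schedule$thin
  nKeep <- schedule$chains * keepPerChain
  betaDraws <- array(NA_real_, c(nKeep, p, M),
                     dimnames = list(NULL, colnames(X), measures))
  sigLDraws <- array(NA_real_, c(nKeep, M, M))
  sigCDraws <- array(NA_real_, c(nKeep, M, M))
  sigEDraws <- matrix(NA_real_, nKeep, M)
  impDraws <- matrix(NA_real_, nKeep, nrow(missingIndex))
  chainId <- integer(nKeep)

  # joint-block design [X | litter indicators | cat indicators]: per
  # measure, (beta_m, u_m, v_m) are drawn in one conjugate block, which
  # decouples the intercept from the random-effect means and mixes far
  # better than one-at-a-time scans
  ZL <- matrix(0, nrow(X), L); ZL[cbind(seq_len(nrow(X)), litRow)] <- 1
  ZC <- matrix(0, nrow(X), C); ZC[cbind(seq_len(nrow(X)), catRow)] <- 1
  Z <- cbind(X, ZL, ZC)
  ZtZ <- crossprod(Z)
  iB <- seq_len(p); iU <- p + seq_len(L); iV <- p + L + seq_len(C)

  slot <- 0L
  for (ch in seq_len(schedule$chains)) {
    set.seed(as.integer(seed) + 1000L * (ch - 1L))
    # dispersed but overdispersion-free inits
    beta <- matrix(rnorm(p * M, 0, 0.5), p, M)
    u <- matrix(rnorm(L * M, 0, 0.1), L, M)
    v <- matrix(rnorm(C * M, 0, 0.1), C, M)
    sig2 <- rep(0.5, M)
    SigL <- diag(0.05, M); SigC <- diag(0.05, M)
    invSigL <- solve(SigL); invSigC <- solve(SigC)
    Ycur <- Y
    Ycur[missMask] <- 0

    for (it in seq_len(schedule$iterations)) {
      # impute missing responses
      if (nrow(missingIndex)) {
        mu_miss <- (X %*% beta)[missingIndex] +
          u[cbind(litRow[missingIndex[, 1]], missingIndex[, 2])] +
          v[cbind(catRow[missingIndex[, 1]], missingIndex[, 2])]
        Ycur[missingIndex] <- mu_miss +
          rnorm(nrow(missingIndex), 0, sqrt(sig2[missingIndex[, 2]]))
      }
      # per-measure joint block (beta_m, u_m, v_m); other measures enter
      # through the conditional prior means implied by the precision rows
      for (j in seq_len(M)) {
        pU <- invSigL[j, j]; pV <- invSigC[j, j]
        mu0U <- -(u[, -j, drop = FALSE] %*% invSigL[-j, j]) / pU
        mu0V <- -(v[, -j, drop = FALSE] %*% invSigC[-j, j]) / pV
        A <- ZtZ / sig2[j]
        dg <- c(rep(betaPrec, p), rep(pU, L), rep(pV, C))
        diag(A) <- diag(A) + dg
        b <- crossprod(Z, Ycur[, j]) / sig2[j] +
          c(numeric(p), pU * mu0U, pV * mu0V)
        cA <- chol(A)
        theta <- backsolve(cA, forwardsolve(t(cA), b) + rnorm(p + L + C))
        beta[, j] <- theta[iB]; u[, j] <- theta[iU]; v[, j] <- theta[iV]
      }
      # covariance matrices (keep the Wishart draw as the precision)
      WL <- rWishart(1, df0 + L, solve(S0 + crossprod(u)))[, , 1]
      invSigL <- WL; SigL <- solve(WL)
      WC <- rWishart(1, df0 + C, solve(S0 + crossprod(v)))[, , 1]
      invSigC <- WC; SigC <- solve(WC)
      # residual variances
      E <- Ycur - X %*% beta - u[litRow, , drop = FALSE] -
        v[catRow, , drop = FALSE]
      SS <- colSums(E^2)
      sig2 <- 1 / rgamma(M, a0 + nrow(E) / 2, b0 + SS / 2)

      if (it > schedule$warmup &&
          (it - schedule$warmup) %% schedule$thin == 0L) {
        slot <- slot + 1L
        betaDraws[slot, , ] <- beta
        sigLDraws[slot, , ] <- SigL
        sigCDraws[slot, , ] <- SigC
        sigEDraws[slot, ] <- sqrt(sig2)
        if (nrow(missingIndex))
          impDraws[slot, ] <- Ycur[missingIndex]
        chainId[slot] <- ch
      }
    }
  }

  # split-Rhat / ESS on the fixed effects
  diag_ <- do.call(rbind, lapply(seq_len(p), function(i)
    do.call(rbind, lapply(seq_len(M), function(j) {
      mat <- matrix(betaDraws[, i, j], ncol = schedule$chains)
      data.frame(parameter = sprintf("beta[%s,%s]", colnames(X)[i],
                                     measures[j]),
                 rhat = splitRhat(mat), ess = essBulk(mat),
                 stringsAsFactors = FALSE)
    }))))
  if (failOnDiagnostics) {
    bad <- diag_$parameter[!is.na(diag_$rhat) & diag_$rhat > rhatLimit]
    if (length(bad))
      stop(sprintf("fitMVMM: split-Rhat > %.2f for: %s", rhatLimit,
                   paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  }

  mIdx <- data.frame(row = missingIndex[, 1], measure_index = missingIndex[, 2])
  if (nrow(mIdx)) {
    mIdx$cat_id <- cats$cat_id[catRow[mIdx$row]]
    mIdx$week <- rep(weeks, each = C)[mIdx$row]
    mIdx$measure <- measures[mIdx$measure_index]
  } else {
    mIdx <- data.frame(row = integer(), measure_index = integer(),
                       cat_id = character(), week = integer(),
                       measure = character())
  }
  new("MVMMPosterior",
      measures = measures, weeks = as.integer(weeks),
      groups = c("intact", "neutered"),
      beta = betaDraws, coefNames = colnames(X),
      sigmaLitter = sigLDraws, sigmaCat = sigCDraws,
      sigmaResid = sigEDraws,
      imputed = if (nrow(mIdx)) impDraws else matrix(0, nKeep, 0),
      missingIndex = mIdx,
      standardization = panel$constants,
      schedule = schedule, diagnostics = diag_,
      chainId = chainId)
}

cellMeanDraws <- function(posterior, group, week) {
  x <- mvmmDesign(rep(group, length(posterior@weeks)), posterior@weeks,
                  posterior@weeks)
  x <- x[match(week, posterior@weeks), , drop = FALSE]
  # draws x measures for one (group, week) cell, standardized scale
  apply(posterior@beta, 3, function(b) as.numeric(b %*% t(x)))
}

#' Simultaneous credible intervals by the sup-t construction
#'
#' Given posterior draws of a family of quantities, finds the smallest
#' expansion factor k such that the per-quantity intervals
#' mean +/- k * SD jointly contain at least \code{level} of the draws, and
#' returns those intervals. Zero-SD (degenerate) quantities get point
#' intervals and are excluded from the k search. Simultaneous intervals
#' are never narrower than the corresponding pointwise intervals.
#'
#' @param draws Numeric matrix, draws x quantities (>= 100 draws).
#' @param level Joint credible level (default 0.95).
#' @return data.frame with \code{mean}, \code{sd}, \code{lower},
#'   \code{upper} per quantity; the factor k is the \code{"k"} attribute.
#' @export
simultaneousCredibleIntervals <- function(draws, level = 0.95) {
  draws <- as.matrix(draws)
  if (nrow(draws) < 100)
    stop("simultaneousCredibleIntervals: need >= 100 draws", call. = FALSE)
  if (ncol(draws) < 1)
    stop("simultaneousCredibleIntervals: empty family", call. = FALSE)
  mu <- colMeans(draws); s <- apply(draws, 2, sd)
  live <- s > 0
  if (any(live)) {
    zMat <- abs(sweep(sweep(draws[, live, drop = FALSE], 2, mu[live]),
                      2, s[live], "/"))
    maxStat <- do.call(pmax, as.data.frame(zMat))
    sorted <- sort(maxStat)
    k <- sorted[ceiling(level * length(sorted))]
  } else k <- 0
  out <- data.frame(mean = mu, sd = s, lower = mu - k * s,
                    upper = mu + k * s)
  cn <- colnames(draws)
  if (!is.null(cn) && !anyDuplicated(cn) && all(nzchar(cn)))
    rownames(out) <- cn
  attr(out, "k") <- k
  out
}

#' Fold changes and between-group fold-change ratios
#'
#' Per posterior draw and measure, the fold change of each group from the
#' baseline week to week w is the ratio of geometric means,
#' \eqn{\exp(s_m (\eta_{g,w} - \eta_{g,base}))} with \eqn{\eta} the
#' standardized-scale cell mean and \eqn{s_m} the stored log-scale SD; the
#' fold-change ratio is neutered fold over intact fold. Summaries carry
#' the posterior mean, pointwise central 95\% intervals, and simultaneous
#' (sup-t) intervals over the family of all measure-by-week ratios
#' (respectively all group fold changes).
#'
#' @param posterior An [MVMMPosterior-class].
#' @param baselineWeek Baseline week label (default: the first week).
#' @param level Credible level (default 0.95).
#' @return List with \code{folds} (per measure x week x group) and
#'   \code{ratios} (per measure x week), both data.frames with pointwise
#'   and simultaneous bounds; draw matrices in the \code{"draws"}
#'   attribute.
#' @export
foldChangeSummaries <- function(posterior, baselineWeek = NULL,
                                level = 0.95) {
  weeks <- posterior@weeks
  if (is.null(baselineWeek)) baselineWeek <- weeks[1]
  if (!baselineWeek %in% weeks)
    stop("foldChangeSummaries: baseline week not in the design", call. = FALSE)
  measures <- posterior@measures
  sLog <- posterior@standardization$sd_log[
    match(measures, posterior@standardization$measure)]
  later <- weeks  # include baseline (ratio identically 1)

  base <- list(intact = cellMeanDraws(posterior, "intact", baselineWeek),
               neutered = cellMeanDraws(posterior, "neutered", baselineWeek))
  foldDraws <- list(); ratioDraws <- list()
  for (w in later) {
    cellI <- cellMeanDraws(posterior, "intact", w)
    cellN <- cellMeanDraws(posterior, "neutered", w)
    dI <- sweep(cellI - base$intact, 2, sLog, "*")
    dN <- sweep(cellN - base$neutered, 2, sLog, "*")
    colnames(dI) <- colnames(dN) <- measures
    foldDraws[[paste("intact", w)]] <- exp(dI)
    foldDraws[[paste("neutered", w)]] <- exp(dN)
    ratioDraws[[as.character(w)]] <- exp(dN - dI)
  }

  flatten <- function(lst) {
    mats <- lapply(names(lst), function(nm) {
      m <- lst[[nm]]
      colnames(m) <- paste(nm, colnames(m))
      m
    })
    do.call(cbind, mats)
  }
  ratioMat <- flatten(ratioDraws)
  foldMat <- flatten(foldDraws)

  summarize <- function(mat, sim) {
    mu <- colMeans(mat)
    lo <- apply(mat, 2, quantile, (1 - level) / 2)
    hi <- apply(mat, 2, quantile, 1 - (1 - level) / 2)
    data.frame(key = colnames(mat), mean = mu, lower = lo, upper = hi,
               sim_lower = sim$lower, sim_upper = sim$upper,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  # sup-t over non-degenerate quantities (the baseline columns are constant)
  simR <- simultaneousCredibleIntervals(ratioMat, level)
  simF <- simultaneousCredibleIntervals(foldMat, level)

  ratios <- summarize(ratioMat, simR)
  parts <- do.call(rbind, strsplit(ratios$key, " "))
  ratios <- data.frame(measure = parts[, 2], week = as.integer(parts[, 1]),
                       ratios[, -1], stringsAsFactors = FALSE)
  folds <- summarize(foldMat, simF)
  parts <- do.call(rbind, strsplit(folds$key, " "))
  folds <- data.frame(group = parts[, 1], week = as.integer(parts[, 2]),
                      measure = parts[, 3], folds[, -1],
                      stringsAsFactors = FALSE)
  structure(list(folds = folds, ratios = ratios,
                 baseline_week = baselineWeek),
            draws = list(ratio = ratioMat, fold = foldMat))
}

#' Posterior predictive density-overlay data
#'
#' For each measure and week, simulates \code{nDraws} replicate trials
#' from evenly spaced retained posterior draws (new litter and cat
#' effects from the covariance draws, new residuals) and returns kernel
#' density traces of the simulated raw-scale values together with the
#' observed trace (draw 0).
#'
#' @param posterior An [MVMMPosterior-class].
#' @param panel The \code{standardizedPanel} the model was fitted to.
#' @param nDraws Number of posterior draws to overlay (default 40; 0 gives
#'   observed traces only).
#' @return data.frame with columns \code{measure}, \code{week},
#'   \code{draw} (0 = observed), \code{x}, \code{density}.
#' @export
posteriorPredictiveCheck <- function(posterior, panel, nDraws = 40) {
  cats <- panel$cats
  weeks <- posterior@weeks; measures <- posterior@measures
  C <- nrow(cats); L <- length(unique(cats$litter_id)); M <- length(measures)
  litterOf <- match(cats$litter_id, unique(cats$litter_id))
  X <- mvmmDesign(rep(cats$group, times = length(weeks)),
                  rep(weeks, each = C), weeks)
  catRow <- rep(seq_len(C), times = length(weeks))
  weekRow <- rep(weeks, each = C)
  nTotal <- dim(posterior@beta)[1]
  sel <- if (nDraws > 0)
    unique(round(seq(1, nTotal, length.out = nDraws))) else integer()

  out <- list()
  for (s in seq_along(sel)) {
    i <- sel[s]
    beta <- posterior@beta[i, , ]
    u <- rmvn1(L, posterior@sigmaLitter[i, , ])
    v <- rmvn1(C, posterior@sigmaCat[i, , ])
    eps <- matrix(rnorm(nrow(X) * M), nrow(X), M) %*%
      diag(posterior@sigmaResid[i, ], M)
    ySim <- X %*% beta + u[litterOf[catRow], ] + v[catRow, ] + eps
    for (j in seq_len(M)) for (w in weeks) {
      vals <- unstandardize(panel, measures[j], ySim[weekRow == w, j])
      dd <- density(vals)
      out[[length(out) + 1]] <- data.frame(
        measure = measures[j], week = w, draw = s,
        x = dd$x, density = dd$y, stringsAsFactors = FALSE)
    }
  }
  d <- panel$data
  for (j in seq_along(measures)) for (w in weeks) {
    vals <- d$value[d$measure == measures[j] & d$week == w & !d$missing]
    if (length(vals) < 2) next
    dd <- density(vals)
    out[[length(out) + 1]] <- data.frame(
      measure = measures[j], week = w, draw = 0L,
      x = dd$x, density = dd$y, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
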