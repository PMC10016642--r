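# Study 2: standardization, the multivariate mixed model sampler, fold
# changes and simultaneous intervals.

test_that("log-standardization round-trips and is scale-invariant", {
  tt <- trialSimTruth(missingRate = 0)
  obs <- simulateTrial(tt, 5, seed = 1)$observations
  panel <- standardizeMeasures(obs)
  d <- panel$data
  expect_equal(unstandardize(panel, "weight",
                             d$y_std[d$measure == "weight"]),
               d$value[d$measure == "weight"], tolerance = 1e-12)
  # standardized observed values have mean 0, SD 1 per measure
  for (m in c("weight", "girth")) {
    y <- d$y_std[d$measure == m & !d$missing]
    expect_equal(mean(y), 0, tolerance = 1e-12)
    expect_equal(sd(y), 1, tolerance = 1e-12)
  }
  # doubling the raw values shifts the log-mean by log 2, leaves y* alone
  obs2 <- obs
  obs2$value[obs2$measure == "weight"] <-
    2 * obs2$value[obs2$measure == "weight"]
  p2 <- standardizeMeasures(obs2)
  expect_equal(p2$constants$mean_log[p2$constants$measure == "weight"],
               panel$constants$mean_log[panel$constants$measure == "weight"] +
                 log(2))
  expect_equal(p2$data$y_std, panel$data$y_std, tolerance = 1e-12)

  # constant measure demands jitter or exclusion
  obsC <- obs
  obsC$value[obsC$measure == "height"] <- 20
  expect_error(standardizeMeasures(obsC), "constant")
  # non-positive value is named
  obsN <- obs; obsN$value[5] <- -1
  expect_error(standardizeMeasures(obsN), "non-positive")
})

test_that("retained-draw accounting is exact and draws are reproducible", {
  tt <- trialSimTruth()
  obs <- simulateTrial(tt, 11, seed = 2)$observations
  panel <- standardizeMeasures(obs)
  sch <- reducedSchedule(chains = 2L, iterations = 300L, warmup = 100L,
                         thin = 2L)
  post <- fitMVMM(panel, schedule = sch, seed = 5,
                  failOnDiagnostics = FALSE)
  expect_equal(nDraws(post), 2 * (300 - 100) %/% 2)
  expect_equal(dim(post@sigmaLitter), c(200, 11, 11))
  post2 <- fitMVMM(panel, schedule = sch, seed = 5,
                   failOnDiagnostics = FALSE)
  expect_identical(post@beta, post2@beta)
  expect_identical(post@imputed, post2@imputed)
  expect_error(fitMVMM(panel, schedule = reducedSchedule(iterations = 100L,
                                                         warmup = 200L)),
               "warmup")
})

test_that("a tight prior pins fixed effects near zero", {
  tt <- trialSimTruth()
  obs <- simulateTrial(tt, 6, seed = 3)$observations
  panel <- standardizeMeasures(obs)
  priors <- analysisConfig()$priors
  priors$beta_sd <- 1e-4
  post <- fitMVMM(panel, priors = priors,
                  schedule = reducedSchedule(chains = 1L, iterations = 200L,
                                             warmup = 100L),
                  seed = 1, failOnDiagnostics = FALSE)
  expect_lt(max(abs(post@beta)), 0.01)
})

test_that("MCAR missingness moves fixed effects by less than one posterior SD", {
  tt <- trialSimTruth(missingRate = 0)
  obs <- simulateTrial(tt, 11, seed = 4)$observations
  panel0 <- standardizeMeasures(obs)
  sch <- reducedSchedule(chains = 2L, iterations = 600L, warmup = 300L)
  post0 <- fitMVMM(panel0, schedule = sch, seed = 7,
                   failOnDiagnostics = FALSE)
  set.seed(99)
  obs5 <- obs
  drop <- sample(nrow(obs5), round(0.05 * nrow(obs5)))
  obs5$value[drop] <- NA
  obs5$missing[drop] <- TRUE
  panel5 <- standardizeMeasures(obs5)
  post5 <- fitMVMM(panel5, schedule = sch, seed = 7,
                   failOnDiagnostics = FALSE)
  expect_equal(ncol(post5@imputed), length(drop))
  m0 <- apply(post0@beta, c(2, 3), mean)
  m5 <- apply(post5@beta, c(2, 3), mean)
  s0 <- apply(post0@beta, c(2, 3), sd)
  expect_lt(max(abs(m5 - m0) / s0), 1)
})

test_that("fold-change ratios are 1 at baseline and intervals nest", {
  tt <- trialSimTruth()
  obs <- simulateTrial(tt, 11, seed = 6)$observations
  panel <- standardizeMeasures(obs)
  post <- fitMVMM(panel, schedule = reducedSchedule(chains = 2L,
                                                    iterations = 500L,
                                                    warmup = 250L),
                  seed = 11, failOnDiagnostics = FALSE)
  fc <- foldChangeSummaries(post, baselineWeek = 11)
  base <- fc$ratios[fc$ratios$week == 11, ]
  expect_equal(base$mean, rep(1, nrow(base)))
  expect_equal(base$upper - base$lower, rep(0, nrow(base)))
  # simultaneous intervals contain the pointwise intervals
  expect_true(all(fc$ratios$sim_lower <= fc$ratios$lower + 1e-12))
  expect_true(all(fc$ratios$sim_upper >= fc$ratios$upper - 1e-12))
  expect_error(foldChangeSummaries(post, baselineWeek = 12), "baseline")
})

test_that("sup-t intervals match their oracles", {
  set.seed(21)
  # family of one: equals the pointwise central interval closely
  x <- matrix(rnorm(20000), ncol = 1)
  s1 <- simultaneousCredibleIntervals(x)
  ptw <- quantile(x, c(0.025, 0.975))
  expect_lt(abs(s1$lower - ptw[1]) / diff(range(ptw)), 0.02)
  expect_lt(abs(s1$upper - ptw[2]) / diff(range(ptw)), 0.02)

  # independent Gaussians, family of 10: k matches the Sidak quantile
  x10 <- matrix(rnorm(50000 * 10), ncol = 10)
  s10 <- simultaneousCredibleIntervals(x10)
  kSidak <- qnorm((1 + 0.95^(1 / 10)) / 2)
  expect_lt(abs(attr(s10, "k") - kSidak), 0.05)

  # perfectly correlated family: simultaneous equals pointwise
  z <- rnorm(20000)
  xc <- cbind(z, 2 * z + 1, -z)
  sc <- simultaneousCredibleIntervals(xc)
  kPoint <- attr(simultaneousCredibleIntervals(cbind(z)), "k")
  expect_equal(attr(sc, "k"), kPoint, tolerance = 1e-10)

  # degenerate quantity: point interval, excluded from the search
  xd <- cbind(z, rep(3, length(z)))
  sd_ <- simultaneousCredibleIntervals(xd)
  expect_equal(sd_$lower[2], 3)
  expect_equal(sd_$upper[2], 3)
  expect_error(simultaneousCredibleIntervals(matrix(rnorm(50), ncol = 1)),
               ">= 100")
})

test_that("posterior predictive data cover every measure-week cell", {
  tt <- trialSimTruth()
  obs <- simulateTrial(tt, 8, seed = 12)$observations
  panel <- standardizeMeasures(obs)
  post <- fitMVMM(panel, schedule = reducedSchedule(chains = 1L,
                                                    iterations = 250L,
                                                    warmup = 150L),
                  seed = 13, failOnDiagnostics = FALSE)
  ppc <- posteriorPredictiveCheck(post, panel, nDraws = 3)
  expect_setequal(unique(ppc$draw), 0:3)
  cells <- unique(ppc[ppc$draw == 1, c("measure", "week")])
  expect_equal(nrow(cells), 11 * 4)
  ppc0 <- posteriorPredictiveCheck(post, panel, nDraws = 0)
  expect_true(all(ppc0$draw == 0))
})

test_that("observed density traces sit inside the posterior envelope", {
  tt <- trialSimTruth(missingRate = 0)
  obs <- simulateTrial(tt, 11, seed = 22)$observations
  panel <- standardizeMeasures(obs)
  post <- fitMVMM(panel, schedule = reducedSchedule(chains = 2L,
                                                    iterations = 400L,
                                                    warmup = 200L),
                  seed = 23, failOnDiagnostics = FALSE)
  ppc <- posteriorPredictiveCheck(post, panel, nDraws = 20)
  traceMean <- function(d) sum(d$x * d$density) / sum(d$density)
  cells <- unique(ppc[, c("measure", "week")])
  inside <- logical(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- ppc[ppc$measure == cells$measure[i] & ppc$week == cells$week[i], ]
    mObs <- traceMean(cell[cell$draw == 0, ])
    mSim <- vapply(split(cell[cell$draw > 0, ], cell$draw[cell$draw > 0]),
                   traceMean, numeric(1))
    inside[i] <- mObs >= min(mSim) && mObs <= max(mSim)
  }
  expect_gte(mean(inside), 0.95)
})
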