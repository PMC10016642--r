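# BCCG distribution mathematics: z-scores, centiles, density, and the
# interpolation layer of growth standards.

test_that("z-score matches its closed forms and is continuous in nu", {
  # linear case: nu = 1
  expect_equal(bccgZScore(4.4, mu = 4, sigma = 0.1, nu = 1), 1)
  # lognormal limit: nu = 0
  expect_equal(bccgZScore(4 * exp(0.2), mu = 4, sigma = 0.1, nu = 0), 2)
  # the median maps to zero for any shape
  for (nu in c(-1, -0.3, 0, 0.6, 1.5))
    expect_equal(bccgZScore(3.2, mu = 3.2, sigma = 0.15, nu = nu), 0)
  # continuity at nu = 0
  y <- c(2.1, 3.9, 5.6)
  expect_lt(max(abs(bccgZScore(y, 4, 0.1, 1e-9) -
                      bccgZScore(y, 4, 0.1, 0))), 1e-6)
  expect_error(bccgZScore(-1, 4, 0.1, 1), "positive")
})

test_that("centile inverts the z-score over a parameter grid", {
  expect_equal(bccgCentile(0.5, mu = 4, sigma = 0.1, nu = 0.7), 4)
  # independent normal-quantile oracle for the linear case
  expect_equal(bccgCentile(0.75, mu = 4, sigma = 0.1, nu = 1),
               4 * (1 + 0.1 * qnorm(0.75)))
  for (nu in c(-1, -0.5, 0, 0.5, 1))
    for (s in c(0.05, 0.1, 0.2))
      for (p in c(0.01, 0.1, 0.5, 0.9, 0.99)) {
        y <- bccgCentile(p, 4, s, nu)
        expect_lt(abs(bccgZScore(y, 4, s, nu) - qnorm(p)), 1e-8)
      }
  expect_error(bccgCentile(1.2, 4, 0.1, 1), "inside")
  # beyond the truncation bound for strongly negative power
  expect_error(bccgCentile(1 - 1e-12, 4, 0.5, -4), "truncation")
})

test_that("density normalizes to one and reduces to the lognormal", {
  for (nu in c(-1, -0.5, 0.5, 1)) {
    I <- integrate(function(y) exp(bccgLogPdf(y, 4, 0.2, nu)),
                   1e-9, Inf, rel.tol = 1e-10)$value
    expect_lt(abs(I - 1), 1e-6)
  }
  y <- c(0.5, 2, 4, 6, 12)
  expect_equal(bccgLogPdf(y, 4, 0.1, 0),
               dlnorm(y, log(4), 0.1, log = TRUE))
  # mode exists inside the support
  ys <- seq(0.5, 12, by = 0.01)
  for (nu in c(-1, 0, 1)) {
    d <- bccgLogPdf(ys, 4, 0.2, nu)
    expect_true(which.max(d) > 1 && which.max(d) < length(ys))
  }
})

test_that("centile tables are non-crossing and agree with direct evaluation", {
  gs <- GrowthStandard("M", c(5, 20, 52, 78, 110),
                       L = c(0.7, 0.6, 0.45, 0.4, 0.38),
                       M = c(0.74, 2.3, 4.0, 4.5, 4.56),
                       S = c(0.13, 0.12, 0.105, 0.10, 0.10))
  ct <- extractCentiles(gs, probs = c(0.05, 0.25, 0.5, 0.75, 0.95))
  for (a in ageGrid(gs)) {
    w <- ct$weight_kg[ct$age_weeks == a]
    expect_true(all(diff(w) > 0))
  }
  # no interpolation error at grid nodes
  direct <- bccgCentile(0.5, gs@M, gs@S, gs@L)
  expect_equal(ct$weight_kg[ct$p == 0.5], direct, tolerance = 1e-12)
  # p = 0.5 is the M curve
  expect_equal(ct$weight_kg[ct$p == 0.5], gs@M)
  expect_error(extractCentiles(gs, ageWeeks = 200), "outside")
})

test_that("z-scoring visits flags out-of-range ages and is monotone", {
  gs <- defaultGrowthStandard("F")
  v <- data.frame(age_weeks = c(20, 20, 500), bodyweight_kg = c(2.0, 2.4, 3))
  vz <- toZScores(gs, v)
  expect_true(is.na(vz$z[3]))
  expect_lt(vz$z[1], vz$z[2])
  expect_equal(nrow(vz), 3)  # rows kept, not dropped
  # a visit exactly on the median curve has z = 0
  m20 <- lmsAt(gs, 20)$M
  expect_equal(toZScores(gs, data.frame(age_weeks = 20,
                                        bodyweight_kg = m20))$z, 0,
               tolerance = 1e-10)
})

test_that("growth standard validity catches malformed curves", {
  expect_error(GrowthStandard("X", 1:5, L = rep(1, 5), M = rep(1, 5),
                              S = rep(0.1, 5)), "sex")
  expect_error(GrowthStandard("M", c(1, 2, 2, 3), L = rep(1, 4),
                              M = rep(1, 4), S = rep(0.1, 4)),
               "increasing")
  expect_error(GrowthStandard("M", 1:4, L = rep(1, 4),
                              M = c(1, 1, -1, 1), S = rep(0.1, 4)),
               "positive")
})
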