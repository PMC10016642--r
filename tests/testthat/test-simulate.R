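# Synthetic-data generators: determinism, degenerate limits, counting,
# and recovery of the generator's own ground truth.

test_that("clinic generator is deterministic and honours degenerate limits", {
  truth <- clinicSimTruth()
  a <- simulateClinic(truth, 200, seed = 9)
  b <- simulateClinic(truth, 200, seed = 9)
  expect_identical(a, b)
  expect_error(simulateClinic(truth, 0, seed = 1), ">= 1")

  # no artifacts, no noise, no offsets, no effect: weights sit exactly on
  # the true median curve
  flat <- clinicSimTruth(catZSD = 0, noiseLogSD = 0,
                         effectAmplitude = c(M = 0, F = 0),
                         artifactRates = list(pound = 0, rolled = 0,
                                              carrier = 0))
  s <- simulateClinic(flat, 100, seed = 2)
  for (sx in c("M", "F")) {
    idx <- s$visits$sex == sx
    m <- lmsAt(flat$standards[[sx]], s$visits$age_weeks[idx],
               extrapolate = TRUE)$M
    expect_equal(s$visits$bodyweight_kg[idx], m, tolerance = 1e-10)
  }
})

test_that("generator truth tables recover the injected neuter effect", {
  truth <- clinicSimTruth(effectAmplitude = c(M = 0.4, F = 1.0),
                          effectDecayPerWeek = 0)
  sim <- simulateClinic(truth, 2000, seed = 4)
  ct <- sim$catTruth
  early <- ct$neutered & ct$sex == "F" & ct$neuter_age_weeks < 25
  expect_gt(sum(early), 100)
  # full shift is exactly the configured amplitude without decay
  expect_equal(unique(ct$full_z_shift[early]), 1.0)
  # realized latent z at end of growth = offset + shift; check via the
  # per-row truth for post-growth rows of early-neutered females
  rows <- merge(sim$truth, ct[, c("cat_id", "z_offset", "neuter_age_weeks",
                                  "full_z_shift")], by = "cat_id")
  v <- sim$visits[match(rows$row_id, sim$visits$row_id), ]
  late <- !is.na(rows$neuter_age_weeks) & rows$neuter_age_weeks < 25 &
    v$age_weeks >= 78 & v$sex == "F"
  expect_gt(sum(late), 50)
  expect_equal(mean(rows$z_latent[late] - rows$z_offset[late]), 1.0,
               tolerance = 0.02)
})

test_that("marginal weights follow the true standard without an effect", {
  truth <- clinicSimTruth(effectAmplitude = c(M = 0, F = 0),
                          artifactRates = list(pound = 0, rolled = 0,
                                               carrier = 0))
  sim <- simulateClinic(truth, 3000, seed = 6)
  for (sx in c("M", "F")) {
    v <- sim$visits[sim$visits$sex == sx, ]
    lms <- lmsAt(truth$standards[[sx]], v$age_weeks, extrapolate = TRUE)
    below <- v$bodyweight_kg < lms$M
    n <- length(below)
    expect_lt(abs(mean(below) - 0.5), 3 * sqrt(0.25 / n) + 0.01)
    q25 <- bccgCentile(0.25, lms$M, lms$S, lms$L)
    expect_lt(abs(mean(v$bodyweight_kg < q25) - 0.25),
              3 * sqrt(0.25 / n) + 0.03)
  }
})

test_that("trial generator counts, degenerates and closes its fold ratio", {
  tt <- trialSimTruth(missingRate = 0)
  sim <- simulateTrial(tt, 11, seed = 8)
  expect_equal(nrow(sim$observations), 11 * 2 * 4 * 11)
  expect_identical(simulateTrial(tt, 11, seed = 8), sim)
  expect_error(simulateTrial(tt, 1, seed = 1), ">= 2")
  expect_error(trialSimTruth(weeks = c(11, 11, 30)), "increasing")
  expect_error(trialSimTruth(missingRate = 0.5), "0, 0.2")

  # all variances zero: values equal exp(baseline + effect)
  tz <- trialSimTruth(litterSD = 0, catSD = 0,
                      residSD = setNames(rep(0, 11), trialMeasureNames()),
                      missingRate = 0)
  sz <- simulateTrial(tz, 3, seed = 2)
  w11 <- sz$observations[sz$observations$measure == "weight" &
                           sz$observations$week == 11 &
                           sz$observations$group == "intact", ]
  expect_equal(unique(w11$value), exp(tz$baselineLog["weight", "11"]))

  # injected fat ratio at the final week closes under geometric means
  tb <- trialSimTruth(effectFinal = c(fat_mass = 1.9), missingRate = 0)
  sb <- simulateTrial(tb, 400, seed = 3)
  fat <- sb$observations[sb$observations$measure == "fat_mass" &
                           sb$observations$week == 52, ]
  gm <- tapply(log(fat$value), fat$group, mean)
  expect_equal(exp(gm[["neutered"]] - gm[["intact"]]), 1.9,
               tolerance = 0.05)
})

test_that("generator configuration errors are caught", {
  expect_error(clinicSimTruth(catZSD = -1), "non-negative")
  expect_error(clinicSimTruth(artifactRates = list(pound = 2, rolled = 0,
                                                   carrier = 0)), "\\[0, 1\\]")
  expect_error(trialSimTruth(residSD = setNames(rep(-1, 11),
                                                trialMeasureNames())),
               "non-negative")
})
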