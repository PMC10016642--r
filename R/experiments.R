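# Simulation experiments validating the two pipelines against the
# generators' known ground truth. These are the package's calibration and
# operating-characteristic studies; the acceptance script and the test
# suite both run them.

#' Null-control trajectory experiment
#'
#' Runs the full Study-1 pipeline on an effect-free clinic population and
#' returns the per-group upward inclinations, which should all be near
#' zero. The default population is large enough that Monte-Carlo noise in
#' the sparse mid-age portions of the subsets does not masquerade as a
#' spurious post-neuter effect.
#'
#' @param nCats Simulated population size (default 80000).
#' @param seed Integer seed.
#' @return The pipeline's inclination table (8 rows, column
#'   \code{delta_z}).
#' @export
nullTrajectoryExperiment <- function(nCats = 80000, seed = 1) {
  truth <- clinicSimTruth(effectAmplitude = c(M = 0, F = 0))
  sim <- simulateClinic(truth, nCats, seed = seed)
  out <- suppressMessages(suppressWarnings(
    runStudy1Pipeline(sim$visits, sim$profiles, truth$standards)))
  out$inclinations
}

#' Type-I error experiment for the pre/post model
#'
#' Replicates the Study-1 pre/post analysis on effect-free populations and
#' records, per replicate, whether any comparison in the restricted family
#' is significant at 5\% after single-step adjustment. Under familywise
#' error control the any-significance rate should be at most about 5\%.
#'
#' @param nReps Number of replicates (default 20).
#' @param nCats Cats per replicate (default 4000).
#' @param seed Integer seed (replicate r uses seed + r).
#' @return data.frame with one row per replicate: \code{any_significant}
#'   and \code{min_p_adjusted}.
#' @export
nullTypeIExperiment <- function(nReps = 20, nCats = 4000, seed = 1) {
  truth <- clinicSimTruth(effectAmplitude = c(M = 0, F = 0))
  res <- lapply(seq_len(nReps), function(r) {
    sim <- simulateClinic(truth, nCats, seed = seed + r)
    out <- suppressMessages(suppressWarnings(
      runStudy1Pipeline(sim$visits, sim$profiles, truth$standards,
                        fitTrajectories = FALSE)))
    p <- out$prepost$comparisons$p_adjusted
    data.frame(replicate = r, any_significant = any(p < 0.05),
               min_p_adjusted = min(p))
  })
  do.call(rbind, res)
}

#' Effect-recovery experiment for the pre/post model
#'
#' Injects a known post-neuter z shift (full shift 1.0 for females, 0.35
#' for males, no decay) and measures how well the pre/post model recovers
#' it. Body condition is made uninformative about z
#' (\code{bcsDependsOnZ = FALSE}) so eligibility does not truncate the
#' estimand, and pairs are restricted to post visits at or beyond the end
#' of growth, where the generator's ramp has delivered the full shift;
#' cell sizes then match the hundreds-per-cell regime of clinic data.
#'
#' @param nReps Number of replicate populations (default 20).
#' @param nCats Cats per replicate (default 7000).
#' @param seed Integer seed (replicate r uses seed + r).
#' @return data.frame of per-replicate cell estimates (sex, group_index,
#'   n, estimate, replicate).
#' @export
effectRecoveryExperiment <- function(nReps = 20, nCats = 7000, seed = 1) {
  truth <- clinicSimTruth(effectAmplitude = c(M = 0.35, F = 1.0),
                          effectDecayPerWeek = 0, bcsDependsOnZ = FALSE)
  res <- lapply(seq_len(nReps), function(r) {
    sim <- simulateClinic(truth, nCats, seed = seed + r, meanVisits = 8)
    out <- suppressMessages(suppressWarnings(
      runStudy1Pipeline(sim$visits, sim$profiles, truth$standards,
                        fitTrajectories = FALSE)))
    pairs <- out$pairs[out$pairs$post_age_weeks >=
                         truth$endOfGrowthWeeks, , drop = FALSE]
    est <- prePostModel(pairs)$estimates
    est$replicate <- r
    est
  })
  do.call(rbind, res)
}

#' Dose-response monotonicity experiment
#'
#' Uses a generator whose post-neuter shift decays steeply with neuter age
#' (equal amplitudes 1.0 for both sexes, decay 0.05 per week, floor 0.2)
#' and checks, per replicate, whether the estimated cell means decrease
#' from neuter group 1 to 4 within each sex.
#'
#' @param nReps Number of replicates (default 20).
#' @param nCats Cats per replicate (default 7000).
#' @param seed Integer seed.
#' @return data.frame with one row per replicate and sex:
#'   \code{monotone} (logical).
#' @export
doseResponseExperiment <- function(nReps = 20, nCats = 7000, seed = 1) {
  truth <- clinicSimTruth(effectAmplitude = c(M = 1.0, F = 1.0),
                          effectDecayPerWeek = 0.05, effectFloor = 0.2,
                          bcsDependsOnZ = FALSE)
  res <- lapply(seq_len(nReps), function(r) {
    sim <- simulateClinic(truth, nCats, seed = seed + r, meanVisits = 8)
    out <- suppressMessages(suppressWarnings(
      runStudy1Pipeline(sim$visits, sim$profiles, truth$standards,
                        fitTrajectories = FALSE)))
    pairs <- out$pairs[out$pairs$post_age_weeks >=
                         truth$endOfGrowthWeeks, , drop = FALSE]
    est <- prePostModel(pairs)$estimates
    do.call(rbind, lapply(split(est, est$sex), function(e) {
      e <- e[order(e$group_index), ]
      data.frame(replicate = r, sex = e$sex[1],
                 monotone = all(diff(e$estimate) < 0))
    }))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Simultaneous-interval coverage experiment for the trial model
#'
#' Replicates the littermate trial at its design size (11 litters) with
#' the generator's default effects (fold-change ratios 1.34 / 1.91 / 1.23
#' / 1.20 / 1.18 on weight, fat, lean, girth, ribcage at the final week),
#' fits the multivariate mixed model at a reduced MCMC schedule, and
#' records whether the simultaneous 95\% intervals cover the entire true
#' ratio vector, and the fat-mass final-week ratio specifically.
#'
#' @param nReps Number of replicates (default 50).
#' @param nLitters Litters per replicate (default 11).
#' @param schedule Reduced MCMC schedule (default 2 chains x 500, 250
#'   warm-up, no thinning: 500 retained draws).
#' @param seed Integer seed (replicate r uses seed + r).
#' @param fatRatio Final-week fat-mass ratio injected by the generator
#'   (default 1.9).
#' @return data.frame with one row per replicate: \code{covers_all} and
#'   \code{covers_fat_final}.
#' @export
mvmmCoverageExperiment <- function(nReps = 50, nLitters = 11,
                                   schedule = list(chains = 2L,
                                                   iterations = 500L,
                                                   warmup = 250L,
                                                   thin = 1L),
                                   seed = 1, fatRatio = 1.9) {
  truth <- trialSimTruth(effectFinal = c(weight = 1.34, fat_mass = fatRatio,
                                         lean_mass = 1.23, girth = 1.20,
                                         ribcage = 1.18))
  weeks <- truth$weeks
  finalWeek <- weeks[length(weeks)]
  trueRatio <- exp(truth$effectLog)  # measure x week matrix
  res <- lapply(seq_len(nReps), function(r) {
    sim <- simulateTrial(truth, nLitters, seed = seed + r)
    panel <- standardizeMeasures(sim$observations)
    post <- fitMVMM(panel, schedule = schedule, seed = seed + r,
                    failOnDiagnostics = FALSE)
    fc <- foldChangeSummaries(post, baselineWeek = weeks[1])
    rt <- fc$ratios
    tv <- trueRatio[cbind(match(rt$measure, rownames(trueRatio)),
                          match(as.character(rt$week),
                                colnames(trueRatio)))]
    live <- rt$week != weeks[1]
    ok <- rt$sim_lower[live] <= tv[live] & tv[live] <= rt$sim_upper[live]
    fat <- rt$measure == "fat_mass" & rt$week == finalWeek
    data.frame(replicate = r, covers_all = all(ok),
               covers_fat_final = rt$sim_lower[fat] <= fatRatio &&
                 fatRatio <= rt$sim_upper[fat])
  })
  do.call(rbind, res)
}
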