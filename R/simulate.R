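# Synthetic clinic and littermate-trial data with fully known ground truth.
# The generators define the study conditions under which the pipelines are
# exercised: every latent quantity used for a record is returned in a truth
# table, so downstream recovery can be checked exactly.

rmvn1 <- function(n, Sigma) {
  # eigen-based so positive *semi*-definite matrices (e.g. zero variance)
  # are valid
  e <- eigen(Sigma, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  A <- e$vectors %*% (sqrt(ev) * t(e$vectors))
  matrix(rnorm(n * ncol(Sigma)), n) %*% A
}

#' Built-in smooth parametric growth standard
#'
#' A qualitative feline growth standard used as the generator's truth:
#' Gompertz-shaped median curve (adult weight 4.6 kg for males, 3.7 kg for
#' females), a coefficient of variation easing from about 0.14 in early
#' kittenhood to 0.10 at maturity, and a mild Box-Cox power decaying with
#' age. Shapes are configuration, not claims about any published standard.
#'
#' @param sex "M" or "F".
#' @param ageGridWeeks Grid on which the curves are tabulated.
#' @return A [GrowthStandard-class].
#' @export
defaultGrowthStandard <- function(sex = c("M", "F"),
                                  ageGridWeeks = seq(3, 135, by = 1)) {
  sex <- match.arg(sex)
  t <- ageGridWeeks
  if (sex == "M") { A <- 4.6; b <- 2.3; k <- 0.060 }
  else            { A <- 3.7; b <- 2.2; k <- 0.062 }
  M <- A * exp(-b * exp(-k * t))
  S <- 0.10 + 0.04 * exp(-t / 40)
  L <- 0.25 + 0.45 * exp(-t / 60)
  GrowthStandard(sex, t, L = L, M = M, S = S)
}

#' Ground truth for the clinic simulator
#'
#' Collects everything [simulateClinic()] needs: the true per-sex growth
#' standards, the SD of the cat-level z offset, the post-neuter z-shift
#' (amplitude per sex, decaying linearly in neuter age), log-scale
#' measurement noise, artifact rates and the neuter-age distributions.
#' The default female amplitude exceeds the male one and the shift decays
#' with neuter age, mirroring the qualitative clinical regime.
#'
#' @param standards Named list of [GrowthStandard-class] objects for "M"
#'   and "F".
#' @param catZSD SD of the stable cat-level z offset.
#' @param noiseLogSD SD of log-scale measurement noise per weighing.
#' @param effectAmplitude Named vector, full post-neuter z shift for a cat
#'   neutered at \code{effectRefAgeWeeks}, per sex.
#' @param effectDecayPerWeek Linear decay of the shift per week of neuter
#'   age beyond the reference age.
#' @param effectFloor Lower clamp on the decay factor.
#' @param effectRefAgeWeeks Neuter age at which the full amplitude applies.
#' @param endOfGrowthWeeks Age by which the post-neuter ramp is complete.
#' @param artifactRates Named list: \code{pound} (fraction of rows rounded
#'   to whole pounds), \code{rolled} (weights rolled over from the previous
#'   visit), \code{carrier} (weighed in a carrier).
#' @param neuterAgeMeanlog,neuterAgeSdlog Named per-sex lognormal
#'   parameters of neuter age in weeks.
#' @param intactFraction Fraction of cats never neutered.
#' @param bcsUnknownRate Fraction of visits with unrecorded BCS.
#' @param exclusionRate Fraction of cats acquiring an exclusion diagnosis.
#' @param bcsDependsOnZ If TRUE (default), body-condition categories are
#'   driven by the cat's current latent z (heavy above +2.2, thin below
#'   -2.2), so eligibility genuinely selects against cats whose z drifts --
#'   the clinic-like regime. FALSE makes every recorded BCS "normal",
#'   decoupling eligibility from the outcome (useful when the estimand is
#'   pure estimator recovery).
#' @return List of class \code{"clinicSimTruth"}.
#' @export
clinicSimTruth <- function(standards = list(M = defaultGrowthStandard("M"),
                                            F = defaultGrowthStandard("F")),
                           catZSD = 0.8, noiseLogSD = 0.06,
                           effectAmplitude = c(M = 0.35, F = 1.3),
                           effectDecayPerWeek = 0.025,
                           effectFloor = 0.3,
                           effectRefAgeWeeks = 20,
                           endOfGrowthWeeks = 78,
                           artifactRates = list(pound = 0.15, rolled = 0.02,
                                                carrier = 0.02),
                           neuterAgeMeanlog = c(M = log(23), F = log(25)),
                           neuterAgeSdlog = c(M = 0.25, F = 0.25),
                           intactFraction = 0.2,
                           bcsUnknownRate = 0.3,
                           exclusionRate = 0.02,
                           bcsDependsOnZ = TRUE) {
  if (catZSD < 0 || noiseLogSD < 0)
    stop("clinicSimTruth: SDs must be non-negative", call. = FALSE)
  rates <- unlist(artifactRates)
  if (any(rates < 0 | rates > 1))
    stop("clinicSimTruth: artifact rates must lie in [0, 1]", call. = FALSE)
  if (any(effectAmplitude < 0))
    stop("clinicSimTruth: effect amplitudes must be non-negative",
         call. = FALSE)
  structure(list(standards = standards, catZSD = catZSD,
                 noiseLogSD = noiseLogSD,
                 effectAmplitude = effectAmplitude,
                 effectDecayPerWeek = effectDecayPerWeek,
                 effectFloor = effectFloor,
                 effectRefAgeWeeks = effectRefAgeWeeks,
                 endOfGrowthWeeks = endOfGrowthWeeks,
                 artifactRates = artifactRates,
                 neuterAgeMeanlog = neuterAgeMeanlog,
                 neuterAgeSdlog = neuterAgeSdlog,
                 intactFraction = intactFraction,
                 bcsUnknownRate = bcsUnknownRate,
                 exclusionRate = exclusionRate,
                 bcsDependsOnZ = bcsDependsOnZ),
            class = c("clinicSimTruth", "list"))
}

#' Full post-neuter z shift implied by a clinic truth
#'
#' @param truth A [clinicSimTruth()] list.
#' @param sex "M" or "F" (vectorized).
#' @param neuterAgeWeeks Neuter age in weeks (vectorized).
#' @return The asymptotic z shift reached by the end of growth.
#' @export
neuterEffectDeltaZ <- function(truth, sex, neuterAgeWeeks) {
  fac <- pmin(pmax(1 - truth$effectDecayPerWeek *
                     (neuterAgeWeeks - truth$effectRefAgeWeeks),
                   truth$effectFloor), 1)
  unname(truth$effectAmplitude[sex] * fac)
}

# Visit-age generator: preventative-care milestone clusters plus a uniform
# background over 5-130 weeks.
milestoneAges <- c(8, 12, 16, 24, 52, 80, 104, 120)
milestoneWeights <- c(0.18, 0.18, 0.14, 0.10, 0.12, 0.12, 0.09, 0.07)

sampleVisitAges <- function(n) {
  fromCluster <- runif(n) < 0.65
  ages <- numeric(n)
  k <- sum(fromCluster)
  if (k) {
    centres <- sample(milestoneAges, k, replace = TRUE,
                      prob = milestoneWeights)
    ages[fromCluster] <- centres + rnorm(k, 0, 1.5)
  }
  ages[!fromCluster] <- runif(n - k, 5, 130)
  pmin(pmax(ages, 5), 130)
}

#' Simulate a clinic population of longitudinal weighings
#'
#' Draws cats with a stable latent z offset around the true sex-specific
#' growth standard, visit ages from a preventative-care milestone mixture,
#' a post-neuter upward z ramp (linear from neuter age, complete by the end
#' of growth), log-normal measurement noise, and configurable measurement
#' artifacts (whole-pound rounding, rolled-over weights, carrier
#' weighings). Every latent quantity is returned in the truth table.
#'
#' @param truth A [clinicSimTruth()] list.
#' @param nCats Number of cats (>= 1).
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @param meanVisits Mean number of visits per cat (Poisson + 2).
#' @return List with \code{visits}, \code{profiles}, \code{truth} (one row
#'   per visit: latent z before and after noise, artifact flags) and
#'   \code{catTruth} (one row per cat: z offset, neuter age, full z shift).
#' @export
simulateClinic <- function(truth, nCats, seed, meanVisits = 5) {
  stopifnot(is(truth, "clinicSimTruth") || inherits(truth, "clinicSimTruth"))
  if (nCats < 1) stop("simulateClinic: nCats must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))

  sex <- sample(c("M", "F"), nCats, replace = TRUE)
  birth <- as.Date("2006-01-01") + sample.int(2500, nCats, replace = TRUE)
  z0 <- rnorm(nCats, 0, truth$catZSD)
  neutered <- runif(nCats) >= truth$intactFraction
  neuterAgeWk <- rep(NA_real_, nCats)
  neuterAgeWk[neutered] <- rlnorm(sum(neutered),
                                  truth$neuterAgeMeanlog[sex[neutered]],
                                  truth$neuterAgeSdlog[sex[neutered]])
  fullShift <- ifelse(neutered,
                      neuterEffectDeltaZ(truth, sex, neuterAgeWk), 0)
  exclCat <- runif(nCats) < truth$exclusionRate

  nVisits <- 2 + rpois(nCats, max(meanVisits - 2, 0.1))
  catIdx <- rep.int(seq_len(nCats), nVisits)
  age <- sampleVisitAges(length(catIdx))
  ord <- order(catIdx, age)
  catIdx <- catIdx[ord]; age <- age[ord]
  # distinct visit days per cat: bump same-day collisions forward, then
  # re-derive age from the day so age_weeks = (visit - birth)/7 exactly
  day <- round(age * DAYS_PER_WEEK)
  for (rows in split(seq_along(day), catIdx)) {
    while (anyDuplicated(day[rows])) {
      dup <- rows[duplicated(day[rows])]
      day[dup] <- day[dup] + 1L
    }
  }
  age <- day / DAYS_PER_WEEK

  ramp <- function(t, nAge) {
    out <- (t - nAge) / pmax(truth$endOfGrowthWeeks - nAge, 1)
    pmin(pmax(out, 0), 1)
  }
  nAgeRow <- neuterAgeWk[catIdx]
  rampRow <- ifelse(is.na(nAgeRow), 0, ramp(age, nAgeRow))
  zLatent <- z0[catIdx] + fullShift[catIdx] * rampRow
  zLatent <- pmin(pmax(zLatent, -6), 6)

  lmsRow <- function(sx) {
    std <- truth$standards[[sx]]
    idx <- which(sex[catIdx] == sx)
    lmsAt(std, age[idx], extrapolate = TRUE)
  }
  weight <- numeric(length(catIdx))
  for (sx in c("M", "F")) {
    idx <- which(sex[catIdx] == sx)
    if (!length(idx)) next
    lms <- lmsAt(truth$standards[[sx]], age[idx], extrapolate = TRUE)
    weight[idx] <- bccgCentile(pnorm(zLatent[idx]), lms$M, lms$S, lms$L)
  }
  noise <- rnorm(length(weight), 0, truth$noiseLogSD)
  weight <- weight * exp(noise)

  # artifacts
  pound <- runif(length(weight)) < truth$artifactRates$pound
  lb <- pmax(round(weight * LB_PER_KG), 1)
  weight[pound] <- lb[pound] / LB_PER_KG
  rolled <- runif(length(weight)) < truth$artifactRates$rolled
  prevSame <- c(FALSE, catIdx[-1] == catIdx[-length(catIdx)])
  rolled <- rolled & prevSame
  if (any(rolled)) weight[rolled] <- weight[which(rolled) - 1L]
  carrier <- runif(length(weight)) < truth$artifactRates$carrier
  weight[carrier] <- weight[carrier] + runif(sum(carrier), 0.5, 2)

  # BCS: driven by the total latent z (offset + ramp), with unknowns
  zObs <- zLatent + noise / 0.1
  bcs <- rep("normal", length(weight))
  if (isTRUE(truth$bcsDependsOnZ)) {
    bcs[zObs > 2.2] <- "heavy"
    bcs[zObs < -2.2] <- "thin"
  }
  bcs[runif(length(weight)) < truth$bcsUnknownRate] <- "unknown"

  vcat <- sample(c("preventative", "healthy_diagnosis", "other"),
                 length(weight), replace = TRUE, prob = c(0.8, 0.1, 0.1))
  exclRow <- rep(FALSE, length(weight))
  for (i in which(exclCat)) {
    rows <- which(catIdx == i)
    exclRow[sample(rows, 1)] <- TRUE
  }

  visits <- data.frame(
    cat_id = sprintf("cat%05d", catIdx),
    sex = sex[catIdx],
    birth_date = birth[catIdx],
    visit_date = birth[catIdx] + day,
    age_weeks = age,
    bodyweight_kg = weight,
    visit_category = vcat,
    bcs_category = bcs,
    rolled_over = rolled,
    in_carrier = carrier,
    stringsAsFactors = FALSE
  )
  visits$row_id <- seq_len(nrow(visits))

  profiles <- data.frame(
    cat_id = sprintf("cat%05d", seq_len(nCats)),
    sex = sex, birth_date = birth,
    stringsAsFactors = FALSE
  )
  profiles$neuter_date <- birth +
    ifelse(neutered, round(neuterAgeWk * DAYS_PER_WEEK), NA)
  profiles$neuter_date <- as.Date(profiles$neuter_date, origin = "1970-01-01")
  profiles$neuter_age_years <-
    as.numeric(profiles$neuter_date - profiles$birth_date) / DAYS_PER_YEAR
  exclDate <- rep(as.Date(NA), nCats)
  exclDate[exclCat] <- visits$visit_date[exclRow][
    match(which(exclCat), catIdx[exclRow])]
  profiles$first_exclusion_date <- exclDate

  truthTab <- data.frame(
    row_id = visits$row_id,
    cat_id = visits$cat_id,
    z_latent = zLatent,
    log_noise = noise,
    pound_rounded = pound,
    rolled_over = rolled,
    in_carrier = carrier,
    exclusion_visit = exclRow,
    stringsAsFactors = FALSE
  )
  catTruth <- data.frame(
    cat_id = profiles$cat_id, sex = sex, z_offset = z0,
    neutered = neutered, neuter_age_weeks = neuterAgeWk,
    full_z_shift = fullShift, exclusion_cat = exclCat,
    stringsAsFactors = FALSE
  )
  list(visits = visits, profiles = profiles, truth = truthTab,
       catTruth = catTruth)
}

#' Ground truth for the littermate-trial simulator
#'
#' Log-scale baselines per measure and week, a group-by-week effect matrix
#' concentrated on weight, fat mass, lean mass, girth and ribcage (zero at
#' the pre-neutering weeks), litter- and cat-level cross-measure random
#' effects with exchangeable correlation, per-measure residual SDs and an
#' MCAR missingness rate.
#'
#' @param weeks Measurement weeks (strictly increasing).
#' @param litterSD,litterCor SD (log scale) and exchangeable correlation of
#'   the litter-level random effect across measures.
#' @param catSD,catCor Same for the cat-level effect.
#' @param residSD Named per-measure residual SDs (log scale).
#' @param effectFinal Named vector of group fold-change ratios at the final
#'   week for the affected measures (log of these enters the effect
#'   matrix); other measures are unaffected.
#' @param effectMidFraction Fraction of the final log effect already
#'   present at the third week (the first post-neutering measurement wave
#'   after the 18-week one).
#' @param missingRate MCAR missingness rate in [0, 0.2].
#' @return List of class \code{"trialSimTruth"} with \code{baselineLog}
#'   (measure x week), \code{effectLog} (measure x week), covariance
#'   matrices and rates.
#' @export
trialSimTruth <- function(weeks = c(11L, 18L, 30L, 52L),
                          litterSD = 0.04, litterCor = 0.4,
                          catSD = 0.06, catCor = 0.5,
                          residSD = NULL,
                          effectFinal = c(weight = 1.34, fat_mass = 1.91,
                                          lean_mass = 1.23, girth = 1.20,
                                          ribcage = 1.18),
                          effectMidFraction = 0.5,
                          missingRate = 0.003) {
  if (any(diff(weeks) <= 0))
    stop("trialSimTruth: weeks must be strictly increasing", call. = FALSE)
  if (missingRate < 0 || missingRate > 0.2)
    stop("trialSimTruth: missingRate must lie in [0, 0.2]", call. = FALSE)
  m <- trialMeasures
  baseline <- rbind(
    weight      = c(1.20, 2.00, 2.80, 3.30),
    fat_mass    = c(0.15, 0.35, 0.55, 0.75),
    lean_mass   = c(1.00, 1.60, 2.20, 2.50),
    height      = c(20.0, 23.0, 25.0, 26.0),
    length      = c(35.0, 42.0, 47.0, 49.0),
    girth       = c(22.0, 25.0, 27.0, 28.0),
    ribcage     = c(26.0, 30.0, 33.0, 34.0),
    chest_depth = c(8.0, 9.5, 10.5, 11.0),
    elbow_width = c(2.6, 3.0, 3.3, 3.4),
    forelimb    = c(8.0, 9.5, 10.5, 11.0),
    hindlimb    = c(9.0, 11.0, 12.0, 12.5)
  )
  if (length(weeks) != ncol(baseline))
    baseline <- t(apply(baseline, 1, function(b)
      approx(c(11, 18, 30, 52), b, xout = weeks, rule = 2)$y))
  baselineLog <- log(baseline)
  colnames(baselineLog) <- as.character(weeks)

  effectLog <- matrix(0, length(m), length(weeks),
                      dimnames = list(m, as.character(weeks)))
  nm <- intersect(names(effectFinal), m)
  nw <- length(weeks)
  effectLog[nm, nw] <- log(effectFinal[nm])
  if (nw >= 3) effectLog[nm, nw - 1] <- effectMidFraction * log(effectFinal[nm])

  exch <- function(sd, rho, k) {
    C <- matrix(rho, k, k); diag(C) <- 1
    (sd^2) * C
  }
  SigmaLitter <- exch(litterSD, litterCor, length(m))
  SigmaCat <- exch(catSD, catCor, length(m))
  dimnames(SigmaLitter) <- dimnames(SigmaCat) <- list(m, m)
  for (S in list(SigmaLitter, SigmaCat))
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("trialSimTruth: random-effect covariance is not positive semi-definite",
           call. = FALSE)

  if (is.null(residSD))
    residSD <- c(weight = 0.04, fat_mass = 0.10, lean_mass = 0.05,
                 height = 0.025, length = 0.02, girth = 0.03,
                 ribcage = 0.025, chest_depth = 0.03, elbow_width = 0.03,
                 forelimb = 0.025, hindlimb = 0.025)
  residSD <- residSD[m]
  if (any(!is.finite(residSD) | residSD < 0))
    stop("trialSimTruth: residSD must be non-negative for every measure",
         call. = FALSE)

  structure(list(weeks = as.integer(weeks), measures = m,
                 baselineLog = baselineLog, effectLog = effectLog,
                 SigmaLitter = SigmaLitter, SigmaCat = SigmaCat,
                 residSD = residSD, missingRate = missingRate),
            class = c("trialSimTruth", "list"))
}

#' Simulate a neutered-vs-intact littermate trial
#'
#' For each litter two cats share a litter-level random effect; one is
#' assigned to each group. Log values are baseline + group-by-week effect
#' + litter effect + cat effect + residual; a configured fraction is
#' flagged missing completely at random.
#'
#' @param truth A [trialSimTruth()] list.
#' @param nLitters Number of litters (>= 2).
#' @param seed Integer seed.
#' @return List with \code{observations} (long data.frame with
#'   \code{missing} flag; \code{value} is NA where missing) and
#'   \code{truth} (latent log-mean per observation).
#' @export
simulateTrial <- function(truth, nLitters, seed) {
  stopifnot(inherits(truth, "trialSimTruth"))
  if (nLitters < 2) stop("simulateTrial: nLitters must be >= 2", call. = FALSE)
  set.seed(as.integer(seed))
  m <- truth$measures; weeks <- truth$weeks
  nm <- length(m); nw <- length(weeks)

  u <- rmvn1(nLitters, truth$SigmaLitter)          # litter x measure
  v <- rmvn1(2 * nLitters, truth$SigmaCat)         # cat x measure

  rows <- expand.grid(measure = m, week = weeks, catInLitter = 1:2,
                      litter = seq_len(nLitters), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  rows$group <- ifelse(rows$catInLitter == 1L, "neutered", "intact")
  catNo <- (rows$litter - 1L) * 2L + rows$catInLitter
  mi <- match(rows$measure, m)
  wi <- match(rows$week, weeks)
  latent <- truth$baselineLog[cbind(mi, wi)] +
    truth$effectLog[cbind(mi, wi)] * (rows$group == "neutered") +
    u[cbind(rows$litter, mi)] + v[cbind(catNo, mi)]
  value <- exp(latent + rnorm(nrow(rows), 0, truth$residSD[mi]))
  miss <- runif(nrow(rows)) < truth$missingRate

  obs <- data.frame(
    litter_id = sprintf("L%02d", rows$litter),
    cat_id = sprintf("L%02dC%d", rows$litter, rows$catInLitter),
    group = rows$group,
    week = as.integer(rows$week),
    measure = rows$measure,
    value = ifelse(miss, NA_real_, value),
    missing = miss,
    stringsAsFactors = FALSE
  )
  truthTab <- data.frame(
    cat_id = obs$cat_id, week = obs$week, measure = obs$measure,
    latent_log_mean = latent, value_complete = value,
    stringsAsFactors = FALSE
  )
  validateTrialObservations(obs)
  list(observations = obs, truth = truthTab)
}
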