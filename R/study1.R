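# Study 1: neuter-group subset construction, per-group BCCG trajectory
# modelling on the z-score scale, and the within-individual pre/post linear
# model with single-step (Tukey-type) multiplicity adjustment.

#' Per-sex neuter-age quartiles and group windows
#'
#' Splits the neuter-age axis at the lower quartile, median and upper
#' quartile of the observed neuter ages for each sex (type-7 linear
#' interpolation), defining four group windows per sex: group 1 from 0 to
#' Q1, group 4 open-ended above Q3.
#'
#' @param neuterAgesBySex Named list (\code{M}, \code{F}) of neuter ages in
#'   years, or a profiles data.frame with \code{sex} and
#'   \code{neuter_age_years}.
#' @return data.frame of group specs: \code{sex}, \code{group_index},
#'   \code{lower_age_years}, \code{upper_age_years}, plus per-sex quartiles
#'   in the \code{"quartiles"} attribute.
#' @export
computeNeuterQuartiles <- function(neuterAgesBySex) {
  if (is.data.frame(neuterAgesBySex)) {
    df <- neuterAgesBySex
    neuterAgesBySex <- split(df$neuter_age_years[!is.na(df$neuter_age_years)],
                             df$sex[!is.na(df$neuter_age_years)])
  }
  specs <- list(); quartiles <- list()
  for (sx in names(neuterAgesBySex)) {
    ages <- neuterAgesBySex[[sx]]
    if (length(ages) < 4)
      stop(sprintf("computeNeuterQuartiles: need >= 4 neuter ages for sex %s",
                   sx), call. = FALSE)
    q <- quantile(ages, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    if (any(diff(q) <= 0))
      stop(sprintf("computeNeuterQuartiles: degenerate (zero-width) neuter groups for sex %s",
                   sx), call. = FALSE)
    quartiles[[sx]] <- q
    specs[[sx]] <- data.frame(
      sex = sx, group_index = 1:4,
      lower_age_years = c(0, q),
      upper_age_years = c(q, Inf),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, specs)
  rownames(out) <- NULL
  attr(out, "quartiles") <- quartiles
  out
}

neuterGroupOf <- function(specs, sex, neuterAgeYears) {
  out <- rep(NA_integer_, length(neuterAgeYears))
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    hit <- sex == s$sex & !is.na(neuterAgeYears) &
      neuterAgeYears >= s$lower_age_years &
      (neuterAgeYears < s$upper_age_years | is.infinite(s$upper_age_years))
    out[hit] <- s$group_index
  }
  out
}

#' Build the 8 neuter-group data subsets
#'
#' For each sex and group window, the subset holds (a) all rows taken while
#' the cat was still sexually intact, at ages up to the window's lower
#' bound, from every cat of that sex, and (b) all rows of cats actually
#' neutered inside the window. Subsets of a sex therefore overlap in their
#' pre-neuter portions; post-window rows of a neutered cat appear only in
#' its own group's subset.
#'
#' @param visits Visits data.frame.
#' @param profiles Profiles data.frame with \code{neuter_age_years}.
#' @param specs Group specs from [computeNeuterQuartiles()].
#' @return Named list (\code{M1} ... \code{F4}) of visit data.frames, each
#'   carrying its spec row and its cohort's neuter ages (weeks) as
#'   attributes.
#' @export
buildNeuterSubsets <- function(visits, profiles, specs) {
  visits <- ensureRowIds(visits)
  m <- match(visits$cat_id, profiles$cat_id)
  nAgeY <- profiles$neuter_age_years[m]
  nAgeW <- yearsToWeeks(nAgeY)
  grp <- neuterGroupOf(specs, visits$sex, nAgeY)
  neuteredSomewhere <- !is.na(nAgeY)
  stopifnot(all(!neuteredSomewhere | !is.na(grp)))  # windows partition the axis

  out <- list()
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    loW <- yearsToWeeks(s$lower_age_years)
    intactRows <- visits$sex == s$sex & visits$age_weeks <= loW &
      (!neuteredSomewhere | visits$age_weeks <= nAgeW)
    memberRows <- visits$sex == s$sex & !is.na(grp) & grp == s$group_index
    sub <- visits[intactRows | memberRows, , drop = FALSE]
    cohort <- profiles$neuter_age_years[!is.na(profiles$neuter_age_years) &
                                          profiles$sex == s$sex]
    cohort <- cohort[cohort >= s$lower_age_years &
                       (cohort < s$upper_age_years |
                          is.infinite(s$upper_age_years))]
    if (!length(cohort))
      warning(sprintf("buildNeuterSubsets: empty neutered contingent for %s group %d",
                      s$sex, s$group_index))
    attr(sub, "spec") <- s
    attr(sub, "neuter_ages_weeks") <- yearsToWeeks(cohort)
    out[[paste0(s$sex, s$group_index)]] <- sub
  }
  out
}

#' Median z-score trajectory of a neuter-group subset
#'
#' Fits a BCCG model to the subset's weights (same machinery as the
#' standards), extracts the median and interquartile centiles on the age
#' grid, and converts each centile curve to z-scores of the reference
#' standard.
#'
#' @param subset A subset from [buildNeuterSubsets()].
#' @param standard Reference [GrowthStandard-class] of the matching sex.
#' @param control A [bccgControl()] list for the subset fit.
#' @param ageGridWeeks Optional evaluation grid.
#' @return A [ZTrajectory-class].
#' @export
medianTrajectoryZ <- function(subset, standard, control = bccgControl(),
                              ageGridWeeks = NULL) {
  s <- attr(subset, "spec")
  if (is.null(s))
    s <- data.frame(sex = unique(subset$sex)[1], group_index = NA_integer_,
                    lower_age_years = NA_real_, upper_age_years = NA_real_)
  fit <- fitGrowthModel(subset, control = control, sex = s$sex,
                        ageGridWeeks = ageGridWeeks)
  grid <- ageGrid(fit)
  rng <- range(ageGrid(standard))
  grid <- grid[grid >= rng[1] & grid <= rng[2]]
  cent <- extractCentiles(fit, grid, probs = c(0.25, 0.5, 0.75))
  lms <- lmsAt(standard, grid)
  zc <- function(p) {
    w <- cent$weight_kg[cent$p == p]
    bccgZScore(w, lms$M, lms$S, lms$L)
  }
  nAges <- attr(subset, "neuter_ages_weeks")
  new("ZTrajectory",
      sex = s$sex, groupIndex = as.integer(s$group_index),
      lowerAgeYears = as.numeric(s$lower_age_years),
      upperAgeYears = as.numeric(s$upper_age_years),
      medianNeuterAgeWeeks = if (length(nAges)) median(nAges) else NA_real_,
      ageGridWeeks = grid,
      zMedian = zc(0.5), zQ25 = zc(0.25), zQ75 = zc(0.75),
      nCats = length(unique(subset$cat_id)), nRows = nrow(subset))
}

#' Upward inclination of a trajectory by the end of growth
#'
#' The change in the median-centile z-score between a reference age and the
#' end of the growth period. By default the reference is the group's median
#' observed neuter age; \code{from = "zero"} measures from z = 0 instead.
#'
#' @param traj A [ZTrajectory-class].
#' @param endAgeWeeks End of the growth period (default 78).
#' @param from Either \code{"neuter_age"} (default) or \code{"zero"}.
#' @return The z-score change (a scalar).
#' @export
upwardInclination <- function(traj, endAgeWeeks = 78,
                              from = c("neuter_age", "zero")) {
  from <- match.arg(from)
  grid <- traj@ageGridWeeks
  if (endAgeWeeks > max(grid) + 1e-9 || endAgeWeeks < min(grid) - 1e-9)
    stop(sprintf("upwardInclination: end age %.1f outside trajectory grid [%.1f, %.1f]",
                 endAgeWeeks, min(grid), max(grid)), call. = FALSE)
  zEnd <- approx(grid, traj@zMedian, xout = endAgeWeeks)$y
  if (from == "zero") return(zEnd)
  ref <- traj@medianNeuterAgeWeeks
  if (!is.finite(ref))
    stop("upwardInclination: trajectory has no median neuter age", call. = FALSE)
  ref <- min(max(ref, min(grid)), max(grid))
  zEnd - approx(grid, traj@zMedian, xout = ref)$y
}

#' Select pre/post-neutering z-score pairs
#'
#' For every neutered cat: the z-score at the last visit strictly before
#' the neuter date and at the last available visit after it. Cats missing
#' either visit, or whose two visits are less than \code{minGapWeeks}
#' apart, are excluded.
#'
#' @param visitsZ Visits data.frame with a \code{z} column (see
#'   [toZScores()]).
#' @param profiles Profiles with \code{neuter_date} and
#'   \code{neuter_age_years}.
#' @param specs Group specs from [computeNeuterQuartiles()].
#' @param minGapWeeks Minimum pre-to-post gap (default 13 weeks = 3
#'   months).
#' @return data.frame: \code{cat_id}, \code{sex}, \code{group_index},
#'   \code{pre_z}, \code{post_z}, \code{gap_weeks}.
#' @export
selectPrePostPairs <- function(visitsZ, profiles, specs, minGapWeeks = 13) {
  stopifnot("z" %in% names(visitsZ))
  prof <- profiles[!is.na(profiles$neuter_date), , drop = FALSE]
  vz <- visitsZ[!is.na(visitsZ$z), , drop = FALSE]
  idx <- split(seq_len(nrow(vz)), vz$cat_id)
  res <- vector("list", nrow(prof))
  for (i in seq_len(nrow(prof))) {
    rows <- idx[[prof$cat_id[i]]]
    if (is.null(rows)) next
    nd <- prof$neuter_date[i]
    pre <- rows[vz$visit_date[rows] < nd]
    post <- rows[vz$visit_date[rows] > nd]
    if (!length(pre) || !length(post)) next
    pre <- pre[which.max(vz$age_weeks[pre])]
    post <- post[which.max(vz$age_weeks[post])]
    gap <- vz$age_weeks[post] - vz$age_weeks[pre]
    if (gap < minGapWeeks) next
    res[[i]] <- data.frame(
      cat_id = prof$cat_id[i], sex = prof$sex[i],
      group_index = neuterGroupOf(specs, prof$sex[i],
                                  prof$neuter_age_years[i]),
      pre_z = vz$z[pre], post_z = vz$z[post], gap_weeks = gap,
      pre_age_weeks = vz$age_weeks[pre],
      post_age_weeks = vz$age_weeks[post],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(cat_id = character(), sex = character(),
                      group_index = integer(), pre_z = numeric(),
                      post_z = numeric(), gap_weeks = numeric(),
                      pre_age_weeks = numeric(), post_age_weeks = numeric())
  rownames(out) <- NULL
  out
}

prePostFamily <- function(cells) {
  # restricted family: groups within sex, and sexes within group
  pairs <- list()
  sexes <- unique(cells$sex); groups <- sort(unique(cells$group_index))
  for (sx in sexes) {
    g <- groups
    for (i in seq_along(g)) for (j in seq_along(g)) if (i < j)
      pairs[[length(pairs) + 1]] <- c(paste0(sx, g[i]), paste0(sx, g[j]))
  }
  if (length(sexes) == 2)
    for (gr in groups)
      pairs[[length(pairs) + 1]] <- c(paste0(sexes[1], gr),
                                      paste0(sexes[2], gr))
  pairs
}

cldInsertAbsorb <- function(items, sigPairs) {
  # insert-and-absorb compact letter display over a significance list
  letters_ <- list(seq_along(items))
  for (p in sigPairs) {
    i <- match(p[1], items); j <- match(p[2], items)
    for (k in rev(seq_along(letters_))) {
      L <- letters_[[k]]
      if (i %in% L && j %in% L) {
        letters_[[k]] <- NULL
        letters_ <- c(letters_, list(setdiff(L, i)), list(setdiff(L, j)))
      }
    }
    # absorb duplicates/subsets
    keep <- rep(TRUE, length(letters_))
    for (a in seq_along(letters_)) for (b in seq_along(letters_))
      if (a != b && keep[a] && keep[b] &&
          all(letters_[[a]] %in% letters_[[b]]) &&
          !(all(letters_[[b]] %in% letters_[[a]]) && a < b))
        keep[a] <- FALSE
    letters_ <- letters_[keep]
  }
  codes <- letters[seq_along(letters_)]
  vapply(seq_along(items), function(i)
    paste0(codes[vapply(letters_, function(L) i %in% L, TRUE)],
           collapse = ""), character(1))
}

#' Pre/post-neutering linear model with Tukey-type adjustment
#'
#' Least-squares fit of the post-neutering z-score on the pre-neutering
#' z-score plus a sex-by-group cell mean (8 cells), so each cell's
#' coefficient is the estimated post-neutering z for a cat at the median
#' weight (pre-z = 0) -- i.e. the estimated change in z-score. Multiplicity
#' over the restricted comparison family (neuter groups within each sex,
#' and sexes within each neuter group) is controlled by single-step
#' max-|t| (Tukey-type) adjusted p-values; compact letter codes are derived
#' per family by insert-and-absorb.
#'
#' @param pairs data.frame from [selectPrePostPairs()].
#' @param level Confidence level for the per-cell intervals (default 0.95).
#' @return List with \code{fit} (the lm), \code{estimates} (per-cell mean
#'   change at pre-z = 0 with pointwise CI and letter codes), and
#'   \code{comparisons} (family contrasts with single-step adjusted
#'   p-values).
#' @export
prePostModel <- function(pairs, level = 0.95) {
  cells <- unique(pairs[, c("sex", "group_index")])
  cells <- cells[order(cells$sex, cells$group_index), ]
  counts <- table(paste0(pairs$sex, pairs$group_index))
  expected <- paste0(rep(c("F", "M"), each = 4), 1:4)
  present <- intersect(expected, names(counts))
  tooSmall <- names(counts)[counts < 2]
  if (length(tooSmall))
    stop(sprintf("prePostModel: cell(s) with < 2 pairs: %s",
                 paste(tooSmall, collapse = ", ")), call. = FALSE)
  pairs$cell <- factor(paste0(pairs$sex, pairs$group_index),
                       levels = sort(unique(paste0(pairs$sex,
                                                   pairs$group_index))))
  fit <- lm(post_z ~ 0 + cell + pre_z, data = pairs)
  cf <- coef(fit)
  cellNames <- levels(pairs$cell)
  est <- cf[paste0("cell", cellNames)]
  ci <- confint(fit, paste0("cell", cellNames), level = level)

  fam <- prePostFamily(data.frame(
    sex = substr(cellNames, 1, 1),
    group_index = as.integer(substr(cellNames, 2, 2))))
  K <- matrix(0, length(fam), length(cf),
              dimnames = list(vapply(fam, paste, character(1),
                                     collapse = " - "), names(cf)))
  for (i in seq_along(fam)) {
    K[i, paste0("cell", fam[[i]][1])] <- 1
    K[i, paste0("cell", fam[[i]][2])] <- -1
  }
  set.seed(1L)  # pin the quasi-MC integration inside the single-step test
  gl <- multcomp::glht(fit, linfct = K)
  sm <- summary(gl, test = multcomp::adjusted("single-step"))
  comparisons <- data.frame(
    contrast = rownames(K),
    estimate = as.numeric(sm$test$coefficients),
    t = as.numeric(sm$test$tstat),
    p_adjusted = as.numeric(sm$test$pvalues),
    stringsAsFactors = FALSE
  )

  sig <- comparisons$p_adjusted < 0.05
  estimates <- data.frame(
    sex = substr(cellNames, 1, 1),
    group_index = as.integer(substr(cellNames, 2, 2)),
    n = as.integer(counts[cellNames]),
    estimate = unname(est), lower = ci[, 1], upper = ci[, 2],
    stringsAsFactors = FALSE
  )
  # letters per sex family (groups within sex)
  estimates$letters_sex <- NA_character_
  for (sx in unique(estimates$sex)) {
    items <- cellNames[substr(cellNames, 1, 1) == sx]
    inFam <- vapply(fam, function(p) all(substr(p, 1, 1) == sx), TRUE)
    sigPairs <- fam[inFam & sig]
    estimates$letters_sex[estimates$sex == sx] <-
      cldInsertAbsorb(items, sigPairs)
  }
  # digits per group family (sexes within group)
  estimates$letters_group <- NA_character_
  for (gr in unique(estimates$group_index)) {
    items <- cellNames[substr(cellNames, 2, 2) == as.character(gr)]
    inFam <- vapply(fam, function(p)
      length(unique(substr(p, 1, 1))) == 2 &&
        all(substr(p, 2, 2) == as.character(gr)), TRUE)
    sigPairs <- fam[inFam & sig]
    codes <- cldInsertAbsorb(items, sigPairs)
    codes <- chartr("abcdefgh", "12345678", codes)
    estimates$letters_group[estimates$group_index == gr] <- codes
  }
  rownames(estimates) <- NULL
  list(fit = fit, estimates = estimates, comparisons = comparisons)
}

#' Monte-Carlo single-step max-|t| adjusted p-values
#'
#' Independent oracle for Tukey-type single-step adjustment: simulates the
#' joint null distribution of the contrast t-statistics from the fitted
#' model's multivariate t and returns, per contrast, the probability that
#' the maximal absolute statistic exceeds the observed one.
#'
#' @param fit An lm.
#' @param K Contrast matrix on the coefficient scale.
#' @param nSim Number of Monte-Carlo draws.
#' @param seed Seed for the simulation.
#' @return Numeric vector of adjusted p-values.
#' @export
maxTAdjustedPMC <- function(fit, K, nSim = 200000, seed = 1) {
  set.seed(seed)
  V <- K %*% vcov(fit) %*% t(K)
  R <- stats::cov2cor(V)
  df <- fit$df.residual
  tObs <- as.numeric(K %*% coef(fit)) / sqrt(diag(V))
  draws <- mvtnorm::rmvt(nSim, sigma = R, df = df)
  maxAbs <- apply(abs(draws), 1, max)
  vapply(abs(tObs), function(t0) mean(maxAbs >= t0), numeric(1))
}
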