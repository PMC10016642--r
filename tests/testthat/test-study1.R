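# Study 1: quartile groups, subset construction, trajectories, pre/post
# model and the single-step multiplicity adjustment.

test_that("neuter quartiles follow the type-7 convention and group labels", {
  q <- computeNeuterQuartiles(list(M = 1:8, F = 1:8))
  # independent oracle: hand-computed type-7 quartiles of 1..8
  expect_equal(attr(q, "quartiles")$M, c(2.75, 4.5, 6.25))
  expect_equal(q$lower_age_years[q$sex == "M"], c(0, 2.75, 4.5, 6.25))
  expect_true(is.infinite(q$upper_age_years[q$group_index == 4][1]))
  expect_error(computeNeuterQuartiles(list(M = rep(2, 10))), "degenerate")
  expect_error(computeNeuterQuartiles(list(M = c(1, 2))), ">= 4")

  # published-style male quartiles reproduce the week-scale group labels
  wk <- yearsToWeeks(c(0.39, 0.44, 0.54))
  expect_equal(round(wk), c(20, 23, 28))
})

test_that("subset construction keeps intact data shared, post-window rows private", {
  v <- rbind(
    makeVisits("intact1", c(10, 15), c(1.2, 1.6), sex = "M"),
    makeVisits("grp2cat", c(10, 25, 60), c(1.2, 2.5, 4.0), sex = "M"),
    makeVisits("grp4cat", c(10, 40, 70), c(1.2, 3.2, 4.3), sex = "M")
  )
  v$row_id <- seq_len(nrow(v))
  p <- makeProfiles(v, neuter_age_weeks = c(NA, 22, 40))
  specs <- data.frame(sex = "M", group_index = 1:4,
                      lower_age_years = weeksToYears(c(0, 20, 24, 30)),
                      upper_age_years = c(weeksToYears(c(20, 24, 30)), Inf))
  subs <- suppressWarnings(buildNeuterSubsets(v, p, specs))

  # the intact cat's early rows appear in every subset with a positive
  # lower bound; group 1 (bound 0) holds only its own neutered cats
  for (g in 2:4)
    expect_true(all(c(1, 2) %in% subs[[paste0("M", g)]]$row_id))
  expect_equal(nrow(subs$M1), 0)
  # the cat neutered in window 2: post-lower-bound rows only in subset 2
  expect_true(all(c(4, 5) %in% subs$M2$row_id))
  expect_false(any(c(4, 5) %in% subs$M3$row_id))
  expect_false(any(c(4, 5) %in% subs$M4$row_id))

  # conservation: every row appears in at least one subset of its sex
  all_ids <- sort(unique(unlist(lapply(subs, function(s) s$row_id))))
  expect_equal(all_ids, v$row_id)
  # post-window rows appear in exactly one subset
  counts <- table(unlist(lapply(subs, function(s) s$row_id)))
  expect_equal(as.integer(counts[c("4", "5")]), c(1L, 1L))
})

test_that("pre/post pair selection respects the 13-week gap", {
  gs <- defaultGrowthStandard("F")
  v <- rbind(
    makeVisits("ok", c(18, 40), c(1.8, 3.2)),
    makeVisits("short", c(18, 26), c(1.8, 2.6)),
    makeVisits("intact", c(18, 40), c(1.8, 3.2))
  )
  v$row_id <- seq_len(nrow(v))
  p <- makeProfiles(v, neuter_age_weeks = c(20, 20, NA))
  specs <- computeNeuterQuartiles(list(F = c(0.3, 0.38, 0.42, 0.5)))
  vz <- toZScores(gs, v)
  pairs <- selectPrePostPairs(vz, p, specs)
  expect_equal(pairs$cat_id, "ok")
  expect_equal(pairs$gap_weeks, 22)
})

test_that("pre/post model recovers noise-free cell shifts exactly", {
  set.seed(42)
  delta <- c(F1 = 1.0, F2 = 0.8, F3 = 0.5, F4 = 0.2,
             M1 = 0.4, M2 = 0.3, M3 = 0.2, M4 = 0.1)
  cells <- expand.grid(sex = c("F", "M"), group_index = 1:4,
                       rep = 1:30, stringsAsFactors = FALSE)
  cells$pre_z <- rnorm(nrow(cells))
  key <- paste0(cells$sex, cells$group_index)
  cells$post_z <- cells$pre_z + delta[key]
  fit <- prePostModel(cells)
  est <- fit$estimates
  expect_equal(est$estimate, unname(delta[paste0(est$sex, est$group_index)]),
               tolerance = 1e-10)
  expect_lt(max(est$upper - est$lower), 1e-6)
  expect_error(prePostModel(cells[key %in% "F1" | cells$rep == 1, ]),
               "< 2 pairs")
})

test_that("single-step adjusted p-values match a Monte-Carlo max-|t| oracle", {
  set.seed(13)
  pairs <- data.frame(
    sex = rep("F", 120), group_index = rep(1:4, each = 30),
    pre_z = rnorm(120)
  )
  pairs$post_z <- pairs$pre_z +
    c(0, 0.25, 0.4, 0.6)[pairs$group_index] + rnorm(120, 0, 0.5)
  fit <- prePostModel(pairs)
  K <- matrix(0, nrow(fit$comparisons), length(coef(fit$fit)),
              dimnames = list(fit$comparisons$contrast,
                              names(coef(fit$fit))))
  for (i in seq_len(nrow(fit$comparisons))) {
    cells <- strsplit(fit$comparisons$contrast[i], " - ")[[1]]
    K[i, paste0("cell", cells[1])] <- 1
    K[i, paste0("cell", cells[2])] <- -1
  }
  mc <- maxTAdjustedPMC(fit$fit, K, nSim = 200000, seed = 2)
  expect_lt(max(abs(mc - fit$comparisons$p_adjusted)), 0.01)
})

test_that("compact letters separate exactly the significant pairs", {
  items <- c("g1", "g2", "g3")
  # only g1 vs g3 differs
  cld <- kittengrowth:::cldInsertAbsorb(items, list(c("g1", "g3")))
  expect_equal(nchar(cld), c(1L, 2L, 1L))
  expect_false(any(strsplit(cld[1], "")[[1]] %in% strsplit(cld[3], "")[[1]]))
  expect_true(any(strsplit(cld[2], "")[[1]] %in% strsplit(cld[1], "")[[1]]))
  # nothing significant: everyone shares one letter
  expect_equal(kittengrowth:::cldInsertAbsorb(items, list()),
               c("a", "a", "a"))
  # everything significant: all letters distinct
  cld3 <- kittengrowth:::cldInsertAbsorb(items,
                                         list(c("g1", "g2"), c("g1", "g3"),
                                              c("g2", "g3")))
  expect_equal(anyDuplicated(cld3), 0)
})

test_that("trajectories from standard-following data stay near z = 0", {
  gs <- defaultGrowthStandard("F")
  d <- sampleFromStandard(gs, 8000, seed = 15)
  d$sex <- "F"
  d$cat_id <- sprintf("c%d", seq_len(nrow(d)))
  tj <- medianTrajectoryZ(d, gs)
  idx <- tj@ageGridWeeks >= 8 & tj@ageGridWeeks <= 90
  expect_lt(max(abs(tj@zMedian[idx])), 0.1)
  expect_true(all(tj@zQ25 <= tj@zMedian + 1e-8))
  expect_true(all(tj@zMedian <= tj@zQ75 + 1e-8))
})

test_that("upward inclination is zero for flat trajectories and checks its grid", {
  flat <- new("ZTrajectory", sex = "F", groupIndex = 1L,
              lowerAgeYears = 0, upperAgeYears = 0.4,
              medianNeuterAgeWeeks = 20,
              ageGridWeeks = seq(5, 90, by = 5),
              zMedian = rep(0.3, 18), zQ25 = rep(0, 18),
              zQ75 = rep(0.6, 18), nCats = 10L, nRows = 50L)
  expect_equal(upwardInclination(flat, 78), 0)
  expect_equal(upwardInclination(flat, 78, from = "zero"), 0.3)
  expect_error(upwardInclination(flat, 200), "outside")
})
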