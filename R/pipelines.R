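# End-to-end orchestration of the two studies, chart rendering and run
# manifests. Charts are best-effort artifacts; all downstream consumption
# is of the CSV/JSON outputs.

configHash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

writeManifest <- function(manifest, outDir) {
  if (is.null(outDir)) return(invisible(NULL))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}

#' Run the full clinic-growth (Study 1) pipeline
#'
#' Composition: BCS carry-over, eligibility filter, pound-rounding removal,
#' neuter-age quartile groups, the per-subset cleaning cascade (extreme
#' outliers, population outliers, duplicates, within-cat cleaning), per
#' subset a BCCG trajectory model expressed as z-scores of the reference
#' standard with its upward inclination, and the pre/post-neutering linear
#' model with single-step multiplicity adjustment.
#'
#' @param visits,profiles Clinic tables ([readVisits()] or
#'   [simulateClinic()]).
#' @param standards Named list of reference [GrowthStandard-class] objects
#'   (\code{M}, \code{F}).
#' @param config An [analysisConfig()].
#' @param outDir Optional directory for CSV outputs and the run manifest.
#' @param fitTrajectories Set FALSE to skip the per-subset BCCG fits (the
#'   pre/post analysis does not need them).
#' @return List: \code{subsets} (cleaned), \code{reports},
#'   \code{trajectories} ([ZTrajectory-class] per subset),
#'   \code{inclinations}, \code{pairs}, \code{prepost}, \code{specs},
#'   \code{manifest}.
#' @export
runStudy1Pipeline <- function(visits, profiles, standards,
                              config = analysisConfig(), outDir = NULL,
                              fitTrajectories = TRUE) {
  cl <- config$cleaning
  visits <- ensureRowIds(visits)
  visits <- carryOverBCS(visits, tolerance = cl$bcs_carry_tolerance)
  elig <- eligibilityFilter(visits, profiles, config)
  pounds <- removeRoundedPounds(elig$visits, epsilonLb = cl$pound_epsilon_lb)

  specs <- computeNeuterQuartiles(profiles)
  subsets <- buildNeuterSubsets(pounds$visits, profiles, specs)

  reports <- list(pre_subset = bindCleaningReports(elig, pounds))
  cleaned <- list(); trajectories <- list(); inclin <- list()
  for (nm in names(subsets)) {
    s1 <- removeExtremeOutliers(subsets[[nm]],
                                multiplier = cl$extreme_outlier_multiplier,
                                minAgeWeeks = cl$extreme_outlier_min_age_weeks)
    s2 <- populationOutlierFilter(s1$visits, nBins = cl$n_bins,
                                  expansion = cl$whisker_expansion,
                                  span = cl$loess_span)
    s3 <- removeDuplicates(s2$visits)
    s4 <- withinCatCleaning(s3$visits, tolerance = cl$within_cat_tolerance,
                            maxFrac = cl$within_cat_max_frac,
                            maxSpanWeeks = cl$within_cat_max_span_weeks)
    sub <- s4$visits
    for (a in c("spec", "neuter_ages_weeks"))
      attr(sub, a) <- attr(subsets[[nm]], a)
    cleaned[[nm]] <- sub
    reports[[nm]] <- bindCleaningReports(s1, s2, s3, s4)
    if (fitTrajectories) {
      sex <- substr(nm, 1, 1)
      tr <- medianTrajectoryZ(sub, standards[[sex]])
      trajectories[[nm]] <- tr
      inclin[[nm]] <- data.frame(
        subset = nm, sex = sex,
        group_index = tr@groupIndex,
        median_neuter_age_weeks = tr@medianNeuterAgeWeeks,
        delta_z = upwardInclination(tr, config$study1$end_of_growth_weeks),
        stringsAsFactors = FALSE)
    }
  }
  inclinations <- if (length(inclin)) do.call(rbind, inclin) else NULL
  if (!is.null(inclinations)) rownames(inclinations) <- NULL

  # pre/post analysis on the union of the cleaned subsets
  pooled <- do.call(rbind, cleaned)
  pooled <- pooled[!duplicated(pooled$row_id), , drop = FALSE]
  prepost <- NULL; pairs <- NULL
  zBySex <- do.call(rbind, lapply(c("M", "F"), function(sx) {
    sub <- pooled[pooled$sex == sx, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    toZScores(standards[[sx]], sub)
  }))
  pairs <- selectPrePostPairs(zBySex, profiles, specs,
                              minGapWeeks = config$study1$min_prepost_gap_weeks)
  if (nrow(pairs) && all(table(paste0(pairs$sex, pairs$group_index)) >= 2))
    prepost <- prePostModel(pairs)

  manifest <- list(subcommand = "study1", seed = config$seed,
                   config_hash = configHash(config),
                   rows_in = nrow(visits),
                   rows_final = nrow(pooled),
                   n_pairs = nrow(pairs),
                   outputs = character())
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (length(trajectories)) {
      tt <- do.call(rbind, lapply(trajectories, trajectoryTable))
      write.csv(tt, file.path(outDir, "trajectories.csv"), row.names = FALSE)
      write.csv(inclinations, file.path(outDir, "inclinations.csv"),
                row.names = FALSE)
    }
    if (!is.null(prepost)) {
      write.csv(prepost$estimates, file.path(outDir, "prepost_estimates.csv"),
                row.names = FALSE)
      write.csv(prepost$comparisons,
                file.path(outDir, "prepost_comparisons.csv"),
                row.names = FALSE)
    }
    allReports <- do.call(rbind, lapply(names(reports), function(nm) {
      r <- reports[[nm]]; r$subset <- nm; r
    }))
    write.csv(allReports, file.path(outDir, "cleaning_report.csv"),
              row.names = FALSE)
    manifest$outputs <- list.files(outDir)
    writeManifest(manifest, outDir)
  }
  list(subsets = cleaned, reports = reports, trajectories = trajectories,
       inclinations = inclinations, pairs = pairs, prepost = prepost,
       specs = specs, manifest = manifest)
}

#' Run the full littermate-trial (Study 2) pipeline
#'
#' Composition: successive-drop cleaning for the monotone-expected
#' zoometric measures, log-standardization, the Bayesian multivariate
#' mixed model, fold-change summaries with simultaneous intervals, and
#' posterior predictive density data.
#'
#' @param observations Trial observations ([readTrialObservations()] or
#'   [simulateTrial()]).
#' @param config An [analysisConfig()]; \code{config$mcmc} is the sampler
#'   schedule and \code{config$seed} the seed.
#' @param outDir Optional directory for CSV outputs and the run manifest.
#' @param ppcDraws Posterior draws for the predictive check (default 40).
#' @param failOnDiagnostics Passed to [fitMVMM()].
#' @return List: \code{cleaning}, \code{panel}, \code{posterior},
#'   \code{foldChanges}, \code{ppc}, \code{manifest}.
#' @export
runStudy2Pipeline <- function(observations, config = analysisConfig(),
                              outDir = NULL, ppcDraws = 40,
                              failOnDiagnostics = TRUE) {
  cleaned <- trialDropCleaning(observations,
                               threshold = config$cleaning$trial_drop_threshold)
  panel <- standardizeMeasures(cleaned$observations)
  posterior <- fitMVMM(panel, priors = config$priors,
                       schedule = config$mcmc, seed = config$seed,
                       failOnDiagnostics = failOnDiagnostics)
  fc <- foldChangeSummaries(posterior,
                            baselineWeek = config$study2$baseline_week)
  ppc <- posteriorPredictiveCheck(posterior, panel, nDraws = ppcDraws)

  manifest <- list(subcommand = "study2", seed = config$seed,
                   config_hash = configHash(config),
                   rows_in = nrow(observations),
                   rows_after_cleaning = nrow(cleaned$observations),
                   retained_draws = nDraws(posterior),
                   outputs = character())
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(fc$ratios, file.path(outDir, "fold_change_ratios.csv"),
              row.names = FALSE)
    write.csv(fc$folds, file.path(outDir, "fold_changes.csv"),
              row.names = FALSE)
    write.csv(posterior@diagnostics, file.path(outDir, "diagnostics.csv"),
              row.names = FALSE)
    write.csv(ppc, file.path(outDir, "ppc_density.csv"), row.names = FALSE)
    write.csv(cleaned$report, file.path(outDir, "cleaning_report.csv"),
              row.names = FALSE)
    manifest$outputs <- list.files(outDir)
    writeManifest(manifest, outDir)
  }
  list(cleaning = cleaned, panel = panel, posterior = posterior,
       foldChanges = fc, ppc = ppc, manifest = manifest)
}

#' Render the standard chart set
#'
#' z-scale trajectory plots with horizontal centile gridlines and
#' neuter-window shading, kg-scale equivalents against the reference
#' centiles, the pre/post estimate dot plot, and the fold-change-ratio
#' interval plot with its reference line at 1. Failures are logged, not
#' raised.
#'
#' @param study1 Output of [runStudy1Pipeline()] (or NULL).
#' @param study2 Output of [runStudy2Pipeline()] (or NULL).
#' @param standards Named list of reference standards (for kg-scale plots).
#' @param outDir Directory for the PDF files.
#' @return Character vector of files written, invisibly.
#' @export
renderCharts <- function(study1 = NULL, study2 = NULL, standards = NULL,
                         outDir = ".") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  save <- function(plot, name, w = 8, h = 5) {
    f <- file.path(outDir, name)
    ok <- tryCatch({
      ggplot2::ggsave(f, plot, width = w, height = h)
      TRUE
    }, error = function(e) {
      message("renderCharts: skipped ", name, ": ", conditionMessage(e))
      FALSE
    })
    if (ok) written <<- c(written, f)
  }
  zGrid <- qnorm(c(0.02, 0.09, 0.25, 0.5, 0.75, 0.91, 0.98))

  if (!is.null(study1) && length(study1$trajectories)) {
    tt <- do.call(rbind, lapply(study1$trajectories, trajectoryTable))
    shades <- do.call(rbind, lapply(study1$trajectories, function(tr)
      data.frame(sex = tr@sex, group_index = tr@groupIndex,
                 lo = yearsToWeeks(tr@lowerAgeYears),
                 hi = min(yearsToWeeks(tr@upperAgeYears),
                          max(tr@ageGridWeeks)),
                 med = tr@medianNeuterAgeWeeks)))
    p <- ggplot2::ggplot(tt, ggplot2::aes(x = age_weeks)) +
      ggplot2::geom_hline(yintercept = zGrid, colour = "grey80",
                          linewidth = 0.3) +
      ggplot2::geom_rect(data = shades,
                         ggplot2::aes(xmin = lo, xmax = hi,
                                      ymin = -Inf, ymax = Inf),
                         inherit.aes = FALSE, fill = "grey70", alpha = 0.3) +
      ggplot2::geom_vline(data = shades, ggplot2::aes(xintercept = med),
                          colour = "grey40") +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = z_q25, ymax = z_q75),
                           fill = "steelblue", alpha = 0.3) +
      ggplot2::geom_line(ggplot2::aes(y = z_median), colour = "steelblue") +
      ggplot2::facet_grid(sex ~ group_index) +
      ggplot2::labs(x = "Age (weeks)", y = "z-score vs growth standard")
    save(p, "trajectories_z.pdf", w = 10, h = 5)

    if (!is.null(standards)) {
      cent <- do.call(rbind, lapply(names(standards), function(sx) {
        cc <- extractCentiles(standards[[sx]],
                              probs = c(0.02, 0.09, 0.25, 0.5, 0.75,
                                        0.91, 0.98))
        cc$sex <- sx; cc
      }))
      ttw <- tt
      for (sx in unique(ttw$sex)) {
        idx <- ttw$sex == sx
        lms <- lmsAt(standards[[sx]], ttw$age_weeks[idx], extrapolate = TRUE)
        ttw$weight[idx] <- bccgCentile(pnorm(pmin(pmax(ttw$z_median[idx],
                                                       -3), 3)),
                                       lms$M, lms$S, lms$L)
      }
      p2 <- ggplot2::ggplot(ttw, ggplot2::aes(age_weeks, weight)) +
        ggplot2::geom_line(data = cent,
                           ggplot2::aes(age_weeks, weight_kg, group = p),
                           linetype = "dashed", colour = "grey60") +
        ggplot2::geom_line(colour = "steelblue") +
        ggplot2::facet_grid(sex ~ group_index) +
        ggplot2::labs(x = "Age (weeks)", y = "Bodyweight (kg)")
      save(p2, "trajectories_kg.pdf", w = 10, h = 5)
    }
  }
  if (!is.null(study1) && !is.null(study1$prepost)) {
    est <- study1$prepost$estimates
    est$label <- paste0(est$letters_sex, est$letters_group)
    p3 <- ggplot2::ggplot(est, ggplot2::aes(factor(group_index), estimate,
                                            colour = sex)) +
      ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = lower, ymax = upper),
                               position = ggplot2::position_dodge(0.4)) +
      ggplot2::geom_text(ggplot2::aes(label = label), vjust = -1,
                         position = ggplot2::position_dodge(0.4),
                         show.legend = FALSE) +
      ggplot2::labs(x = "Neuter group", y = "Estimated change in z-score")
    save(p3, "prepost_estimates.pdf")
  }
  if (!is.null(study2)) {
    r <- study2$foldChanges$ratios
    r <- r[r$week != study2$foldChanges$baseline_week, ]
    p4 <- ggplot2::ggplot(r, ggplot2::aes(week, mean)) +
      ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = sim_lower,
                                            ymax = sim_upper)) +
      ggplot2::facet_wrap(~measure, scales = "free_y") +
      ggplot2::labs(x = "Week", y = "Fold-change ratio (neutered / intact)")
    save(p4, "fold_change_ratios.pdf", w = 10, h = 7)

    f <- study2$foldChanges$folds
    comp <- f[f$measure %in% c("fat_mass", "lean_mass"), ]
    p5 <- ggplot2::ggplot(comp, ggplot2::aes(factor(week), mean,
                                             fill = measure)) +
      ggplot2::geom_col(position = "stack") +
      ggplot2::facet_wrap(~group) +
      ggplot2::labs(x = "Week", y = "Fold change from baseline")
    save(p5, "body_composition.pdf")
  }
  invisible(written)
}

utils::globalVariables(c("age_weeks", "z_q25", "z_q75", "z_median", "lo",
                         "hi", "med", "weight_kg", "weight", "group_index",
                         "estimate", "lower", "upper", "label", "week",
                         "sim_lower", "sim_upper", "measure"))
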