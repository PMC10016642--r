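# The record-cleaning cascade: every eligibility filter and cleaning rule of
# both studies as composable, auditable pure filters. Each stage returns the
# filtered table plus a one-row CleaningReport; removed row ids are carried
# as an attribute so a pipeline's reports reconcile exactly.

ensureRowIds <- function(visits) {
  if (!"row_id" %in% names(visits)) visits$row_id <- seq_len(nrow(visits))
  visits
}

newCleaningReport <- function(stage, before, after) {
  rep <- data.frame(
    stage = stage,
    rows_in = nrow(before), rows_out = nrow(after),
    cats_in = length(unique(before$cat_id)),
    cats_out = length(unique(after$cat_id)),
    stringsAsFactors = FALSE
  )
  attr(rep, "removed_row_ids") <- setdiff(before$row_id, after$row_id)
  rep
}

#' Bind stage reports into a cascade table
#'
#' @param ... One-row cleaning reports (or lists with a \code{report}
#'   element) in pipeline order.
#' @return data.frame mirroring a per-stage cleaning table; removed ids are
#'   kept in the \code{"removed_row_ids"} attribute as a list.
#' @export
bindCleaningReports <- function(...) {
  reps <- lapply(list(...), function(x) if (is.data.frame(x)) x else x$report)
  out <- do.call(rbind, reps)
  attr(out, "removed_row_ids") <- lapply(reps, attr, "removed_row_ids")
  out
}

#' Study 1 eligibility filter
#'
#' Applies the clinic-record eligibility rules: keeps only preventative or
#' healthy-diagnosis visits, drops rolled-over and in-carrier weighings,
#' then drops whole cats that (a) have a recorded-sex/procedure conflict
#' (when the profiles carry a \code{procedure} column), (b) acquired an
#' exclusion diagnosis before 208 weeks (4 years) of age, (c) lack a
#' "normal" body-condition rating at 78-130 weeks, (d) ever received an
#' abnormal (thin/heavy) rating up to 208 weeks, or (e) retain no
#' bodyweight in the 5-91 week window. Body-condition criteria are
#' assessed over all parsed visits; the weight-window criterion over the
#' rows remaining after the row-level drops.
#'
#' @param visits Visits data.frame (see [readVisits()]).
#' @param profiles Per-cat profiles; every visit's cat must be present.
#' @param config An [analysisConfig()] list.
#' @return List with \code{visits} and a one-row \code{report}.
#' @export
eligibilityFilter <- function(visits, profiles, config = analysisConfig()) {
  visits <- ensureRowIds(visits)
  orphan <- setdiff(visits$cat_id, profiles$cat_id)
  if (length(orphan))
    stop(sprintf("eligibilityFilter: %d cat id(s) in visits missing from profiles (e.g. %s)",
                 length(orphan), orphan[1]), call. = FALSE)
  el <- config$eligibility

  keepRow <- visits$visit_category %in% c("preventative", "healthy_diagnosis") &
    !visits$rolled_over & !visits$in_carrier

  badCats <- character(0)
  if ("procedure" %in% names(profiles)) {
    conflict <- (profiles$sex == "M" & profiles$procedure %in% "ovariohysterectomy") |
      (profiles$sex == "F" & profiles$procedure %in% "castration")
    badCats <- c(badCats, profiles$cat_id[conflict %in% TRUE])
  }
  if ("first_exclusion_date" %in% names(profiles)) {
    exclAge <- as.numeric(profiles$first_exclusion_date - profiles$birth_date) /
      DAYS_PER_WEEK
    badCats <- c(badCats,
                 profiles$cat_id[!is.na(exclAge) &
                                   exclAge < el$exclusion_horizon_weeks])
  }
  bcsWin <- el$bcs_normal_window_weeks
  normalOK <- tapply(
    visits$bcs_category == "normal" &
      visits$age_weeks >= bcsWin[1] & visits$age_weeks <= bcsWin[2],
    visits$cat_id, any)
  badCats <- c(badCats, names(normalOK)[!normalOK])
  abnormal <- tapply(
    visits$bcs_category %in% c("thin", "heavy") &
      visits$age_weeks <= el$bcs_abnormal_horizon_weeks,
    visits$cat_id, any)
  badCats <- c(badCats, names(abnormal)[abnormal])

  out <- visits[keepRow & !visits$cat_id %in% badCats, , drop = FALSE]
  wWin <- el$weight_window_weeks
  hasW <- tapply(out$age_weeks >= wWin[1] & out$age_weeks <= wWin[2],
                 out$cat_id, any)
  out <- out[out$cat_id %in% names(hasW)[hasW], , drop = FALSE]
  list(visits = out, report = newCleaningReport("eligibility", visits, out))
}

#' Carry over body-condition scores between close-in-weight visits
#'
#' An unknown BCS is replaced by the BCS of the nearest-in-time visit of
#' the same cat (previous or subsequent) whose bodyweight lies within a
#' tolerance (default +/-5\%) of the current visit's weight. Ties between
#' equidistant qualifying neighbours are broken towards the earlier visit.
#' Only the BCS field is filled; no rows are added or removed.
#'
#' @param visits Visits data.frame.
#' @param tolerance Relative weight tolerance (default 0.05).
#' @return The visits data.frame with imputed \code{bcs_category}.
#' @export
carryOverBCS <- function(visits, tolerance = 0.05) {
  visits <- ensureRowIds(visits)
  ord <- order(visits$cat_id, visits$visit_date)
  idx <- split(ord, visits$cat_id[ord])
  for (rows in idx) {
    unknown <- rows[visits$bcs_category[rows] == "unknown"]
    known <- rows[visits$bcs_category[rows] != "unknown"]
    if (!length(unknown) || !length(known)) next
    for (i in unknown) {
      w <- visits$bodyweight_kg[i]
      cand <- known[abs(visits$bodyweight_kg[known] - w) / w <= tolerance]
      if (!length(cand)) next
      dt <- abs(as.numeric(visits$visit_date[cand] - visits$visit_date[i]))
      best <- cand[order(dt, visits$visit_date[cand], cand)][1]
      visits$bcs_category[i] <- visits$bcs_category[best]
    }
  }
  visits
}

#' Remove weights rounded to whole pounds
#'
#' Flags the whole-pound signature: a kg weight whose pound equivalent
#' (1 kg = 2.2046226218 lb) lies within \code{epsilonLb} of an integer.
#'
#' @param visits Visits data.frame.
#' @param epsilonLb Detection tolerance in pounds (default 0.005; 0 removes
#'   only exactly integral pounds).
#' @return List with \code{visits} and \code{report}.
#' @export
removeRoundedPounds <- function(visits, epsilonLb = 0.005) {
  visits <- ensureRowIds(visits)
  lb <- visits$bodyweight_kg * LB_PER_KG
  rounded <- abs(lb - round(lb)) <= epsilonLb
  out <- visits[!rounded, , drop = FALSE]
  list(visits = out, report = newCleaningReport("pound_rounding", visits, out))
}

#' Remove extreme bodyweight outliers
#'
#' Computes the median bodyweight over all visits of cats older than 9
#' months (365.25/12*9/7 = 39.13 weeks) and removes any visit, at any age,
#' whose weight exceeds \code{multiplier} times that median.
#'
#' @param visits Visits data.frame.
#' @param multiplier Threshold multiple of the adult median (default 3).
#' @param minAgeWeeks Age floor defining the adult median (default 9
#'   months in weeks).
#' @return List with \code{visits} and \code{report}.
#' @export
removeExtremeOutliers <- function(visits, multiplier = 3,
                                  minAgeWeeks = 365.25 / 12 * 9 / 7) {
  visits <- ensureRowIds(visits)
  adult <- visits$bodyweight_kg[visits$age_weeks > minAgeWeeks]
  if (!length(adult)) {
    warning("removeExtremeOutliers: no visits over 9 months; stage skipped")
    return(list(visits = visits,
                report = newCleaningReport("extreme_outliers", visits, visits)))
  }
  threshold <- multiplier * median(adult)
  out <- visits[visits$bodyweight_kg <= threshold, , drop = FALSE]
  rep <- newCleaningReport("extreme_outliers", visits, out)
  list(visits = out, report = rep, threshold_kg = threshold)
}

tukeyWhiskers <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lowFence <- q[1] - 1.5 * iqr
  highFence <- q[3] + 1.5 * iqr
  c(lower = min(x[x >= lowFence]), median = q[2],
    upper = max(x[x <= highFence]))
}

#' Population-level outlier filter
#'
#' Rows are sorted by age and split into \code{nBins} equal-count age
#' groups. Per bin, Tukey box-plot whiskers are computed and expanded by
#' \code{expansion} about the bin median (upper limit = median +
#' expansion * (upper whisker - median); lower limit analogously). Loess
#' curves (degree 1) are fitted through the (bin mid-age, limit) points,
#' separately for the upper and lower limits, and rows outside the
#' smoothed band are removed.
#'
#' @param visits Visits data.frame (needs at least \code{nBins} rows for
#'   the full bin count; fewer rows reduce the bin count with a warning).
#' @param nBins Number of equal-count age bins (default 50).
#' @param expansion Whisker expansion factor about the bin median
#'   (default 1.75).
#' @param span Loess span (default 0.5).
#' @return List with \code{visits}, \code{report} and \code{limits}
#'   (per-bin raw and smoothed limit curves).
#' @export
populationOutlierFilter <- function(visits, nBins = 50, expansion = 1.75,
                                    span = 0.5) {
  visits <- ensureRowIds(visits)
  n <- nrow(visits)
  nBinsEff <- nBins
  if (n < nBins) {
    nBinsEff <- max(1L, n %/% 4L)
    warning(sprintf("populationOutlierFilter: %d rows < %d bins; using %d bins",
                    n, nBins, nBinsEff))
  }
  ord <- order(visits$age_weeks)
  bin <- integer(n)
  bin[ord] <- ceiling(seq_len(n) / n * nBinsEff)
  mids <- tapply(visits$age_weeks, bin, median)
  wh <- tapply(visits$bodyweight_kg, bin, function(x) tukeyWhiskers(x))
  wh <- do.call(rbind, wh)
  upperLim <- wh[, "median"] + expansion * (wh[, "upper"] - wh[, "median"])
  lowerLim <- wh[, "median"] - expansion * (wh[, "median"] - wh[, "lower"])

  smoothLimit <- function(y, ages) {
    if (length(mids) >= 8) {
      fit <- loess(y ~ m, data.frame(m = as.numeric(mids), y = y),
                   span = span, degree = 1,
                   control = loess.control(surface = "direct"))
      predict(fit, data.frame(m = ages))
    } else {
      approx(as.numeric(mids), y, xout = ages, rule = 2)$y
    }
  }
  up <- smoothLimit(upperLim, visits$age_weeks)
  lo <- smoothLimit(lowerLim, visits$age_weeks)
  keep <- visits$bodyweight_kg <= up + 1e-12 & visits$bodyweight_kg >= lo - 1e-12
  out <- visits[keep, , drop = FALSE]
  limits <- data.frame(bin = as.integer(rownames(wh)),
                       mid_age_weeks = as.numeric(mids),
                       lower_whisker = wh[, "lower"],
                       median = wh[, "median"],
                       upper_whisker = wh[, "upper"],
                       lower_limit = lowerLim, upper_limit = upperLim)
  list(visits = out,
       report = newCleaningReport("population_outliers", visits, out),
       limits = limits)
}

#' Remove duplicate observations
#'
#' For identical (cat, visit date) one row is retained: exact duplicates
#' collapse silently; conflicting duplicates (same cat/date, different
#' weight) keep the first row in file order and are logged via a message.
#'
#' @param visits Visits data.frame.
#' @return List with \code{visits} and \code{report}.
#' @export
removeDuplicates <- function(visits) {
  visits <- ensureRowIds(visits)
  key <- paste(visits$cat_id, visits$visit_date)
  dup <- duplicated(key)
  if (any(dup)) {
    conflicts <- tapply(visits$bodyweight_kg, key,
                        function(w) length(unique(w)) > 1)
    nConf <- sum(conflicts)
    if (nConf)
      message(sprintf("removeDuplicates: %d cat/date key(s) with conflicting weights; keeping first by file order",
                      nConf))
  }
  out <- visits[!dup, , drop = FALSE]
  list(visits = out, report = newCleaningReport("duplicates", visits, out))
}

#' Within-cat trajectory plausibility cleaning
#'
#' For each cat with at least 3 remaining visits, iteratively removes the
#' interior visit whose log-weight deviates most from the value linearly
#' interpolated (log-weight versus age) between its neighbours, while that
#' relative deviation exceeds \code{tolerance}; at most
#' \code{ceiling(maxFrac * visits)} of a cat's rows are removed. A point is
#' only judged when its bracketing neighbours span at most
#' \code{maxSpanWeeks}: growth is concave in log-weight, so a chord across
#' a long visit gap systematically under-predicts genuine mid-growth
#' weights and such points are treated as unjudgeable rather than
#' implausible. This stage is a reconstruction of
#' trajectory-implausibility cleaning: the rule, its threshold, its span
#' window and its cap are package choices.
#'
#' @param visits Visits data.frame.
#' @param tolerance Relative deviation triggering removal (default 0.25).
#' @param maxFrac Cap on the per-cat fraction removed (default 0.2).
#' @param maxSpanWeeks Maximum neighbour-to-neighbour age span within which
#'   a point is judged (default 20 weeks).
#' @return List with \code{visits} and \code{report}.
#' @export
withinCatCleaning <- function(visits, tolerance = 0.25, maxFrac = 0.2,
                              maxSpanWeeks = 20) {
  visits <- ensureRowIds(visits)
  drop <- logical(nrow(visits))
  for (rows in split(seq_len(nrow(visits)), visits$cat_id)) {
    rows <- rows[order(visits$age_weeks[rows])]
    if (length(rows) < 3) next
    cap <- ceiling(maxFrac * length(rows))
    active <- rows
    removed <- 0
    while (removed < cap && length(active) >= 3) {
      age <- visits$age_weeks[active]
      lw <- log(visits$bodyweight_kg[active])
      k <- length(active)
      i <- 2:(k - 1)
      predLw <- lw[i - 1] + (lw[i + 1] - lw[i - 1]) *
        (age[i] - age[i - 1]) / (age[i + 1] - age[i - 1])
      dev <- exp(abs(lw[i] - predLw)) - 1
      dev[age[i + 1] - age[i - 1] > maxSpanWeeks] <- 0
      if (max(dev) <= tolerance) break
      worst <- i[which.max(dev)]
      drop[active[worst]] <- TRUE
      active <- active[-worst]
      removed <- removed + 1
    }
  }
  out <- visits[!drop, , drop = FALSE]
  list(visits = out, report = newCleaningReport("within_cat", visits, out))
}

monotoneMeasures <- c("height", "chest_depth", "length", "elbow_width",
                      "forelimb", "hindlimb")

#' Trial successive-drop cleaning for monotone-expected measures
#'
#' For each cat and each measure expected to increase with growth (height,
#' chest depth, length, elbow width, forelimb, hindlimb), successive
#' timepoint pairs showing a drop greater than \code{threshold} are
#' identified; within each pair the point with the larger absolute z-score
#' (z over all cats for that measure at that timepoint) is removed. Mass
#' and girth measures are untouched by this rule. Ties go to the later
#' (dropped-to) point.
#'
#' @param observations Trial observation data.frame.
#' @param threshold Relative drop triggering the rule (default 0.10).
#' @return List with \code{observations} and \code{report} (reporting rows
#'   as observations, cats as cats).
#' @export
trialDropCleaning <- function(observations, threshold = 0.10) {
  obs <- observations
  obs$.row <- seq_len(nrow(obs))
  zOf <- function(measure, week, value) {
    peers <- obs$value[obs$measure == measure & obs$week == week &
                         !is.na(obs$value)]
    if (length(peers) < 2) return(NA_real_)
    (value - mean(peers)) / sd(peers)
  }
  drop <- logical(nrow(obs))
  for (m in intersect(monotoneMeasures, unique(obs$measure))) {
    sub <- obs[obs$measure == m & !is.na(obs$value), , drop = FALSE]
    for (rows in split(sub$.row, sub$cat_id)) {
      rows <- rows[order(obs$week[rows])]
      if (length(rows) < 2) next
      for (j in seq_len(length(rows) - 1)) {
        a <- rows[j]; b <- rows[j + 1]
        if (drop[a] || drop[b]) next
        relDrop <- (obs$value[a] - obs$value[b]) / obs$value[a]
        if (relDrop <= threshold) next
        za <- zOf(m, obs$week[a], obs$value[a])
        zb <- zOf(m, obs$week[b], obs$value[b])
        if (is.na(za) || is.na(zb)) {
          warning(sprintf("trialDropCleaning: <2 cats for %s at a timepoint; pair skipped", m))
          next
        }
        drop[if (abs(za) > abs(zb)) a else b] <- TRUE
      }
    }
  }
  out <- obs[!drop, setdiff(names(obs), ".row"), drop = FALSE]
  rep <- data.frame(stage = "trial_drop",
                    rows_in = nrow(obs), rows_out = nrow(out),
                    cats_in = length(unique(obs$cat_id)),
                    cats_out = length(unique(out$cat_id)),
                    stringsAsFactors = FALSE)
  attr(rep, "removed_row_ids") <- obs$.row[drop]
  list(observations = out, report = rep)
}
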