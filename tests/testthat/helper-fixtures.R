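# Small in-code fixture builders shared across tests.

makeVisits <- function(cat_id, age_weeks, bodyweight_kg,
                       sex = "F", bcs = "normal",
                       visit_category = "preventative",
                       birth_date = as.Date("2010-01-01"),
                       rolled_over = FALSE, in_carrier = FALSE) {
  n <- max(length(cat_id), length(age_weeks), length(bodyweight_kg))
  d <- data.frame(
    cat_id = rep_len(as.character(cat_id), n),
    sex = rep_len(sex, n),
    birth_date = rep_len(birth_date, n),
    age_weeks = rep_len(age_weeks, n),
    bodyweight_kg = rep_len(bodyweight_kg, n),
    visit_category = rep_len(visit_category, n),
    bcs_category = rep_len(bcs, n),
    rolled_over = rep_len(rolled_over, n),
    in_carrier = rep_len(in_carrier, n),
    stringsAsFactors = FALSE
  )
  d$visit_date <- d$birth_date + round(d$age_weeks * 7)
  d$row_id <- seq_len(n)
  d
}

makeProfiles <- function(visits, neuter_age_weeks = NA) {
  ids <- unique(visits$cat_id)
  p <- data.frame(
    cat_id = ids,
    sex = visits$sex[match(ids, visits$cat_id)],
    birth_date = visits$birth_date[match(ids, visits$cat_id)],
    stringsAsFactors = FALSE
  )
  naw <- rep_len(neuter_age_weeks, length(ids))
  p$neuter_date <- p$birth_date + round(naw * 7)
  p$neuter_age_years <- naw * 7 / 365.25
  p$first_exclusion_date <- as.Date(NA)
  p
}

# A flat-in-z clinic-like sample drawn exactly from a given standard
sampleFromStandard <- function(standard, n, seed, ages = NULL) {
  set.seed(seed)
  if (is.null(ages)) ages <- runif(n, 5, 110)
  lms <- lmsAt(standard, ages, extrapolate = TRUE)
  w <- bccgCentile(runif(n), lms$M, lms$S, lms$L)
  data.frame(age_weeks = ages, bodyweight_kg = w)
}

reducedSchedule <- function(chains = 2L, iterations = 400L,
                            warmup = 200L, thin = 1L) {
  list(chains = chains, iterations = iterations, warmup = warmup,
       thin = thin)
}
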