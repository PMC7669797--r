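#' Synthetic cohort generator configuration
#'
#' Defaults reproduce the statistical structure of a consecutive
#' designer-series of 1000 medial unicompartmental knee replacements:
#' age at surgery 66.6 (SD 9.6, range 33-88), 49% female, ~22% of patients
#' contributing both knees, recruitment spread over 10.75 years with a
#' minimum administrative follow-up of 5 years (so potential follow-up
#' averages ~10.3 years), a constant revision hazard of 0.0057 per
#' implant-year (which yields on the order of 50 revisions per cohort),
#' and a small non-informative withdrawal fraction.
#'
#' @param n_knees Number of knees (rows) to generate.
#' @param bilateral_fraction Proportion of patients contributing two knees.
#' @param age_mean,age_sd,age_bounds Truncated-normal age-at-surgery
#'   distribution (years).
#' @param female_fraction Proportion of patients who are female.
#' @param revision_hazard Constant revision hazard per implant-year.
#' @param recruitment_span Years over which surgery dates are uniform.
#' @param min_followup,max_followup Administrative follow-up bounds in
#'   years: a knee entering at time `e` has potential follow-up
#'   `min(recruitment_span - e + min_followup, max_followup)`.
#' @param withdrawal_fraction Proportion of knees withdrawn (non-informative
#'   censoring at a uniform time before the administrative horizon).
#' @param seed Integer seed; generation is reproducible given the seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_knees = 1000L,
                          bilateral_fraction = 0.22,
                          age_mean = 66.6, age_sd = 9.6,
                          age_bounds = c(33, 88),
                          female_fraction = 0.49,
                          revision_hazard = 0.0057,
                          recruitment_span = 10.75,
                          min_followup = 5, max_followup = 17,
                          withdrawal_fraction = 0.042,
                          seed = NULL) {
  cfg <- list(n_knees = as.integer(n_knees),
              bilateral_fraction = bilateral_fraction,
              age_mean = age_mean, age_sd = age_sd,
              age_bounds = as.numeric(age_bounds),
              female_fraction = female_fraction,
              revision_hazard = revision_hazard,
              recruitment_span = recruitment_span,
              min_followup = min_followup, max_followup = max_followup,
              withdrawal_fraction = withdrawal_fraction,
              seed = seed)
  if (cfg$n_knees < 1L) stop("`n_knees` must be >= 1")
  for (nm in c("bilateral_fraction", "female_fraction", "withdrawal_fraction")) {
    v <- cfg[[nm]]
    if (!is.finite(v) || v < 0 || v > 1) stop("`", nm, "` must be in [0, 1]")
  }
  if (!is.finite(cfg$revision_hazard) || cfg$revision_hazard < 0)
    stop("`revision_hazard` must be >= 0")
  if (cfg$age_sd <= 0) stop("`age_sd` must be > 0")
  if (length(cfg$age_bounds) != 2L || diff(cfg$age_bounds) <= 0)
    stop("`age_bounds` must be an increasing pair of ages")
  if (cfg$min_followup >= cfg$max_followup)
    stop("`min_followup` must be below `max_followup`")
  if (cfg$recruitment_span <= 0) stop("`recruitment_span` must be > 0")
  class(cfg) <- "cohort_config"
  cfg
}

# Truncated normal by rejection: exact on the bounded support, and cheap at
# these truncation points (< 1% mass outside the bounds).
.rr_rtruncnorm <- function(n, mean, sd, bounds) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= bounds[1] & x <= bounds[2]])
  }
  out[seq_len(n)]
}

# Years until death for individuals of (real) current age `age`, walking the
# life table one attained year at a time; deaths are uniform within their
# year. Only resolved out to `horizon` years; later deaths return Inf.
.rr_sample_death_times <- function(age, lt, horizon) {
  n <- length(age)
  max_lt <- max(lt$age)
  needed <- floor(max(age) + horizon)
  if (needed > max_lt)
    stop("life table ends at age ", max_lt, " but attained ages up to ",
         needed, " are possible; extend the table over ages ",
         max_lt + 1L, "-", needed)
  tdeath <- rep(Inf, n)
  for (j in 0:ceiling(horizon)) {
    alive <- is.infinite(tdeath)
    if (!any(alive)) break
    att <- pmin(floor(age[alive] + j), max_lt)
    q <- qx_at(lt, att)
    dies <- stats::runif(sum(alive)) < q
    idx <- which(alive)[dies]
    tdeath[idx] <- j + stats::runif(length(idx))
  }
  tdeath
}

#' Generate a synthetic cohort of knee replacements
#'
#' Each patient receives an age at surgery (truncated normal), a sex, an
#' entry time uniform over the recruitment span and a death time drawn from
#' the life table conditional on age; patients contribute one knee, or two
#' with probability `bilateral_fraction` (both knees share the patient's
#' age, sex, entry and death time but carry independent revision and
#' withdrawal processes). Per knee, a revision time is drawn exponential
#' with the configured hazard and a withdrawal time is drawn for the
#' configured fraction; the observed follow-up is the minimum of potential
#' administrative follow-up, revision, death and withdrawal, and the event
#' indicator is 1 exactly when revision comes first.
#'
#' @param config A [cohort_config()].
#' @param lt A [life_table()] covering all attainable ages during follow-up.
#' @return A data frame of class `revrisk_cohort` with one row per knee:
#'   `knee_id`, `patient_id`, `age_at_surgery`, `sex` (`"F"`/`"M"`),
#'   `followup_time`, `event`, `censor_reason` (`NA` for revised knees),
#'   and `potential_followup` (administrative horizon, kept for
#'   calibration reporting).
#' @export
generate_cohort <- function(config = cohort_config(), lt = makeham_life_table()) {
  stopifnot(inherits(config, "cohort_config"), inherits(lt, "life_table"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_knees

  # patients until the knee budget is filled
  n_pat_guess <- ceiling(n / (1 + config$bilateral_fraction) * 1.3) + 10L
  bilat <- stats::runif(n_pat_guess) < config$bilateral_fraction
  knees_per_pat <- ifelse(bilat, 2L, 1L)
  n_pat <- which(cumsum(knees_per_pat) >= n)[1]
  if (is.na(n_pat)) n_pat <- n_pat_guess  # extreme configs; pad below
  knees_per_pat <- knees_per_pat[seq_len(n_pat)]
  excess <- sum(knees_per_pat) - n
  if (excess > 0L) knees_per_pat[n_pat] <- knees_per_pat[n_pat] - excess

  age_pat <- .rr_rtruncnorm(n_pat, config$age_mean, config$age_sd, config$age_bounds)
  sex_pat <- ifelse(stats::runif(n_pat) < config$female_fraction, "F", "M")
  entry_pat <- stats::runif(n_pat, 0, config$recruitment_span)
  horizon <- config$recruitment_span + config$min_followup
  tdeath_pat <- .rr_sample_death_times(age_pat, lt, horizon)

  pid <- rep(seq_len(n_pat), times = knees_per_pat)
  age <- age_pat[pid]
  sex <- sex_pat[pid]
  entry <- entry_pat[pid]
  tdeath <- tdeath_pat[pid]

  potential <- pmin(config$recruitment_span - entry + config$min_followup,
                    config$max_followup)
  trev <- if (config$revision_hazard > 0)
    stats::rexp(n, config$revision_hazard) else rep(Inf, n)
  withdrawn <- stats::runif(n) < config$withdrawal_fraction
  twd <- ifelse(withdrawn, stats::runif(n) * potential, Inf)

  fu <- pmin(potential, trev, tdeath, twd)
  event <- as.integer(trev <= pmin(potential, tdeath, twd))
  reason <- rep(NA_character_, n)
  cens <- event == 0L
  reason[cens & fu == potential] <- "end_of_study"
  reason[cens & fu == tdeath] <- "death"
  reason[cens & fu == twd] <- "withdrawal"

  out <- data.frame(
    knee_id = sprintf("K%04d", seq_len(n)),
    patient_id = sprintf("P%04d", pid),
    age_at_surgery = age,
    sex = sex,
    followup_time = fu,
    event = event,
    censor_reason = reason,
    potential_followup = potential,
    stringsAsFactors = FALSE
  )
  class(out) <- c("revrisk_cohort", "data.frame")
  out
}

#' Summarise a cohort against the calibration demographics
#'
#' Age bands are closed on the left and open on the right: under 60,
#' 60 to under 75, and 75 and over.
#'
#' @param cohort A cohort data frame (generated or read from CSV).
#' @return A list of class `cohort_summary` with `n`, `n_revisions`,
#'   `mean_age`, `sd_age`, `mean_followup` (observed time at risk),
#'   `mean_potential_followup` (administrative horizon; `NA` when the
#'   column is absent, e.g. for external cohorts), `followup_range`,
#'   `n_age_lt60`, `n_age_60to74`, `n_age_75plus`, `female_fraction`.
#' @export
summarize_cohort <- function(cohort) {
  if (NROW(cohort) == 0L) stop("cannot summarise an empty cohort")
  a <- cohort$age_at_surgery
  out <- list(
    n = nrow(cohort),
    n_revisions = sum(cohort$event == 1L),
    mean_age = mean(a),
    sd_age = stats::sd(a),
    mean_followup = mean(cohort$followup_time),
    mean_potential_followup =
      if ("potential_followup" %in% names(cohort))
        mean(cohort$potential_followup) else NA_real_,
    followup_range = range(cohort$followup_time),
    n_age_lt60 = sum(a < 60),
    n_age_60to74 = sum(a >= 60 & a < 75),
    n_age_75plus = sum(a >= 75),
    female_fraction = mean(cohort$sex == "F")
  )
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d knees, %d revisions\n", x$n, x$n_revisions))
  cat(sprintf("  age %.1f (SD %.1f); <60 / 60-74 / 75+ = %d / %d / %d; %.0f%% female\n",
              x$mean_age, x$sd_age, x$n_age_lt60, x$n_age_60to74,
              x$n_age_75plus, 100 * x$female_fraction))
  cat(sprintf("  follow-up: observed mean %.2f y (range %.1f-%.1f)",
              x$mean_followup, x$followup_range[1], x$followup_range[2]))
  if (is.finite(x$mean_potential_followup))
    cat(sprintf(", potential mean %.2f y", x$mean_potential_followup))
  cat("\n")
  invisible(x)
}

#' Read / write the cohort CSV dialect
#'
#' Header `knee_id,patient_id,age_at_surgery,sex,followup_time,event,
#' censor_reason`; sex coded `F`/`M`, event `0`/`1`, `.` decimal,
#' comma-separated, UTF-8. `censor_reason` is empty for revised knees.
#'
#' @param path Path to the CSV file.
#' @return `read_cohort_csv()` returns a `revrisk_cohort` data frame;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  classes <- c(knee_id = "character", patient_id = "character",
               sex = "character", censor_reason = "character")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = classes[names(classes) %in% hdr])
  req <- c("knee_id", "patient_id", "age_at_surgery", "sex",
           "followup_time", "event")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("cohort CSV ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!all(df$event %in% c(0L, 1L)))
    stop("cohort CSV ", path, ": `event` must be 0 or 1")
  if (any(!is.finite(df$followup_time)) || any(df$followup_time <= 0))
    stop("cohort CSV ", path, ": `followup_time` must be positive")
  if (!all(df$sex %in% c("F", "M")))
    stop("cohort CSV ", path, ": `sex` must be coded F or M")
  if (!"censor_reason" %in% names(df)) df$censor_reason <- NA_character_
  df$censor_reason[df$censor_reason == ""] <- NA_character_
  class(df) <- c("revrisk_cohort", "data.frame")
  df
}

#' @rdname read_cohort_csv
#' @param cohort Cohort data frame to write.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- c("knee_id", "patient_id", "age_at_surgery", "sex",
            "followup_time", "event", "censor_reason")
  df <- as.data.frame(cohort)[, cols]
  df$censor_reason[is.na(df$censor_reason)] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
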