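# Shared fixtures: built in code, no files on disk.

fixture_lt <- makeham_life_table()

# Flat annual mortality q at every age below the closing age.
flat_life_table <- function(q, max_age = 120, start_age = 0) {
  ages <- start_age:max_age
  qx <- rep(q, length(ages))
  qx[length(qx)] <- 1
  life_table(ages, qx)
}

# A fit object with parameters set by hand (no data behind it), enough for
# survival_prob() and the Markov model.
manual_fit <- function(family, params) {
  structure(list(family = family, params = params, loglik = NA_real_,
                 n_params = length(params), aic = NA_real_,
                 converged = TRUE, n = 0L, n_events = 0L),
            class = "revrisk_fit")
}

# Small deterministic cohort data frame for incidence / summary tests.
toy_cohort <- function(followup, event, age = 65, sex = "F") {
  n <- length(followup)
  structure(data.frame(
    knee_id = sprintf("K%02d", seq_len(n)),
    patient_id = sprintf("P%02d", seq_len(n)),
    age_at_surgery = rep_len(age, n),
    sex = rep_len(sex, n),
    followup_time = followup,
    event = as.integer(event),
    censor_reason = ifelse(event == 1L, NA_character_, "end_of_study"),
    stringsAsFactors = FALSE
  ), class = c("revrisk_cohort", "data.frame"))
}

# Independent product-limit oracle: straightforward loop over unique event
# times, at-risk counts recomputed by enumeration.
km_oracle <- function(time, event, at) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  for (tt in ut) {
    if (tt > at) break
    n_risk <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}
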