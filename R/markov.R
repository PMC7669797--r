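#' Hazard-modification scenario
#'
#' Scenarios rescale the revision hazard used in the Markov model:
#' `global_hazard_multiplier` applies at every age (e.g. to impose a
#' registry-level revision rate), and `hazard_multiplier_above_threshold`
#' applies additionally at attained ages at or above `age_threshold`
#' (e.g. halving the revision hazard beyond age 90 to reflect reluctance
#' to revise the very elderly).
#'
#' @param age_threshold Attained age at which the threshold multiplier
#'   starts to apply, or `NULL` for no age-dependent modification.
#' @param hazard_multiplier_above_threshold Multiplier applied at ages
#'   `>= age_threshold` (default 0.5).
#' @param global_hazard_multiplier Multiplier applied at all ages
#'   (default 1).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(age_threshold = NULL,
                            hazard_multiplier_above_threshold = 0.5,
                            global_hazard_multiplier = 1) {
  if (!is.null(age_threshold) &&
      (!is.finite(age_threshold) || age_threshold < 0))
    stop("`age_threshold` must be a non-negative age or NULL")
  if (!is.finite(hazard_multiplier_above_threshold) ||
      hazard_multiplier_above_threshold < 0)
    stop("`hazard_multiplier_above_threshold` must be finite and >= 0")
  if (!is.finite(global_hazard_multiplier) || global_hazard_multiplier <= 0)
    stop("`global_hazard_multiplier` must be finite and > 0")
  structure(list(age_threshold = age_threshold,
                 hazard_multiplier_above_threshold = hazard_multiplier_above_threshold,
                 global_hazard_multiplier = global_hazard_multiplier),
            class = "scenario_config")
}

#' Specification of the three-state Markov cohort model
#'
#' The model tracks a cohort entering at `entry_age` immediately after
#' surgery through the states unrevised, revised and dead, in annual
#' cycles. The revision transition is driven by the fitted parametric
#' survival model (as a cause-specific hazard over each cycle); both
#' living states transition to death according to the life table at the
#' attained age. `revised` is absorbing except for death (re-revisions are
#' not modelled), and the model stops at `max_age`, where the life table
#' closes.
#'
#' @param entry_age Integer age at surgery.
#' @param fit A `revrisk_fit` for the revision process.
#' @param lt A [life_table()] covering `entry_age` to `max_age`.
#' @param max_age Model horizon (default 110).
#' @param scenario Optional [scenario_config()].
#' @return A list of class `markov_spec`.
#' @export
markov_spec <- function(entry_age, fit, lt = makeham_life_table(),
                        max_age = 110L, scenario = NULL) {
  entry_age <- as.integer(entry_age)
  max_age <- as.integer(max_age)
  if (entry_age >= max_age) stop("`entry_age` must be below `max_age`")
  stopifnot(inherits(lt, "life_table"))
  if (!all(seq.int(entry_age, max_age) %in% lt$age))
    stop("life table must cover ages ", entry_age, "-", max_age)
  if (!is.null(scenario) && !inherits(scenario, "scenario_config"))
    stop("`scenario` must be a scenario_config or NULL")
  structure(list(entry_age = entry_age, fit = fit, life_table = lt,
                 cycle_length = 1, max_age = max_age, scenario = scenario),
            class = "markov_spec")
}

#' Attach a scenario to a Markov specification
#'
#' @param spec A [markov_spec()].
#' @param scenario A [scenario_config()].
#' @return The spec with the scenario applied.
#' @export
apply_scenario <- function(spec, scenario) {
  stopifnot(inherits(spec, "markov_spec"), inherits(scenario, "scenario_config"))
  spec$scenario <- scenario
  spec
}

# Scenario multiplier at an attained age.
.rr_scenario_multiplier <- function(scenario, attained_age) {
  if (is.null(scenario)) return(1)
  m <- scenario$global_hazard_multiplier
  if (!is.null(scenario$age_threshold) && attained_age >= scenario$age_threshold)
    m <- m * scenario$hazard_multiplier_above_threshold
  m
}

#' One-cycle transition probabilities
#'
#' Over cycle `t -> t + 1` (times since surgery), the revision
#' cause-specific hazard is `h_r = -log(S(t+1)/S(t))` from the fitted
#' survival model, rescaled by any active scenario multiplier, and the
#' mortality hazard is `h_m = -log(1 - qx)` at the attained age (with `qx`
#' capped just below 1 so the log stays finite). Competing risks within
#' the cycle are resolved by constant-hazard apportionment: total exit
#' probability from the unrevised state is `1 - exp(-(h_r + h_m))`, split
#' between revision and death in ratio `h_r : h_m`. From the revised
#' state, death occurs with probability `qx`.
#'
#' @param spec A [markov_spec()].
#' @param cycle_index Cycle number, 0-based; attained age is
#'   `entry_age + cycle_index`.
#' @return Named vector `p_revision`, `p_death_unrevised`,
#'   `p_death_revised`.
#' @export
cycle_probabilities <- function(spec, cycle_index) {
  stopifnot(inherits(spec, "markov_spec"))
  age <- spec$entry_age + cycle_index
  if (age > spec$max_age)
    stop("attained age ", age, " exceeds the model horizon ", spec$max_age)
  qx <- min(qx_at(spec$life_table, age), 1 - 1e-12)
  s0 <- survival_prob(spec$fit, cycle_index)
  s1 <- survival_prob(spec$fit, cycle_index + 1)
  h_r <- if (s0 <= 0) 0 else -log(s1 / s0)
  h_r <- h_r * .rr_scenario_multiplier(spec$scenario, age)
  h_m <- -log1p(-qx)
  h_tot <- h_r + h_m
  if (h_tot <= 0) {
    p_rev <- 0; p_die <- 0
  } else {
    p_exit <- -expm1(-h_tot)
    p_rev <- p_exit * h_r / h_tot
    p_die <- p_exit * h_m / h_tot
  }
  c(p_revision = p_rev, p_death_unrevised = p_die,
    p_death_revised = qx_at(spec$life_table, age))
}

#' Run the Markov cohort model
#'
#' Deterministic propagation of expected state occupancy from (1, 0, 0) at
#' cycle 0 until the cohort reaches `max_age` or the living mass falls
#' below 1e-10. Each trace row reports the occupancy at the *start* of the
#' cycle and the mass newly revised *during* that cycle; the final row is
#' the terminal occupancy with zero new revisions.
#'
#' @param spec A [markov_spec()].
#' @return A data frame of class `state_trace` with columns `cycle`,
#'   `attained_age`, `unrevised`, `revised`, `dead`, `newly_revised`, and
#'   attributes `entry_age` and `family`.
#' @export
run_markov <- function(spec) {
  stopifnot(inherits(spec, "markov_spec"))
  n_max <- spec$max_age - spec$entry_age
  cyc <- integer(0); unrev <- numeric(0); revd <- numeric(0)
  dead <- numeric(0); newr <- numeric(0)
  u <- 1; r <- 0; d <- 0
  for (t in 0:n_max) {
    cyc <- c(cyc, t); unrev <- c(unrev, u); revd <- c(revd, r)
    dead <- c(dead, d)
    if (t == n_max || u + r < 1e-10) {
      newr <- c(newr, 0)
      break
    }
    p <- cycle_probabilities(spec, t)
    nr <- u * p[["p_revision"]]
    d_new <- d + u * p[["p_death_unrevised"]] + r * p[["p_death_revised"]]
    r_new <- r * (1 - p[["p_death_revised"]]) + nr
    u_new <- u * (1 - p[["p_revision"]] - p[["p_death_unrevised"]])
    newr <- c(newr, nr)
    u <- u_new; r <- r_new; d <- d_new
  }
  out <- data.frame(cycle = cyc, attained_age = spec$entry_age + cyc,
                    unrevised = unrev, revised = revd, dead = dead,
                    newly_revised = newr)
  attr(out, "entry_age") <- spec$entry_age
  attr(out, "family") <- spec$fit$family
  class(out) <- c("state_trace", "data.frame")
  out
}

#' Lifetime revision risk from a Markov trace
#'
#' The probability of undergoing at least one revision before death: the
#' sum of newly revised mass over all cycles.
#'
#' @param trace A `state_trace` from [run_markov()].
#' @return An object of class `lifetime_risk`: list with `entry_age`,
#'   `risk`, `ci_low`/`ci_high` (`NA` until bootstrapped) and `family`.
#' @export
lifetime_risk <- function(trace) {
  stopifnot(inherits(trace, "state_trace"))
  structure(list(entry_age = attr(trace, "entry_age"),
                 risk = sum(trace$newly_revised),
                 ci_low = NA_real_, ci_high = NA_real_,
                 family = attr(trace, "family")),
            class = "lifetime_risk")
}

#' @export
print.lifetime_risk <- function(x, ...) {
  ci <- if (is.finite(x$ci_low))
    sprintf(" (95%% CI %.1f-%.1f%%)", 100 * x$ci_low, 100 * x$ci_high) else ""
  cat(sprintf("Lifetime revision risk at age %d (%s): %.1f%%%s\n",
              x$entry_age, x$family, 100 * x$risk, ci))
  invisible(x)
}

#' Model-predicted revision incidence per 100 component-years
#'
#' Used to validate the extrapolation against the observed cohort: over
#' the first `horizon` cycles, 100 times the newly revised mass divided by
#' the unrevised person-time, the latter trapezoid-approximated as the
#' mean of cycle-start and cycle-end occupancy.
#'
#' @param trace A `state_trace` covering at least `horizon` cycles.
#' @param horizon Years of prediction to use (default 10).
#' @return Rate per 100 component-years.
#' @export
predicted_incidence_rate <- function(trace, horizon = 10) {
  stopifnot(inherits(trace, "state_trace"))
  if (nrow(trace) < horizon + 1)
    stop("trace covers only ", nrow(trace) - 1, " cycles; horizon ", horizon,
         " requested")
  i <- seq_len(horizon)
  events <- sum(trace$newly_revised[i])
  person_time <- sum((trace$unrevised[i] + trace$unrevised[i + 1]) / 2)
  100 * events / person_time
}

#' Observed revision incidence per 100 component-years
#'
#' @param cohort Cohort data frame with `followup_time` and `event`.
#' @param horizon Restrict to the first `horizon` years of each knee's
#'   follow-up (default 10).
#' @return Rate per 100 component-years.
#' @export
observed_incidence_rate <- function(cohort, horizon = 10) {
  if (NROW(cohort) == 0L) stop("empty cohort")
  events <- sum(cohort$event == 1L & cohort$followup_time <= horizon)
  person_time <- sum(pmin(cohort$followup_time, horizon))
  100 * events / person_time
}

#' Stochastic microsimulation counterpart of the cohort trace
#'
#' Simulates `n` individuals through the same per-cycle transition
#' probabilities as [run_markov()] and reports state *counts* per cycle.
#' The deterministic trace is the expectation of this simulation; the
#' microsimulation exists for illustration of between-patient variability,
#' not for estimation.
#'
#' @param spec A [markov_spec()].
#' @param n Number of simulated individuals (default 1000).
#' @param seed Optional integer seed.
#' @return A data frame with `cycle`, `attained_age`, and counts
#'   `unrevised`, `revised`, `dead`, `newly_revised`.
#' @export
run_microsim <- function(spec, n = 1000L, seed = NULL) {
  stopifnot(inherits(spec, "markov_spec"))
  if (!is.null(seed)) set.seed(seed)
  n_max <- spec$max_age - spec$entry_age
  state <- rep.int(1L, n)  # 1 unrevised, 2 revised, 3 dead
  rows <- vector("list", n_max + 1)
  for (t in 0:n_max) {
    rows[[t + 1]] <- data.frame(cycle = t, attained_age = spec$entry_age + t,
                                unrevised = sum(state == 1L),
                                revised = sum(state == 2L),
                                dead = sum(state == 3L),
                                newly_revised = 0L)
    if (t == n_max || all(state == 3L)) break
    p <- cycle_probabilities(spec, t)
    was_rev <- which(state == 2L)
    was_unrev <- which(state == 1L)
    if (length(was_rev)) {
      dies <- stats::runif(length(was_rev)) < p[["p_death_revised"]]
      state[was_rev[dies]] <- 3L
    }
    if (length(was_unrev)) {
      u01 <- stats::runif(length(was_unrev))
      dest <- ifelse(u01 < p[["p_revision"]], 2L,
              ifelse(u01 < p[["p_revision"]] + p[["p_death_unrevised"]], 3L, 1L))
      state[was_unrev] <- dest
      rows[[t + 1]]$newly_revised <- sum(dest == 2L)
    }
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Export a state trace as CSV
#'
#' Columns `cycle,attained_age,unrevised,revised,dead,newly_revised`,
#' suitable for plotting state occupancy over time.
#'
#' @param trace A `state_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_state_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
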