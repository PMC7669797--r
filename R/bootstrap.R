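#' Bootstrap configuration
#'
#' @param n_boot Number of bootstrap replicates (default 250).
#' @param resample_unit `"knee"` (rows resampled independently, the
#'   default, matching an analysis of knees) or `"patient"` (clusters of
#'   knees resampled together, available because some patients contribute
#'   both knees).
#' @param seed Integer seed for the resampling stream.
#' @param ci_level Confidence level of the percentile interval
#'   (default 0.95).
#' @return A list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_boot = 250L, resample_unit = c("knee", "patient"),
                             seed = NULL, ci_level = 0.95) {
  n_boot <- as.integer(n_boot)
  if (n_boot < 2L) stop("`n_boot` must be at least 2")
  if (!is.finite(ci_level) || ci_level <= 0 || ci_level >= 1)
    stop("`ci_level` must be in (0, 1)")
  structure(list(n_boot = n_boot,
                 resample_unit = match.arg(resample_unit),
                 seed = seed, ci_level = ci_level),
            class = "bootstrap_config")
}

.rr_resample <- function(cohort, unit) {
  if (unit == "knee") {
    cohort[sample.int(nrow(cohort), replace = TRUE), , drop = FALSE]
  } else {
    ids <- unique(cohort$patient_id)
    picked <- sample(ids, length(ids), replace = TRUE)
    idx <- unlist(lapply(picked, function(p) which(cohort$patient_id == p)),
                  use.names = FALSE)
    cohort[idx, , drop = FALSE]
  }
}

#' Percentile-bootstrap confidence interval for lifetime revision risk
#'
#' For each replicate the cohort is resampled with replacement (at knee or
#' patient level), the survival family of `spec` is refitted, the Markov
#' model is rerun, and the lifetime risk recorded; the interval is the
#' percentile interval of the replicate risks. The point estimate comes
#' from the original, non-resampled fit in `spec`. Resamples containing no
#' revision events cannot be fitted and are redrawn (up to ten times the
#' replicate budget in total; exceeded only for pathologically sparse
#' data).
#'
#' @param cohort Cohort data frame (`followup_time`, `event`,
#'   `patient_id`).
#' @param spec A [markov_spec()] defining the entry age, family, life
#'   table and any scenario; its `fit` provides the point estimate.
#' @param config A [bootstrap_config()].
#' @return A `lifetime_risk` object with `ci_low`/`ci_high` filled in and
#'   attributes `replicates` (the replicate risks) and `n_redrawn`
#'   (zero-event resamples discarded).
#' @export
bootstrap_lifetime_risk <- function(cohort, spec, config = bootstrap_config()) {
  stopifnot(inherits(spec, "markov_spec"), inherits(config, "bootstrap_config"))
  if (NROW(cohort) == 0L) stop("empty cohort")
  if (!is.null(config$seed)) set.seed(config$seed)

  point <- lifetime_risk(run_markov(spec))
  risks <- numeric(config$n_boot)
  n_redrawn <- 0L
  max_draws <- 10L * config$n_boot
  draws <- 0L
  for (b in seq_len(config$n_boot)) {
    repeat {
      draws <- draws + 1L
      if (draws > max_draws)
        stop("exceeded ", max_draws, " resampling attempts without ",
             "obtaining enough resamples containing a revision event")
      rs <- .rr_resample(cohort, config$resample_unit)
      if (sum(rs$event) >= 1L) break
      n_redrawn <- n_redrawn + 1L
    }
    fit_b <- fit_parametric(spec$fit$family, as_surv_data(rs))
    spec_b <- spec
    spec_b$fit <- fit_b
    risks[b] <- lifetime_risk(run_markov(spec_b))$risk
  }
  alpha <- 1 - config$ci_level
  ci <- unname(stats::quantile(risks, c(alpha / 2, 1 - alpha / 2), type = 7))
  if (n_redrawn > 0L)
    message(n_redrawn, " zero-event resample(s) redrawn during bootstrap")
  point$ci_low <- ci[1]
  point$ci_high <- ci[2]
  attr(point, "replicates") <- risks
  attr(point, "n_redrawn") <- n_redrawn
  point
}

#' Write bootstrap replicate risks to CSV
#'
#' Diagnostic export: columns `replicate,risk`.
#'
#' @param estimate A `lifetime_risk` returned by
#'   [bootstrap_lifetime_risk()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bootstrap_replicates <- function(estimate, path) {
  risks <- attr(estimate, "replicates")
  if (is.null(risks)) stop("estimate carries no bootstrap replicates")
  utils::write.csv(data.frame(replicate = seq_along(risks), risk = risks),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
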