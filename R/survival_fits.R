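#' Right-censored survival data
#'
#' Pairs a positive time since surgery with an event indicator (1 = revised,
#' 0 = censored). Deaths, withdrawals and administrative end of follow-up
#' are all treated as censoring for the revision process; mortality is
#' reintroduced later through the life table in the Markov model.
#'
#' @param time Numeric vector of strictly positive times in years.
#' @param event Integer vector of 0/1 event indicators.
#' @return A data frame of class `surv_data` with columns `time`, `event`.
#' @export
surv_data <- function(time, event) {
  time <- as.numeric(time)
  event <- as.integer(event)
  if (length(time) != length(event) || length(time) == 0L)
    stop("`time` and `event` must be non-empty vectors of equal length")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("all times must be finite and strictly positive")
  if (!all(event %in% c(0L, 1L))) stop("`event` must be 0 or 1")
  structure(data.frame(time = time, event = event),
            class = c("surv_data", "data.frame"))
}

#' Extract revision survival data from a cohort
#'
#' @param cohort A cohort data frame with `followup_time` and `event`
#'   columns (see [generate_cohort()] / [read_cohort_csv()]).
#' @return A [surv_data()] object.
#' @export
as_surv_data <- function(cohort) surv_data(cohort$followup_time, cohort$event)

#' Right-censored log-likelihood of a parametric family
#'
#' Computes `sum(event * log f(t) + (1 - event) * log S(t))` under the
#' family's density `f` and survival function `S`, the standard likelihood
#' for right-censored data. Parameterizations are documented in
#' [survival_prob()].
#'
#' @param family One of `"exponential"`, `"gompertz"`, `"weibull"`,
#'   `"lognormal"`, `"loglogistic"`, `"gengamma"`.
#' @param params Named numeric vector of the family's parameters.
#' @param data A [surv_data()] object.
#' @return The log-likelihood (scalar).
#' @examples
#' d <- surv_data(2, 1)
#' surv_loglik("exponential", c(rate = 0.5), d)  # log(0.5) - 1
#' @export
surv_loglik <- function(family, params, data) {
  family <- .rr_check_family(family)
  params <- .rr_check_params(family, params)
  stopifnot(inherits(data, "surv_data"))
  ll <- 0
  ev <- data$event == 1L
  if (any(ev)) ll <- ll + sum(.rr_logdens(family, params, data$time[ev]))
  if (any(!ev)) ll <- ll + sum(log(pmax(.rr_surv(family, params, data$time[!ev]),
                                        .Machine$double.xmin)))
  ll
}

# Transform between the optimiser's unconstrained scale and natural
# parameters: positive parameters are log-transformed, sign-free parameters
# (Gompertz shape, gengamma Q) stay on the identity scale.
.rr_free_mask <- function(family) {
  switch(family,
    exponential = c(rate = FALSE),
    gompertz    = c(rate = FALSE, shape = TRUE),
    weibull     = c(shape = FALSE, scale = FALSE),
    lognormal   = c(meanlog = TRUE, sdlog = FALSE),
    loglogistic = c(scale = FALSE, shape = FALSE),
    gengamma    = c(mu = TRUE, sigma = FALSE, Q = TRUE))
}

.rr_to_unconstrained <- function(family, params) {
  free <- .rr_free_mask(family)
  ifelse(free, params, log(params))
}

.rr_from_unconstrained <- function(family, theta) {
  free <- .rr_free_mask(family)
  p <- ifelse(free, theta, exp(theta))
  names(p) <- names(free)
  p
}

# Initial values: rate from the exponential closed form, shape parameters at
# their nested-null values so richer families start at the loglik of the
# model they nest.
.rr_init <- function(family, data, nested = NULL) {
  lam <- sum(data$event) / sum(data$time)
  switch(family,
    exponential = c(rate = lam),
    gompertz    = c(rate = lam, shape = 1e-4),
    weibull     = c(shape = 1, scale = 1 / lam),
    lognormal   = {
      lt <- log(data$time[data$event == 1L])
      c(meanlog = mean(lt), sdlog = max(stats::sd(lt), 0.5))
    },
    loglogistic = c(scale = 1 / lam, shape = 1),
    gengamma    = {
      if (!is.null(nested) && nested$family == "weibull") {
        c(mu = log(nested$params[["scale"]]),
          sigma = 1 / nested$params[["shape"]], Q = 1)
      } else c(mu = -log(lam), sigma = 1, Q = 1)
    })
}

#' Fit a parametric survival family by maximum likelihood
#'
#' The exponential rate has the closed-form estimate events / total time;
#' the remaining families are maximised numerically on an unconstrained
#' scale (positive parameters log-transformed), initialised from the
#' exponential fit with shape parameters at their nested-null values
#' (Weibull shape 1, Gompertz shape ~0, generalised gamma Q = 1 started
#' from the fitted Weibull). The returned log-likelihood is guaranteed to
#' be at least that of the initialisation point.
#'
#' @param family Family name; see [surv_loglik()].
#' @param data A [surv_data()] object with at least one event.
#' @return An object of class `revrisk_fit`: a list with `family`, named
#'   `params`, `loglik`, `n_params`, `aic` (= 2 * n_params - 2 * loglik),
#'   `converged`, `n`, `n_events`.
#' @examples
#' d <- surv_data(c(2, 4, 6), c(1, 0, 1))
#' fit_parametric("exponential", d)  # rate = 2/12
#' @export
fit_parametric <- function(family, data) {
  family <- .rr_check_family(family)
  stopifnot(inherits(data, "surv_data"))
  if (sum(data$event) < 1L) stop("cannot fit with zero events")

  if (family == "exponential") {
    lam <- sum(data$event) / sum(data$time)
    params <- c(rate = lam)
    return(.rr_make_fit(family, params, surv_loglik(family, params, data),
                        TRUE, data))
  }

  nested <- if (family == "gengamma") fit_parametric("weibull", data) else NULL
  init <- .rr_init(family, data, nested)
  negll <- function(theta) {
    p <- .rr_from_unconstrained(family, theta)
    ll <- tryCatch(surv_loglik(family, p, data), error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  theta0 <- .rr_to_unconstrained(family, init)
  opt <- stats::optim(theta0, negll, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 5000))
  polish <- tryCatch(
    stats::optim(opt$par, negll, method = "BFGS",
                 control = list(reltol = 1e-10, maxit = 500)),
    error = function(e) opt)
  if (polish$value <= opt$value) opt <- polish
  params <- .rr_from_unconstrained(family, opt$par)
  ll <- -opt$value
  converged <- opt$convergence == 0
  ll0 <- surv_loglik(family, init, data)
  if (ll < ll0) {  # optimiser must never end below its start
    params <- init
    ll <- ll0
    converged <- FALSE
  }
  if (!converged) warning("fit for family '", family, "' did not converge")
  .rr_make_fit(family, params, ll, converged, data)
}

.rr_make_fit <- function(family, params, loglik, converged, data) {
  k <- length(.rr_param_names[[family]])
  structure(list(
    family = family,
    params = params,
    loglik = loglik,
    n_params = k,
    aic = 2 * k - 2 * loglik,
    converged = converged,
    n = nrow(data),
    n_events = sum(data$event)
  ), class = "revrisk_fit")
}

#' @export
print.revrisk_fit <- function(x, ...) {
  cat("Parametric survival fit:", x$family, "\n")
  cat("  params:", paste(names(x$params), signif(x$params, 5),
                         sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  loglik %.3f  AIC %.3f  (n = %d, events = %d)%s\n",
              x$loglik, x$aic, x$n, x$n_events,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Survival function of a fitted (or specified) family
#'
#' Evaluates S(t) under the family's parameterization: exponential
#' `exp(-rate*t)`; Weibull `exp(-(t/scale)^shape)`; Gompertz hazard
#' `rate*exp(shape*t)` with sign-free shape; log-normal
#' `1 - Phi((log t - meanlog)/sdlog)`; log-logistic
#' `1/(1 + (t/scale)^shape)`; generalised gamma in the log-location form
#' `(mu, sigma, Q)`, which nests Weibull at `Q = 1` and log-normal at
#' `Q -> 0`.
#'
#' @param fit A `revrisk_fit` object, or a list with `family` and `params`.
#' @param t Non-negative time(s) in years.
#' @return Survival probabilities in \[0, 1\]; `S(0) = 1`.
#' @export
survival_prob <- function(fit, t) {
  if (any(t < 0)) stop("`t` must be non-negative")
  family <- .rr_check_family(fit$family)
  params <- .rr_check_params(family, fit$params, boundary_ok = TRUE)
  s <- .rr_surv(family, params, t)
  s[t == 0] <- 1
  pmin(pmax(s, 0), 1)
}

#' Rank fitted families by AIC
#'
#' @param fits List of `revrisk_fit` objects fitted to the same data (same
#'   `n` and `n_events`).
#' @return A data frame sorted by ascending AIC with columns `family`,
#'   `n_params`, `loglik`, `aic`, `delta_aic`, `converged`. Ties are broken
#'   alphabetically by family name.
#' @export
compare_models <- function(fits) {
  if (length(fits) < 2L) stop("need at least two fits to compare")
  stopifnot(all(vapply(fits, inherits, logical(1), "revrisk_fit")))
  ns <- vapply(fits, `[[`, numeric(1), "n")
  evs <- vapply(fits, `[[`, numeric(1), "n_events")
  if (length(unique(ns)) > 1L || length(unique(evs)) > 1L)
    stop("fits were made on differing data (n or event counts differ); ",
         "AIC comparison is only valid on identical data")
  tab <- data.frame(
    family = vapply(fits, `[[`, character(1), "family"),
    n_params = vapply(fits, `[[`, numeric(1), "n_params"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    converged = vapply(fits, `[[`, logical(1), "converged")
  )
  tab <- tab[order(tab$aic, tab$family), , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  tab[, c("family", "n_params", "loglik", "aic", "delta_aic", "converged")]
}

#' Fit all six parametric families
#'
#' @param data A [surv_data()] object.
#' @param families Character vector of families to fit (default all six).
#' @return Named list of `revrisk_fit` objects.
#' @export
fit_all_families <- function(data, families = .rr_families) {
  families <- vapply(families, .rr_check_family, character(1))
  stats::setNames(lapply(families, fit_parametric, data = data), families)
}

#' Kaplan-Meier estimate of revision-free survival
#'
#' Product-limit estimate with Greenwood variance and normal-approximation
#' (plain) 95% confidence limits, as implemented in the survival package.
#' Ties between events and censorings at the same time follow the usual
#' convention (events first).
#'
#' @param data A [surv_data()] object.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `km_estimate`: a data frame with columns
#'   `time`, `n_risk`, `n_event`, `surv`, `lower`, `upper`.
#' @export
km_estimate <- function(data, conf_level = 0.95) {
  stopifnot(inherits(data, "surv_data"))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = data,
                          conf.type = "plain", conf.int = conf_level)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                    surv = sf$surv,
                    lower = pmax(sf$lower, 0), upper = pmin(sf$upper, 1))
  class(out) <- c("km_estimate", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier estimate at given horizons
#'
#' @param km A [km_estimate()].
#' @param times Horizons in years.
#' @return Data frame with `time`, `surv`, `lower`, `upper`, `n_risk`
#'   (number still at risk at each horizon).
#' @export
km_at <- function(km, times) {
  stopifnot(inherits(km, "km_estimate"))
  out <- lapply(times, function(tt) {
    idx <- which(km$time <= tt)
    at_risk_idx <- which(km$time >= tt)
    n_risk <- if (length(at_risk_idx)) km$n_risk[at_risk_idx[1]] else 0L
    if (length(idx) == 0L)
      data.frame(time = tt, surv = 1, lower = 1, upper = 1, n_risk = n_risk)
    else {
      i <- max(idx)
      data.frame(time = tt, surv = km$surv[i], lower = km$lower[i],
                 upper = km$upper[i], n_risk = n_risk)
    }
  })
  do.call(rbind, out)
}
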