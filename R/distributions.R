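# Parameterizations of the six time-to-revision families.
#
#   exponential  rate                    S(t) = exp(-rate * t)
#   weibull      shape k, scale s        S(t) = exp(-(t/s)^k)
#   gompertz     rate, shape (any sign)  h(t) = rate * exp(shape * t)
#   lognormal    meanlog, sdlog          S(t) = 1 - Phi((log t - meanlog)/sdlog)
#   loglogistic  scale a, shape b        S(t) = 1 / (1 + (t/a)^b)
#   gengamma     mu, sigma, Q            log-location form; Q = 1 is Weibull
#                                        (k = 1/sigma, s = exp(mu)), Q -> 0 is
#                                        log-normal(mu, sigma)
#
# The generalised gamma uses the log-location (Prentice) form throughout:
# with w = (log t - mu)/sigma and a = Q^-2 (Q != 0), a * exp(Q * w) is
# gamma(a, 1) distributed, which keeps the likelihood numerically stable
# where the classical (shape, scale, power) form overflows.

.rr_families <- c("exponential", "gompertz", "weibull", "lognormal",
                  "loglogistic", "gengamma")

.rr_param_names <- list(
  exponential = "rate",
  gompertz    = c("rate", "shape"),
  weibull     = c("shape", "scale"),
  lognormal   = c("meanlog", "sdlog"),
  loglogistic = c("scale", "shape"),
  gengamma    = c("mu", "sigma", "Q")
)

.rr_check_family <- function(family) {
  family <- match.arg(family, .rr_families)
  family
}

# `boundary_ok` admits a zero hazard rate (exponential/Gompertz) for
# survival-function evaluation; the likelihood itself needs rate > 0.
.rr_check_params <- function(family, params, boundary_ok = FALSE) {
  nm <- .rr_param_names[[family]]
  if (is.null(names(params))) {
    if (length(params) != length(nm))
      stop(family, " expects ", length(nm), " parameters (", paste(nm, collapse = ", "), ")")
    names(params) <- nm
  }
  if (!all(nm %in% names(params)))
    stop(family, " parameters must be named ", paste(nm, collapse = ", "))
  params <- params[nm]
  if (any(!is.finite(params))) stop("non-finite parameter for family ", family)
  pos <- switch(family,
    exponential = "rate",
    gompertz    = "rate",
    weibull     = c("shape", "scale"),
    lognormal   = "sdlog",
    loglogistic = c("scale", "shape"),
    gengamma    = "sigma")
  if (boundary_ok && family %in% c("exponential", "gompertz") &&
      params[["rate"]] >= 0)
    pos <- setdiff(pos, "rate")
  if (any(params[pos] <= 0))
    stop("parameter(s) ", paste(pos[params[pos] <= 0], collapse = ", "),
         " must be > 0 for family ", family)
  params
}

# Survival function S(t); t >= 0, vectorized.
.rr_surv <- function(family, params, t) {
  if (any(t < 0)) stop("negative time passed to a survival function")
  switch(family,
    exponential = exp(-params[["rate"]] * t),
    weibull = exp(-(t / params[["scale"]])^params[["shape"]]),
    gompertz = {
      g <- params[["shape"]]; r <- params[["rate"]]
      H <- if (abs(g) < 1e-12) r * t else r * (exp(g * t) - 1) / g
      exp(-H)
    },
    lognormal = 1 - stats::pnorm((log(t) - params[["meanlog"]]) / params[["sdlog"]]),
    loglogistic = 1 / (1 + (t / params[["scale"]])^params[["shape"]]),
    gengamma = {
      mu <- params[["mu"]]; sg <- params[["sigma"]]; q <- params[["Q"]]
      if (abs(q) < 1e-8) return(1 - stats::pnorm((log(t) - mu) / sg))
      w <- (log(t) - mu) / sg
      u <- exp(q * w) / q^2
      if (q > 0) stats::pgamma(u, shape = 1 / q^2, lower.tail = FALSE)
      else       stats::pgamma(u, shape = 1 / q^2, lower.tail = TRUE)
    })
}

# log f(t); t > 0, vectorized.
.rr_logdens <- function(family, params, t) {
  if (any(t <= 0)) stop("event times must be strictly positive")
  switch(family,
    exponential = log(params[["rate"]]) - params[["rate"]] * t,
    weibull = stats::dweibull(t, shape = params[["shape"]],
                              scale = params[["scale"]], log = TRUE),
    gompertz = {
      g <- params[["shape"]]; r <- params[["rate"]]
      H <- if (abs(g) < 1e-12) r * t else r * (exp(g * t) - 1) / g
      log(r) + g * t - H
    },
    lognormal = stats::dlnorm(t, meanlog = params[["meanlog"]],
                              sdlog = params[["sdlog"]], log = TRUE),
    loglogistic = {
      a <- params[["scale"]]; b <- params[["shape"]]
      lz <- b * (log(t) - log(a))
      log(b) - log(a) + (b - 1) * (log(t) - log(a)) - 2 * log1p(exp(lz))
    },
    gengamma = {
      mu <- params[["mu"]]; sg <- params[["sigma"]]; q <- params[["Q"]]
      if (abs(q) < 1e-8)
        return(stats::dlnorm(t, meanlog = mu, sdlog = sg, log = TRUE))
      w <- (log(t) - mu) / sg
      a <- 1 / q^2
      log(abs(q)) + a * log(a) - log(sg) - log(t) - lgamma(a) +
        a * (q * w - exp(q * w))
    })
}
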