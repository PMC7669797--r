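test_that("right-censored log-likelihood matches hand arithmetic", {
  expect_equal(surv_loglik("exponential", c(rate = 0.5), surv_data(2, 1)),
               log(0.5) - 1, tolerance = 1e-12)
  expect_equal(surv_loglik("exponential", c(rate = 0.5), surv_data(2, 0)),
               -1, tolerance = 1e-12)
  expect_error(surv_loglik("exponential", c(rate = -1), surv_data(2, 1)), "> 0")
  expect_error(surv_data(c(0, 1), c(1, 1)), "positive")
})

test_that("exponential MLE equals the closed form events / time", {
  f <- fit_parametric("exponential", surv_data(c(1, 2, 3), c(1, 1, 1)))
  expect_identical(f$params[["rate"]], 3 / 6)

  d <- surv_data(c(2, 4, 6), c(1, 0, 1))
  f2 <- fit_parametric("exponential", d)
  expect_identical(f2$params[["rate"]], 2 / 12)
  expect_equal(f2$loglik, 2 * log(1 / 6) - 2, tolerance = 1e-12)
  expect_equal(f2$aic, 2 * 1 - 2 * f2$loglik, tolerance = 1e-15)

  expect_error(fit_parametric("exponential", surv_data(c(1, 2), c(0, 0))),
               "zero events")
})

test_that("nesting identities hold between families", {
  set.seed(4)
  d <- surv_data(rexp(200, 0.1), rbinom(200, 1, 0.7))
  # gengamma at Q = 1 is Weibull with shape = 1/sigma, scale = exp(mu)
  wb <- c(shape = 1.4, scale = 9)
  gg <- c(mu = log(9), sigma = 1 / 1.4, Q = 1)
  expect_equal(surv_loglik("gengamma", gg, d), surv_loglik("weibull", wb, d),
               tolerance = 1e-8)
  # gengamma at Q -> 0 is log-normal
  ln <- c(meanlog = 2, sdlog = 0.8)
  expect_equal(surv_loglik("gengamma", c(mu = 2, sigma = 0.8, Q = 0), d),
               surv_loglik("lognormal", ln, d), tolerance = 1e-8)
  # Weibull at shape 1 is exponential with rate 1/scale
  tg <- seq(0, 60, by = 0.5)
  expect_equal(survival_prob(manual_fit("weibull", c(shape = 1, scale = 200)), tg),
               survival_prob(manual_fit("exponential", c(rate = 1 / 200)), tg),
               tolerance = 1e-12)
})

test_that("survival functions start at 1, stay in [0,1] and never increase", {
  set.seed(9)
  d <- surv_data(rexp(400, 0.08), rbinom(400, 1, 0.6))
  tg <- c(0, 10^seq(-3, 2, length.out = 200))
  for (fam in revision_families()) {
    fit <- fit_parametric(fam, d)
    s <- survival_prob(fit, tg)
    expect_equal(s[1], 1, info = fam)
    expect_true(all(s >= 0 & s <= 1), info = fam)
    expect_true(all(diff(s) <= 1e-12), info = fam)
  }
  expect_error(survival_prob(fit, -1), "non-negative")
})

test_that("the optimiser never ends below its start and nesting orders logliks", {
  co <- generate_cohort(cohort_config(seed = 31), fixture_lt)
  d <- as_surv_data(co)
  fits <- fit_all_families(d)
  for (f in fits) {
    expect_true(f$converged, info = f$family)
    expect_equal(f$aic, 2 * f$n_params - 2 * f$loglik, tolerance = 1e-12)
  }
  # nested families can only improve the maximised likelihood
  expect_gte(fits$weibull$loglik, fits$exponential$loglik - 1e-6)
  expect_gte(fits$gengamma$loglik, fits$weibull$loglik - 1e-6)
  expect_gte(fits$gompertz$loglik, fits$exponential$loglik - 1e-6)
})

test_that("each family recovers its own generating parameters", {
  # Monte-Carlo recovery: mean estimate over replicates within 3 standard
  # errors of the truth (errors estimated from the replicate spread).
  gens <- list(
    exponential = list(p = c(rate = 0.02),
                       r = function(n) rexp(n, 0.02)),
    weibull     = list(p = c(shape = 1.4, scale = 45),
                       r = function(n) rweibull(n, 1.4, 45)),
    gompertz    = list(p = c(rate = 0.01, shape = 0.06),
                       r = function(n) {  # inverse-CDF draw
                         u <- runif(n)
                         log(1 - 0.06 * log(u) / 0.01) / 0.06
                       }),
    lognormal   = list(p = c(meanlog = 3.4, sdlog = 0.9),
                       r = function(n) rlnorm(n, 3.4, 0.9)),
    loglogistic = list(p = c(scale = 40, shape = 2.2),
                       r = function(n) 40 * (1 / runif(n) - 1)^(-1 / 2.2))
  )
  set.seed(77)
  n <- 2000; reps <- 8
  for (fam in names(gens)) {
    g <- gens[[fam]]
    est <- replicate(reps, {
      t_raw <- g$r(n)
      cens <- runif(n, 0, 2 * stats::median(t_raw))  # ~independent censoring
      d <- surv_data(pmin(t_raw, cens), as.integer(t_raw <= cens))
      fit_parametric(fam, d)$params
    })
    est <- matrix(est, nrow = length(g$p))
    for (i in seq_along(g$p)) {
      se <- sd(est[i, ]) / sqrt(reps)
      expect_lt(abs(mean(est[i, ]) - g$p[i]), 3 * se + 1e-8,
                label = paste(fam, names(g$p)[i]))
    }
  }
})

test_that("maximised likelihoods agree with an independent implementation", {
  skip_if_not_installed("flexsurv")
  set.seed(12)
  t_raw <- rweibull(600, 1.3, 30)
  cens <- runif(600, 0, 45)
  d <- surv_data(pmin(t_raw, cens), as.integer(t_raw <= cens))
  map <- c(exponential = "exp", weibull = "weibull", gompertz = "gompertz",
           lognormal = "lnorm", loglogistic = "llogis", gengamma = "gengamma")
  for (fam in names(map)) {
    mine <- fit_parametric(fam, d)
    ref <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = d,
                                 dist = map[[fam]])
    expect_equal(mine$loglik, ref$loglik, tolerance = 1e-4, info = fam)
  }
})

test_that("AIC ranking sorts ascending with deltas from the best", {
  set.seed(21)
  d <- surv_data(rexp(300, 0.05), rbinom(300, 1, 0.5))
  fits <- fit_all_families(d, c("exponential", "weibull", "gompertz"))
  tab <- compare_models(fits)
  expect_equal(tab$aic, sort(tab$aic))
  expect_equal(tab$delta_aic, tab$aic - tab$aic[1])
  expect_equal(tab$delta_aic[1], 0)

  # ties break alphabetically by family name
  f1 <- fits$exponential; f2 <- fits$exponential
  f2$family <- "zzz-duplicate"
  tie <- compare_models(list(f2, f1))
  expect_equal(tie$family, c("exponential", "zzz-duplicate"))
  expect_equal(tie$delta_aic, c(0, 0))

  # differing data refuse to compare
  other <- fit_parametric("exponential", surv_data(c(1, 2), c(1, 1)))
  expect_error(compare_models(list(fits$exponential, other)), "differing data")
})

test_that("constant-hazard cohorts are usually best described by the exponential", {
  wins <- 0L
  reps <- 10L
  for (s in 1:reps) {
    co <- generate_cohort(cohort_config(seed = 9000 + s), fixture_lt)
    tab <- compare_models(fit_all_families(as_surv_data(co)))
    wins <- wins + (tab$family[1] == "exponential")
  }
  expect_gt(wins, reps / 2)
})
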