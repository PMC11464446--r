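test_that("least squares recovers parameters exactly from an exact curve", {
  truth <- c(scale = 0.0766, shape = 1.268)
  d <- surv_dist("loglogistic", scale = truth[1], shape = truth[2])
  grid <- seq(0.5, 40, length.out = 40)
  fit <- fit_parametric(km_curve(grid, survival_at(d, grid)), "loglogistic")
  expect_equal(unname(coef(fit)), unname(truth), tolerance = 1e-6)
  # refit on the curve generated from the fitted law: idempotent
  refit <- fit_parametric(km_curve(grid, survival_at(fit$dist, grid)),
                          "loglogistic")
  expect_equal(coef(refit), coef(fit), tolerance = 1e-6)
})

test_that("exponential MLE matches the events-over-exposure closed form", {
  d <- surv_dist("exponential", rate = 0.07)
  ipd <- simulate_ipd(d, 800, admin_censor = 30, dropout_rate = 0,
                      seed = 31)
  fit <- fit_parametric(ipd, "exponential")
  expect_equal(unname(coef(fit)["rate"]),
               sum(ipd$event) / sum(ipd$time), tolerance = 1e-5)
})

test_that("maximum-likelihood fits agree with an independent fitter", {
  skip_if_not_installed("flexsurv")
  d <- fitted_dists()$ch_os
  ipd <- simulate_ipd(d, 600, seed = 17)
  mine <- fit_parametric(ipd, "loglogistic")
  ref <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1,
                               data = ipd, dist = "llogis")
  expect_equal(unname(coef(mine)["shape"]),
               unname(ref$res["shape", "est"]), tolerance = 1e-4)
  expect_equal(unname(coef(mine)["scale"]),
               unname(1 / ref$res["scale", "est"]), tolerance = 1e-4)
  expect_equal(mine$loglik, ref$loglik, tolerance = 1e-6)
  expect_equal(mine$aic, ref$AIC, tolerance = 1e-4)
  mw <- fit_parametric(ipd, "weibull")
  rw <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1,
                              data = ipd, dist = "weibull")
  expect_equal(unname(coef(mw)), unname(rw$res[c("shape", "scale"), "est"]),
               tolerance = 1e-4)
})

test_that("AIC and BIC follow their definitions", {
  ipd <- simulate_ipd(fitted_dists()$ch_os, 300, seed = 3)
  f <- fit_parametric(ipd, "loglogistic")
  expect_equal(f$aic, 2 * f$k - 2 * f$loglik)
  expect_equal(f$bic, f$k * log(f$n) - 2 * f$loglik)
  expect_equal(f$n, 300)
})

test_that("Wald intervals cover the truth at their nominal rate", {
  truth <- fitted_pars()$ch_os
  d <- fitted_dists()$ch_os
  set.seed(1)
  hits <- replicate(200, {
    ipd <- simulate_ipd(d, 500)
    ci <- confint(fit_parametric(ipd, "loglogistic"))
    truth >= ci[, 1] & truth <= ci[, 2]
  })
  cover <- rowMeans(hits)
  expect_gte(cover[1], 0.93)   # scale
  expect_gte(cover[2], 0.93)   # shape
})

test_that("fit ranking is by AIC, then BIC, then parsimony", {
  base <- fit_parametric(simulate_ipd(fitted_dists()$ch_os, 100, seed = 2),
                         "loglogistic")
  mk <- function(aic, bic, k) {
    f <- base; f$aic <- aic; f$bic <- bic; f$k <- k; f
  }
  r <- rank_fits(list(mk(110, 100, 2), mk(100, 120, 2)))
  expect_equal(r[[1]]$aic, 100)
  r <- rank_fits(list(mk(100, 105, 2), mk(100, 102, 2)))
  expect_equal(r[[1]]$bic, 102)
  r <- rank_fits(list(mk(100, 102, 3), mk(100, 102, 2)))
  expect_equal(r[[1]]$k, 2)
  expect_error(rank_fits(list()), "no fits")
})

test_that("information criteria select the generating family", {
  d <- fitted_dists()$ch_os
  fams <- c("exponential", "weibull", "lognormal", "loglogistic",
            "gompertz", "gengamma")
  set.seed(7)
  wins <- replicate(100, {
    ipd <- simulate_ipd(d, 1000)
    fits <- lapply(fams, function(fm) {
      tryCatch(fit_parametric(ipd, fm), error = function(e) NULL)
    })
    rank_fits(Filter(Negate(is.null), fits))[[1]]$dist$family
  })
  expect_gte(mean(wins == "loglogistic"), 0.80)
})

test_that("parameter bias shrinks with sample size", {
  d <- fitted_dists()$ch_os
  truth <- fitted_pars()$ch_os
  err <- vapply(c(100, 500, 2000), function(n) {
    est <- vapply(1:8, function(r) {
      coef(fit_parametric(simulate_ipd(d, n, seed = 5000 + 17 * n + r),
                          "loglogistic"))
    }, numeric(2))
    max(abs(rowMeans(est) / truth - 1))
  }, 0)
  expect_lt(err[3], err[1])
  expect_lt(err[3], 0.03)
})

test_that("degenerate curves produce a fit error with a diagnostic", {
  flat <- km_curve(1:10, rep(1, 10))
  expect_error(fit_parametric(flat, "loglogistic"), "degenerate")
})

test_that("pseudo-IPD reconstruction approximates the generating curve", {
  d <- fitted_dists()$ch_pfs
  ipd <- simulate_ipd(d, 1500, seed = 19)
  cv <- km_estimate(ipd)
  rec <- reconstruct_ipd(cv)
  expect_equal(nrow(rec), nrow(ipd), tolerance = 0.02)
  fit <- fit_parametric(cv, "loglogistic", method = "mle")
  expect_equal(unname(coef(fit)), unname(fitted_pars()$ch_pfs),
               tolerance = 0.08)
})

test_that("fits serialize to JSON with family, parameters and criteria", {
  f <- fit_parametric(simulate_ipd(fitted_dists()$ch_os, 200, seed = 4),
                      "loglogistic")
  path <- tempfile(fileext = ".json")
  write_fit_json(f, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$family, "loglogistic")
  expect_equal(back$parameters$scale, unname(coef(f)["scale"]),
               tolerance = 1e-12)
  expect_equal(back$aic, f$aic, tolerance = 1e-12)
})
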