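# Shared fixtures: the four fitted log-logistic laws of the shipped base
# case, a cached configuration, and small helpers.

fitted_dists <- function() {
  list(
    ev_pfs = surv_dist("loglogistic", scale = 0.07657114, shape = 1.267575),
    ev_os  = surv_dist("loglogistic", scale = 0.02895679, shape = 1.226923),
    ch_pfs = surv_dist("loglogistic", scale = 0.1565434,  shape = 1.997612),
    ch_os  = surv_dist("loglogistic", scale = 0.06252743, shape = 1.524174))
}

fitted_pars <- function() {
  list(ev_pfs = c(0.07657114, 1.267575), ev_os = c(0.02895679, 1.226923),
       ch_pfs = c(0.1565434, 1.997612),  ch_os = c(0.06252743, 1.524174))
}

cached_config <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- base_config()
    cfg
  }
})

example_dists <- function() {
  list(
    exponential = surv_dist("exponential", rate = 0.08),
    weibull     = surv_dist("weibull", shape = 1.4, scale = 14),
    lognormal   = surv_dist("lognormal", meanlog = 2.4, sdlog = 0.9),
    loglogistic = surv_dist("loglogistic", scale = 0.0766, shape = 1.268),
    gompertz    = surv_dist("gompertz", shape = 0.05, rate = 0.04),
    gengamma    = surv_dist("gengamma", mu = 2.5, sigma = 0.8, Q = 0.7))
}
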