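# Fitting parametric survival laws to digitized curves or (pseudo-)IPD.
#
# Two objectives, mirroring how extrapolation models are fitted to digitized
# Kaplan-Meier data in practice: maximum likelihood on individual
# event/censoring times where available, and weighted least squares on the
# complementary log-log survival scale for bare coordinate sets.

par_transforms <- function(family) {
  switch(family,
         exponential = c(rate = "log"),
         weibull     = c(shape = "log", scale = "log"),
         lognormal   = c(meanlog = "identity", sdlog = "log"),
         loglogistic = c(scale = "log", shape = "log"),
         # Gompertz shape is restricted to > 0 during fitting so that the
         # fitted law is proper (S -> 0); negative shapes remain
         # representable in surv_dist itself.
         gompertz    = c(shape = "log", rate = "log"),
         gengamma    = c(mu = "identity", sigma = "log", Q = "log"))
}

to_unconstrained <- function(pars, tr) {
  ifelse(tr == "log", log(pars), pars)
}

from_unconstrained <- function(theta, tr) {
  out <- ifelse(tr == "log", exp(theta), theta)
  names(out) <- names(tr)
  out
}

# Regression-based starting values from (time, survival) coordinates.
start_values <- function(family, time, surv) {
  keep <- time > 0 & surv > 1e-6 & surv < 1 - 1e-6
  t <- time[keep]; s <- surv[keep]
  if (length(t) < 2) stop("too few usable points for starting values",
                          call. = FALSE)
  lt <- log(t)
  switch(family,
    exponential = c(rate = max(mean(-log(s) / t), 1e-8)),
    weibull = {
      f <- stats::lm(log(-log(s)) ~ lt)
      sh <- max(stats::coef(f)[2], 0.05)
      c(shape = unname(sh), scale = unname(exp(-stats::coef(f)[1] / sh)))
    },
    lognormal = {
      f <- stats::lm(stats::qnorm(1 - s) ~ lt)
      sd <- max(1 / stats::coef(f)[2], 0.05)
      c(meanlog = unname(-stats::coef(f)[1] * sd), sdlog = unname(sd))
    },
    loglogistic = {
      f <- stats::lm(log((1 - s) / s) ~ lt)
      ga <- max(stats::coef(f)[2], 0.05)
      c(scale = unname(exp(stats::coef(f)[1] / ga)), shape = unname(ga))
    },
    gompertz = {
      c(shape = 0.02, rate = max(mean(-log(s) / t), 1e-8))
    },
    gengamma = {
      w <- start_values("weibull", time, surv)
      c(mu = unname(log(w["scale"])), sigma = unname(1 / w["shape"]), Q = 1)
    })
}

#' Fit a parametric survival distribution
#'
#' Fits one of the six supported families either to a digitized
#' Kaplan-Meier curve ([km_curve()]) or to individual patient data (a data
#' frame with `time` and `event` columns, as produced by
#' [simulate_ipd()]).
#'
#' With IPD the objective is the censored log-likelihood.  With a bare
#' curve the objective is (weighted) least squares on
#' `log(-log S)`; weights default to numbers at risk when the curve
#' carries them.  A curve with numbers at risk can also be fitted by
#' maximum likelihood after interval reconstruction of pseudo-IPD
#' (`method = "mle"`; see [reconstruct_ipd()]).
#'
#' @param x A `km_curve` or a data frame with columns `time`, `event`.
#' @param family Distribution family, see [surv_dist()].
#' @param method `"auto"` (MLE for IPD, least squares for curves),
#'   `"mle"`, or `"wls"`.
#' @param weights Optional least-squares weights (curves only).
#' @return A `fit_result`: the fitted `surv_dist` plus `loglik`, `aic`,
#'   `bic`, problem size `n`, and standard errors.
#' @examples
#' d <- surv_dist("loglogistic", scale = 0.0766, shape = 1.268)
#' cv <- km_curve(1:40, survival_at(d, 1:40))
#' fit <- fit_parametric(cv, "loglogistic")
#' coef(fit)
#' @export
fit_parametric <- function(x, family, method = c("auto", "mle", "wls"),
                           weights = NULL) {
  method <- match.arg(method)
  is_ipd <- !inherits(x, "km_curve") && all(c("time", "event") %in% names(x))
  if (method == "auto") method <- if (is_ipd) "mle" else "wls"
  if (is_ipd) {
    if (method != "mle") stop("IPD input is fitted by maximum likelihood",
                              call. = FALSE)
    return(fit_mle(x, family))
  }
  if (!inherits(x, "km_curve")) x <- km_curve(x$time, x$survival)
  if (method == "mle") {
    return(fit_mle(reconstruct_ipd(x), family))
  }
  fit_wls(x, family, weights)
}

fit_objective <- function(family, fn, start) {
  tr <- par_transforms(family)
  theta0 <- to_unconstrained(start[names(tr)], tr)
  obj <- function(theta) fn(from_unconstrained(theta, tr))
  if (length(theta0) > 1) {
    pre <- stats::optim(theta0, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    theta0 <- pre$par
  }
  opt <- stats::optim(theta0, obj, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  list(pars = from_unconstrained(opt$par, tr), value = opt$value,
       hessian = opt$hessian, tr = tr, theta = opt$par,
       converged = opt$convergence == 0)
}

fit_mle <- function(ipd, family) {
  stopifnot(all(ipd$time > 0), all(ipd$event %in% 0:1))
  if (sum(ipd$event) < 1) stop("no events in data", call. = FALSE)
  km <- km_estimate(ipd)
  start <- start_values(family, km$time, km$survival)
  negll <- function(pars) {
    d <- try(do.call(surv_dist, c(list(family), as.list(pars))),
             silent = TRUE)
    if (inherits(d, "try-error")) return(1e10)
    f <- density_at(d, ipd$time); s <- survival_at(d, ipd$time)
    v <- -sum(ipd$event * log(pmax(f, 1e-300)) +
                (1 - ipd$event) * log(pmax(s, 1e-300)))
    if (!is.finite(v)) 1e10 else v
  }
  opt <- fit_objective(family, negll, start)
  dist <- do.call(surv_dist, c(list(family), as.list(opt$pars)))
  ll <- -opt$value
  k <- n_params(dist); n <- nrow(ipd)
  new_fit_result(dist, ll, k, n, sum(ipd$event), "mle", opt)
}

fit_wls <- function(curve, family, weights = NULL) {
  usable <- curve$time > 0 & curve$survival > 1e-6 &
    curve$survival < 1 - 1e-6
  if (sum(usable) < 2 * length(surv_dist_pars(family))) {
    stop("degenerate curve: need at least 2 usable points per free ",
         "parameter after cleaning", call. = FALSE)
  }
  t <- curve$time[usable]; s <- curve$survival[usable]
  # default weights: inverse delta-method variance of log(-log S) under
  # homoskedastic ordinate noise, i.e. (S log S)^2, times numbers at risk
  # when the curve carries them
  w <- if (!is.null(weights)) weights[usable]
       else (s * log(s))^2 *
         (if (!is.null(curve$n_risk)) curve$n_risk[usable] else 1)
  y <- log(-log(s))
  start <- start_values(family, t, s)
  rss_fn <- function(pars) {
    d <- try(do.call(surv_dist, c(list(family), as.list(pars))),
             silent = TRUE)
    if (inherits(d, "try-error")) return(1e10)
    sm <- survival_at(d, t)
    sm <- pmin(pmax(sm, 1e-12), 1 - 1e-12)
    v <- sum(w * (log(-log(sm)) - y)^2)
    if (!is.finite(v)) 1e10 else v
  }
  opt <- fit_objective(family, rss_fn, start)
  dist <- do.call(surv_dist, c(list(family), as.list(opt$pars)))
  n <- length(t)
  # Gaussian pseudo-likelihood of the transformed residuals, so that
  # AIC/BIC are comparable across families fitted on the same points.
  sigma2 <- opt$value / sum(w)
  ll <- -sum(w) / 2 * (log(2 * pi * sigma2) + 1)
  new_fit_result(dist, ll, n_params(dist), n, NULL, "wls", opt)
}

new_fit_result <- function(dist, loglik, k, n, n_events, method, opt) {
  se <- rep(NA_real_, k)
  vc <- try(solve(opt$hessian), silent = TRUE)
  if (!inherits(vc, "try-error") && all(is.finite(vc)) &&
      all(diag(vc) >= 0)) {
    se <- sqrt(diag(vc))
  }
  structure(list(dist = dist, loglik = loglik,
                 aic = 2 * k - 2 * loglik,
                 bic = k * log(n) - 2 * loglik,
                 k = k, n = n, n_events = n_events, method = method,
                 se_trans = se, transforms = opt$tr, theta = opt$theta,
                 converged = opt$converged),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s fit (%s), n = %d\n", x$dist$family,
              x$method, x$n))
  print(x$dist)
  cat(sprintf("  logLik = %.3f  AIC = %.3f  BIC = %.3f\n",
              x$loglik, x$aic, x$bic))
  invisible(x)
}

#' @export
coef.fit_result <- function(object, ...) object$dist$pars

#' Wald confidence intervals for fitted parameters
#'
#' Computed on the unconstrained (log) scale and back-transformed, the
#' usual construction for positive survival parameters.
#'
#' @param object A `fit_result`.
#' @param parm Ignored; all parameters are returned.
#' @param level Confidence level.
#' @param ... Unused.
#' @export
confint.fit_result <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- object$theta - z * object$se_trans
  hi <- object$theta + z * object$se_trans
  tr <- object$transforms
  out <- cbind(lower = ifelse(tr == "log", exp(lo), lo),
               upper = ifelse(tr == "log", exp(hi), hi))
  rownames(out) <- names(object$dist$pars)
  out
}

#' Rank competing fits by information criteria
#'
#' Ascending AIC, ties broken by BIC, then by fewer free parameters
#' (parsimony).
#'
#' @param fits A list of `fit_result` objects fitted on the same data.
#' @return The list reordered, best first.
#' @export
rank_fits <- function(fits) {
  if (length(fits) == 0) stop("no fits to rank", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, TRUE, "fit_result")))
  aic <- vapply(fits, `[[`, 0, "aic")
  bic <- vapply(fits, `[[`, 0, "bic")
  k <- vapply(fits, `[[`, 0, "k")
  fits[order(aic, bic, k)]
}

#' Reconstruct pseudo-IPD from a curve with numbers at risk
#'
#' Interval-based reconstruction: within each interval between curve
#' coordinates, the number of events is inferred from the drop in survival
#' conditional on the number at risk, the remainder of the at-risk
#' difference is treated as censored, and both are placed at the interval
#' midpoint.  This is the minimal reconstruction needed to fit digitized
#' curves by maximum likelihood; it assumes the coordinate grid is fine
#' relative to the event rate.
#'
#' @param curve A `km_curve` with an `n_risk` column.
#' @return A data frame with `time` and `event` columns.
#' @export
reconstruct_ipd <- function(curve) {
  if (is.null(curve$n_risk)) {
    stop("pseudo-IPD reconstruction requires numbers at risk", call. = FALSE)
  }
  tt <- c(0, curve$time); ss <- c(1, curve$survival)
  nn <- c(curve$n_risk[1], curve$n_risk)
  times <- numeric(0); events <- integer(0)
  for (i in seq_len(length(tt) - 1)) {
    mid <- (tt[i] + tt[i + 1]) / 2
    d <- round(nn[i] * (1 - ss[i + 1] / max(ss[i], 1e-12)))
    d <- max(min(d, nn[i]), 0)
    cens <- max(nn[i] - d - nn[i + 1], 0)
    times <- c(times, rep(mid, d + cens))
    events <- c(events, rep(1L, d), rep(0L, cens))
  }
  nlast <- nn[length(nn)]
  if (nlast > 0) {
    times <- c(times, rep(tt[length(tt)], nlast))
    events <- c(events, rep(0L, nlast))
  }
  data.frame(time = times, event = events)
}

#' Serialize a fit to JSON
#'
#' @param fit A `fit_result`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(family = fit$dist$family,
         parameters = as.list(fit$dist$pars),
         loglik = fit$loglik, aic = fit$aic, bic = fit$bic,
         n = fit$n, method = fit$method),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
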