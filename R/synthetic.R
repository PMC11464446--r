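# Synthetic-data generators: simulated IPD with censoring, product-limit
# estimation, and emulation of figure digitization.  These stand in for
# trial patient data (never deposited) and for the manual digitization
# step, giving the fitting stage inputs with known ground truth.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

#' Simulate individual patient data from a survival law
#'
#' Event times are drawn by inverse transform, `T = S^{-1}(U)` with
#' `U ~ U(0,1)` (for the log-logistic,
#' `T = (1/lambda) (1/U - 1)^{1/gamma}`).  Censoring combines an
#' administrative cutoff (trial follow-up end) and random exponential
#' dropout.
#'
#' @param dist A `surv_dist` generating the event times.
#' @param n Number of subjects.
#' @param admin_censor Administrative censoring time in months
#'   (`Inf` to disable).  Default mimics a trial with roughly two years of
#'   follow-up.
#' @param dropout_rate Annual random-dropout probability (exponential
#'   hazard), default 5 percent per year.
#' @param seed Integer seed; generators never touch global random state
#'   beyond a save/restore.
#' @return A data frame of class `sim_ipd` with columns `time` (months)
#'   and `event` (1 = event, 0 = censored); the generating distribution is
#'   attached as attribute `truth`.
#' @export
simulate_ipd <- function(dist, n, admin_censor = 25, dropout_rate = 0.05,
                         seed = NULL) {
  stopifnot(n >= 1, admin_censor >= 0, dropout_rate >= 0, dropout_rate < 1)
  with_seed(seed, {
    u <- stats::runif(n)
    tev <- quantile_surv(dist, u)
    cens <- rep(admin_censor, n)
    if (dropout_rate > 0) {
      # monthly hazard such that P(dropout within 12 months) = dropout_rate
      h <- -log(1 - dropout_rate) / 12
      cens <- pmin(cens, stats::rexp(n, h))
    }
    out <- data.frame(time = pmax(pmin(tev, cens), 1e-9),
                      event = as.integer(tev <= cens))
    attr(out, "truth") <- dist
    attr(out, "seed") <- seed
    class(out) <- c("sim_ipd", "data.frame")
    out
  })
}

#' Kaplan-Meier estimate from individual patient data
#'
#' Product-limit estimator (via [survival::survfit()]) returned as a
#' [km_curve()] with numbers at risk.
#'
#' @param ipd Data frame with `time` and `event` columns, at least one
#'   event.
#' @export
km_estimate <- function(ipd) {
  stopifnot(all(c("time", "event") %in% names(ipd)))
  if (sum(ipd$event) < 1) stop("all observations censored", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  km_curve(sf$time, sf$surv, n_risk = sf$n.risk, clean = FALSE)
}

#' Emulate figure digitization of a survival curve
#'
#' Samples `n_points` coordinates on an even time grid over the curve's
#' support, perturbs the survival ordinates with truncated Gaussian jitter
#' (the read-off error of graph-digitizer software), and re-monotonizes.
#'
#' @param curve A `km_curve` (typically from [km_estimate()]).
#' @param n_points Number of coordinates to sample (`>= 2`).
#' @param jitter_sd Standard deviation of the ordinate jitter; 0 returns
#'   exact step-function values on the grid.
#' @param seed Integer seed.
#' @return A cleaned `km_curve` without numbers at risk.
#' @export
emulate_digitization <- function(curve, n_points = 40, jitter_sd = 0.005,
                                 seed = NULL) {
  stopifnot(n_points >= 2, jitter_sd >= 0)
  with_seed(seed, {
    grid <- seq(min(curve$time), max(curve$time), length.out = n_points)
    s <- km_survival_at(curve, grid)
    if (jitter_sd > 0) {
      jit <- stats::rnorm(n_points, 0, jitter_sd)
      jit <- pmin(pmax(jit, -3 * jitter_sd), 3 * jitter_sd)
      s <- s + jit
    }
    km_curve(grid, s, clean = TRUE)
  })
}

#' Write simulated IPD as CSV
#'
#' @param ipd A `sim_ipd` data frame.
#' @param path Output path.
#' @export
write_ipd_csv <- function(ipd, path) {
  utils::write.csv(ipd[, c("time", "event")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
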