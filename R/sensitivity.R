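# Deterministic and probabilistic sensitivity machinery.  Every uncertain
# parameter is addressed by its configuration path, so the same model code
# runs unchanged for base case, one-way analysis and Monte Carlo draws.

#' Enumerate uncertain parameters with their ranges
#'
#' One row per economic input: costs, utilities, adverse-event incidences
#' per arm, patient profile, and the discount rate (distribution `fixed`:
#' varied in one-way analysis only, never in the PSA).
#'
#' @param config A `run_config`.
#' @return Data frame with `path`, `label`, `base`, `low`, `high`,
#'   `dist`.
#' @export
param_ranges <- function(config) {
  rows <- list()
  add <- function(path, label, x) {
    rows[[length(rows) + 1]] <<- data.frame(
      path = path, label = label, base = x$base, low = x$min,
      high = x$max, dist = tolower(x$dist))
  }
  for (nm in names(config$costs)) {
    add(sprintf("costs.%s.base", nm), paste0("cost: ", nm),
        config$costs[[nm]])
  }
  for (nm in names(config$utilities)) {
    add(sprintf("utilities.%s.base", nm), paste0("utility: ", nm),
        config$utilities[[nm]])
  }
  for (nm in names(config$profile)) {
    add(sprintf("profile.%s.base", nm), paste0("profile: ", nm),
        config$profile[[nm]])
  }
  for (arm in names(config$arms)) {
    aes <- config$arms[[arm]]$adverse_events
    for (i in seq_along(aes)) {
      add(sprintf("arms.%s.adverse_events.%d.incidence.base", arm, i),
          sprintf("AE incidence (%s): %s", arm, aes[[i]]$event),
          aes[[i]]$incidence)
    }
  }
  add("settings.discount_rate.base", "discount rate",
      config$settings$discount_rate)
  do.call(rbind, rows)
}

model_icer <- function(config) run_model(config)$comparison$icer

#' One-way deterministic sensitivity analysis
#'
#' Each parameter is set to its low and high bound in turn (all others at
#' base) and the model re-run; entries are sorted by ICER spread, the
#' tornado-diagram ordering.
#'
#' @param config A `run_config`.
#' @param ranges Parameter table from [param_ranges()] (default: all).
#' @return Data frame of class `owsa_result` with `icer_low`,
#'   `icer_high`, `spread`, plus the base-case ICER as attribute
#'   `icer_base`.
#' @export
run_owsa <- function(config, ranges = param_ranges(config)) {
  base_icer <- model_icer(config)
  res <- lapply(seq_len(nrow(ranges)), function(i) {
    r <- ranges[i, ]
    lo <- model_icer(cfg_set(config, r$path, r$low))
    hi <- model_icer(cfg_set(config, r$path, r$high))
    data.frame(parameter = r$label, path = r$path,
               low = r$low, high = r$high,
               icer_low = lo, icer_high = hi,
               spread = abs(hi - lo))
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  attr(out, "icer_base") <- base_icer
  class(out) <- c("owsa_result", "data.frame")
  out
}

# moment-matched distribution sampler for one parameter row
psa_sampler <- function(base, low, high, dist) {
  s <- (high - low) / (2 * 1.96)
  if (dist == "fixed" || s <= 0) return(function(n) rep(base, n))
  switch(dist,
    beta = {
      if (base <= 0 || base >= 1 || s^2 >= base * (1 - base)) {
        # infeasible moment match: range-preserving fallback on [low, high]
        message(sprintf("beta moment match infeasible (base %g); %s",
                        base, "falling back to range-preserving Beta(2,2)"))
        return(function(n) low + (high - low) * stats::rbeta(n, 2, 2))
      }
      nu <- base * (1 - base) / s^2 - 1
      a <- base * nu; b <- (1 - base) * nu
      function(n) stats::rbeta(n, a, b)
    },
    gamma = {
      shape <- (base / s)^2
      rate <- base / s^2
      function(n) stats::rgamma(n, shape, rate)
    },
    normal = {
      lo_trunc <- 0.1 * base   # guard against nonphysical draws
      function(n) {
        plo <- stats::pnorm(lo_trunc, base, s)
        stats::qnorm(stats::runif(n, plo, 1), base, s)
      }
    },
    stop(sprintf("unknown PSA distribution '%s'", dist), call. = FALSE))
}

#' Draw parameter vectors for probabilistic sensitivity analysis
#'
#' Beta and Gamma parameters are moment-matched to the base value with
#' `SD = (high - low) / (2 x 1.96)` (ranges read as 95 percent intervals);
#' Normal parameters are truncated below at one tenth of the base;
#' `fixed` rows never vary.
#'
#' @param config A `run_config`.
#' @param n Number of draws.
#' @param seed Integer seed (same seed, same draws).
#' @param ranges Optional parameter table.
#' @return Matrix `n x n_parameters`; column names are parameter paths.
#' @export
sample_psa <- function(config, n = 1000, seed = NULL,
                       ranges = param_ranges(config)) {
  stopifnot(n >= 1)
  samplers <- lapply(seq_len(nrow(ranges)), function(i) {
    r <- ranges[i, ]
    if (r$dist == "fixed") function(n) rep(r$base, n)
    else psa_sampler(r$base, r$low, r$high, r$dist)
  })
  with_seed(seed, {
    draws <- vapply(samplers, function(f) f(n), numeric(n))
    if (n == 1) draws <- matrix(draws, nrow = 1)
    colnames(draws) <- ranges$path
    draws
  })
}

#' Probabilistic sensitivity analysis
#'
#' Evaluates the full model once per parameter draw and summarises the
#' incremental cloud.
#'
#' @param config A `run_config`.
#' @param n Number of Monte Carlo draws (ignored when `samples` given).
#' @param seed Integer seed.
#' @param samples Optional draw matrix from [sample_psa()].
#' @param runner Function mapping a configuration to a `model_run`
#'   (default [run_model()]; subgroup and scenario analyses substitute
#'   their own).
#' @return Data frame of class `psa_result` with per-draw arm costs and
#'   QALYs, incremental pairs and net-monetary-benefit at the configured
#'   threshold; attribute `prob_ce` holds the probability the
#'   intervention is cost-effective at that threshold.
#' @export
run_psa <- function(config, n = 1000, seed = NULL, samples = NULL,
                    runner = run_model) {
  if (is.null(samples)) samples <- sample_psa(config, n, seed)
  wtp <- config$settings$wtp
  res <- lapply(seq_len(nrow(samples)), function(i) {
    cfg <- config
    for (j in seq_len(ncol(samples))) {
      cfg <- cfg_set(cfg, colnames(samples)[j], samples[i, j])
    }
    run <- runner(cfg)
    a <- run$arms[[1]]; b <- run$arms[[2]]
    data.frame(draw = i,
               cost_int = a$cost, qaly_int = a$qaly,
               cost_comp = b$cost, qaly_comp = b$qaly,
               delta_cost = a$cost - b$cost,
               delta_qaly = a$qaly - b$qaly)
  })
  out <- do.call(rbind, res)
  out$icer <- ifelse(abs(out$delta_qaly) > 1e-12,
                     out$delta_cost / out$delta_qaly, NA_real_)
  out$inmb <- wtp * out$delta_qaly - out$delta_cost
  attr(out, "wtp") <- wtp
  attr(out, "prob_ce") <- mean(out$inmb > 0)
  attr(out, "seed") <- seed
  class(out) <- c("psa_result", "data.frame")
  out
}

#' Cost-effectiveness acceptability curve
#'
#' Probability that the intervention has the higher net monetary benefit
#' at each willingness-to-pay value.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Vector of thresholds.
#' @return Data frame `wtp`, `probability`.
#' @export
ceac <- function(psa, wtp_grid) {
  if (length(wtp_grid) == 0) stop("empty WTP grid", call. = FALSE)
  prob <- vapply(wtp_grid, function(w) {
    mean(w * psa$delta_qaly - psa$delta_cost > 0)
  }, 0)
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Joint price-threshold search
#'
#' Finds the common multiplier on the intervention's drug prices at which
#' the ICER equals the willingness-to-pay threshold (bisection to within
#' `tol` currency units of the threshold).  Cost is linear and strictly
#' increasing in the multiplier, so the crossing is unique when it
#' exists.
#'
#' @param config A `run_config`.
#' @param cost_items Configuration cost items to scale jointly (default:
#'   the two intervention drugs).
#' @param wtp Threshold (default: configured WTP).
#' @param tol Absolute ICER tolerance in currency/QALY.
#' @return List with `multiplier`, scaled `prices`, and the achieved
#'   `icer`; `feasible = FALSE` when no crossing exists on (0, 1].
#' @export
threshold_price <- function(config,
                            cost_items = c("ev_vial", "pembrolizumab_vial"),
                            wtp = config$settings$wtp, tol = 1) {
  base_prices <- vapply(cost_items,
                        function(it) config$costs[[it]]$base, 0)
  icer_at <- function(m) {
    cfg <- config
    for (i in seq_along(cost_items)) {
      cfg <- cfg_set(cfg, sprintf("costs.%s.base", cost_items[i]),
                     base_prices[i] * m)
    }
    model_icer(cfg)
  }
  if (icer_at(1) <= wtp) {
    return(list(multiplier = 1, prices = base_prices, icer = icer_at(1),
                feasible = TRUE))
  }
  lo <- 1e-6; hi <- 1
  if (icer_at(lo) > wtp) {
    return(list(multiplier = NA_real_, prices = NULL, icer = NA_real_,
                feasible = FALSE))
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    ic <- icer_at(mid)
    if (abs(ic - wtp) < tol) break
    if (ic > wtp) hi <- mid else lo <- mid
  }
  list(multiplier = mid, prices = base_prices * mid, icer = ic,
       feasible = TRUE)
}

#' Export sensitivity outputs as CSV
#'
#' Writes `tornado.csv`, `psa_draws.csv` and `ceac.csv`.
#'
#' @param owsa An `owsa_result` (or `NULL`).
#' @param psa A `psa_result` (or `NULL`).
#' @param ceac_curve A CEAC data frame (or `NULL`).
#' @param dir Output directory.
#' @export
write_sensitivity <- function(owsa = NULL, psa = NULL, ceac_curve = NULL,
                              dir = ".") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(owsa)) {
    utils::write.csv(as.data.frame(owsa), file.path(dir, "tornado.csv"),
                     row.names = FALSE)
  }
  if (!is.null(psa)) {
    utils::write.csv(as.data.frame(psa), file.path(dir, "psa_draws.csv"),
                     row.names = FALSE)
  }
  if (!is.null(ceac_curve)) {
    utils::write.csv(ceac_curve, file.path(dir, "ceac.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
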