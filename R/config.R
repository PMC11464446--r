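# Configuration: one structured file is the single source of truth for
# every model parameter.  The engine reads values from the configuration
# at run time, so sensitivity machinery can perturb any entry by path.

#' Path of the shipped base-case configuration
#' @export
default_config_path <- function() {
  system.file("extdata", "base_config.yaml", package = "psm3cea",
              mustWork = TRUE)
}

#' Load and validate a model configuration
#'
#' @param path YAML (or JSON) configuration file.
#' @return A validated configuration list of class `run_config`.
#' @export
load_config <- function(path = default_config_path()) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(cfg)
}

#' The shipped base-case configuration
#' @export
base_config <- function() load_config(default_config_path())

#' Write a configuration back to YAML
#'
#' Round-trips with [load_config()]: loading the written file yields
#' identical parameter values.
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 12)
  invisible(path)
}

#' Validate a configuration list
#'
#' Checks section presence, rejects unknown top-level keys, and enforces
#' range sanity (`min <= base <= max`, probabilities in `[0, 1]`,
#' non-negative costs).
#'
#' @param cfg A configuration list.
#' @return The list, classed `run_config`.
#' @export
validate_config <- function(cfg) {
  known <- c("settings", "profile", "policies", "costs", "utilities",
             "arms", "comparison", "psa", "subgroups", "scenarios")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop("unknown configuration keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  need <- c("settings", "profile", "policies", "costs", "utilities",
            "arms", "comparison")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    stop("missing configuration sections: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  chk_range <- function(x, nm, lo = -Inf, hi = Inf) {
    if (!all(c("base", "min", "max") %in% names(x))) {
      stop(sprintf("'%s' needs base/min/max", nm), call. = FALSE)
    }
    if (x$min > x$base || x$base > x$max) {
      stop(sprintf("'%s' violates min <= base <= max", nm), call. = FALSE)
    }
    if (x$min < lo || x$max > hi) {
      stop(sprintf("'%s' outside [%g, %g]", nm, lo, hi), call. = FALSE)
    }
  }
  for (nm in names(cfg$costs)) chk_range(cfg$costs[[nm]], nm, lo = 0)
  for (nm in names(cfg$utilities)) chk_range(cfg$utilities[[nm]], nm, 0, 1)
  for (arm in names(cfg$arms)) {
    for (ae in cfg$arms[[arm]]$adverse_events) {
      chk_range(ae$incidence, paste0(arm, ":", ae$event), 0, 1)
      if (!ae$cost_item %in% names(cfg$costs)) {
        stop(sprintf("AE '%s' references unknown cost item '%s'",
                     ae$event, ae$cost_item), call. = FALSE)
      }
    }
  }
  for (arm in unlist(cfg$comparison)) {
    if (!arm %in% names(cfg$arms)) {
      stop(sprintf("comparison references unknown arm '%s'", arm),
           call. = FALSE)
    }
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Get / set a configuration value by dotted path
#'
#' Numeric path components index lists (e.g.
#' `"arms.chemo.adverse_events.2.incidence.base"`).
#'
#' @param cfg A configuration list.
#' @param path Dotted path string.
#' @rdname cfg_path
#' @export
cfg_get <- function(cfg, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  for (p in parts) {
    idx <- suppressWarnings(as.integer(p))
    cfg <- if (!is.na(idx)) cfg[[idx]] else cfg[[p]]
    if (is.null(cfg)) stop(sprintf("unknown parameter path '%s'", path),
                           call. = FALSE)
  }
  cfg
}

#' @param value Replacement value.
#' @rdname cfg_path
#' @export
cfg_set <- function(cfg, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(x, parts) {
    p <- parts[[1]]
    idx <- suppressWarnings(as.integer(p))
    key <- if (!is.na(idx)) idx else p
    if (is.null(x[[key]])) stop(sprintf("unknown parameter path '%s'", path),
                                call. = FALSE)
    if (length(parts) == 1) x[[key]] <- value
    else x[[key]] <- rec(x[[key]], parts[-1])
    x
  }
  rec(cfg, parts)
}

settings_from_config <- function(config) {
  s <- config$settings
  model_settings(cycle_length_days = s$cycle_length_days,
                 horizon_years = s$horizon_years,
                 discount_rate = s$discount_rate$base,
                 wtp = s$wtp,
                 timing = s$timing,
                 background_mortality = s$background_mortality)
}

econ_from_config <- function(config) {
  p <- config$profile
  list(costs = config$costs,
       utilities = config$utilities,
       profile = patient_profile(p$weight$base, p$bsa$base, p$crcl$base),
       vial_policy = config$policies$vial_pricing,
       accrual = list(tests = config$policies$tests_accrual,
                      follow_up = config$policies$followup_accrual),
       bsc_proportion = config$policies$bsc_proportion)
}

dist_from_config <- function(sv) {
  do.call(surv_dist, c(list(sv$family), sv[setdiff(names(sv), "family")]))
}

#' Build the internal arm object from a configuration
#'
#' Resolves drug specifications (vial prices via their cost items),
#' adverse-event profiles and survival laws for one strategy.
#'
#' @param arm_name Name of the arm in `config$arms`.
#' @param config A `run_config`.
#' @param survival Optional list with `pfs`/`os` curve objects overriding
#'   the arm's fitted laws (used by subgroup analysis).
#' @export
build_arm <- function(arm_name, config, survival = NULL) {
  ac <- config$arms[[arm_name]]
  if (is.null(ac)) stop(sprintf("unknown arm '%s'", arm_name), call. = FALSE)
  drugs <- lapply(ac$drugs, function(d) {
    drug_spec(name = d$name, dosing = d$dosing,
              vial_size_mg = d$vial_size_mg,
              vial_price = config$costs[[d$vial_item]]$base,
              admins_per_cycle = d$admins_per_cycle,
              max_cycles = if (is.null(d$max_cycles)) Inf else d$max_cycles,
              mix_weight = if (is.null(d$mix_weight)) 1 else d$mix_weight,
              duration = d$duration)
  })
  ae <- data.frame(
    event = vapply(ac$adverse_events, `[[`, "", "event"),
    incidence = vapply(ac$adverse_events,
                       function(x) x$incidence$base, 0),
    cost_item = vapply(ac$adverse_events, `[[`, "", "cost_item"))
  sv <- if (!is.null(survival)) survival else {
    list(pfs = dist_from_config(ac$survival$pfs),
         os = dist_from_config(ac$survival$os))
  }
  list(name = arm_name, label = ac$label, drugs = drugs, ae = ae,
       survival = sv, cured_frac = NULL, treatment_stop_cycle = NULL)
}

#' Evaluate one strategy under a configuration
#'
#' Builds the occupancy trace from the arm's survival laws and accrues
#' discounted costs and QALYs.
#'
#' @inheritParams build_arm
#' @param cure Optional cure-model override, a list with `time_months`
#'   and `background_mortality`: patients still progression-free at the
#'   cure time stop treatment, keep one examination (tests item) per
#'   cycle, and die only at the background rate thereafter.
#' @return An `arm_result`.
#' @export
evaluate_arm <- function(arm_name, config, survival = NULL, cure = NULL) {
  settings <- settings_from_config(config)
  econ <- econ_from_config(config)
  arm <- build_arm(arm_name, config, survival)
  trace <- build_occupancy(arm$survival$pfs, arm$survival$os, settings)
  if (!is.null(cure)) {
    cm <- apply_cure_model(trace, arm$survival$os, settings,
                           cure$time_months, cure$background_mortality)
    trace <- cm$trace
    arm$cured_frac <- cm$cured_frac
    arm$treatment_stop_cycle <- cm$stop_cycle
  }
  accumulate(arm, trace, settings, econ)
}

# Scenario-4 machinery: freeze progression at the cure time.  The
# progression-free cohort at that point is considered cured: it stops
# treatment and thereafter dies only at the background rate; the
# progressed cohort keeps decaying with the conditional overall-survival
# hazard.
apply_cure_model <- function(trace, os_dist, settings, time_months,
                             background_annual) {
  k <- seq_len(settings$n_cycles)
  tk <- eval_times(settings, k)
  kc <- which(tk >= time_months)[1]
  if (is.na(kc)) {
    return(list(trace = trace, cured_frac = rep(0, length(k)),
                stop_cycle = NULL))
  }
  q_bg <- 1 - (1 - background_annual)^(settings$cycle_length_days / 365)
  cured0 <- trace$pfs[kc + 1]
  pd0 <- trace$pd[kc + 1]
  s0 <- survival_at(os_dist, tk[kc])
  post <- k >= kc
  cured <- numeric(length(k))
  cured[post] <- cured0 * (1 - q_bg)^(k[post] - kc)
  pd <- trace$pd[-1]
  pd[post] <- pd0 * survival_at(os_dist, tk[post]) / max(s0, 1e-12)
  pfs <- trace$pfs[-1]
  pfs[post] <- cured[post]
  dead <- 1 - pfs - pd
  out <- trace
  out$pfs <- c(1, pfs); out$pd <- c(0, pd); out$dead <- c(0, dead)
  out$new_deaths <- c(0, diff(out$dead))
  list(trace = out, cured_frac = cured, stop_cycle = kc - 1)
}

#' Run the full base-case comparison
#'
#' Evaluates both configured strategies and compares them at the
#' configured willingness-to-pay threshold.
#'
#' @param config A `run_config` (default: the shipped base case).
#' @return A list of class `model_run` with `arms` (named
#'   `arm_result`s), `comparison` (a `cea_comparison`) and the resolved
#'   `settings`.
#' @examples
#' \donttest{
#' res <- run_model(base_config())
#' res$comparison
#' }
#' @export
run_model <- function(config = base_config()) {
  settings <- settings_from_config(config)
  int <- evaluate_arm(config$comparison$intervention, config)
  com <- evaluate_arm(config$comparison$comparator, config)
  structure(list(
    arms = stats::setNames(list(int, com),
                           c(config$comparison$intervention,
                             config$comparison$comparator)),
    comparison = compare(int, com, settings$wtp),
    settings = settings,
    metadata = run_metadata(config)
  ), class = "model_run")
}

run_metadata <- function(config) {
  list(package_version = as.character(utils::packageVersion("psm3cea")),
       timing = config$settings$timing,
       vial_pricing = config$policies$vial_pricing,
       duration_rules = lapply(config$arms, function(a) {
         stats::setNames(lapply(a$drugs, `[[`, "duration"),
                         vapply(a$drugs, `[[`, "", "name"))
       }))
}

#' @export
print.model_run <- function(x, ...) {
  for (a in x$arms) print(a)
  print(x$comparison)
  invisible(x)
}

#' Write model results to JSON and CSV
#'
#' @param run A `model_run`.
#' @param dir Output directory (created if needed).
#' @export
write_results <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(
    arms = lapply(run$arms, function(a) {
      list(strategy = a$strategy, cost = a$cost, qaly = a$qaly,
           life_years = a$life_years, breakdown = as.list(a$breakdown))
    }),
    comparison = unclass(run$comparison),
    metadata = run$metadata)
  jsonlite::write_json(out, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA)
  tab <- do.call(rbind, lapply(run$arms, function(a) {
    data.frame(strategy = a$strategy, cost = a$cost, qaly = a$qaly,
               life_years = a$life_years)
  }))
  utils::write.csv(tab, file.path(dir, "results.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
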