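# Costing and outcome accrual: dosing arithmetic, vial pricing, per-cycle
# cost components, discounting, QALY accrual and comparative results.

#' Patient profile used for dosing arithmetic
#'
#' @param weight Body weight in kg.
#' @param bsa Body surface area in m^2.
#' @param crcl Creatinine clearance in mL/min (used by the Calvert
#'   formula for carboplatin).
#' @export
patient_profile <- function(weight = 65, bsa = 1.72, crcl = 70) {
  stopifnot(weight > 0, bsa > 0, crcl > 0)
  structure(list(weight = weight, bsa = bsa, crcl = crcl),
            class = "patient_profile")
}

#' Drug specification
#'
#' @param name Drug identifier.
#' @param dosing A list with `rule` one of `"per_kg"` (fields `mg_per_kg`,
#'   optional `cap_mg`), `"flat"` (`mg`), `"per_bsa"` (`mg_per_m2`), or
#'   `"calvert"` (`auc`; dose = AUC x (CrCl + 25) mg).
#' @param vial_size_mg,vial_price Vial size and unit price.
#' @param admins_per_cycle Administrations per model cycle.
#' @param max_cycles Hard cap on treated cycles (`Inf` = none).
#' @param mix_weight Fraction of the cohort receiving this drug (used for
#'   the cisplatin/carboplatin split).
#' @param duration Treatment-duration rule, a list with `rule` one of
#'   `"to_progression"` (on treatment while progression-free),
#'   `"median_cap"` (`median_months`: hard stop at the median duration),
#'   `"tot_loglogistic"` (`median_months`, `shape`: on-treatment fraction
#'   follows a log-logistic time-on-treatment curve, never exceeding PFS
#'   occupancy), or `"fixed_course"` (whole cohort treated each cycle up
#'   to `max_cycles`).
#' @export
drug_spec <- function(name, dosing, vial_size_mg, vial_price,
                      admins_per_cycle = 1, max_cycles = Inf,
                      mix_weight = 1,
                      duration = list(rule = "to_progression")) {
  stopifnot(vial_size_mg > 0, vial_price >= 0, admins_per_cycle >= 1,
            max_cycles >= 1, mix_weight >= 0, mix_weight <= 1)
  structure(list(name = name, dosing = dosing,
                 vial_size_mg = vial_size_mg, vial_price = vial_price,
                 admins_per_cycle = admins_per_cycle,
                 max_cycles = max_cycles, mix_weight = mix_weight,
                 duration = duration),
            class = "drug_spec")
}

#' Dose per administration in mg
#'
#' Applies the drug's dosing rule to a patient profile: weight-based with
#' an optional cap, flat, body-surface-area-based, or the Calvert formula
#' `AUC x (CrCl + 25)` for carboplatin.
#'
#' @param spec A [drug_spec()].
#' @param profile A [patient_profile()].
#' @export
dose_per_administration <- function(spec, profile) {
  d <- spec$dosing
  switch(d$rule,
    per_kg  = {
      dose <- d$mg_per_kg * profile$weight
      if (!is.null(d$cap_mg)) dose <- min(dose, d$cap_mg)
      dose
    },
    flat    = d$mg,
    per_bsa = d$mg_per_m2 * profile$bsa,
    calvert = d$auc * (profile$crcl + 25),
    stop(sprintf("unknown dosing rule '%s'", d$rule), call. = FALSE))
}

#' Acquisition cost of one administration
#'
#' @param dose_mg Administered dose.
#' @param vial_size_mg,vial_price Vial size and price.
#' @param policy `"whole_vial"` (ceiling; unused remainder wasted, the
#'   default) or `"linear"` (exact mg pricing).
#' @export
administration_cost <- function(dose_mg, vial_size_mg, vial_price,
                                policy = c("whole_vial", "linear")) {
  policy <- match.arg(policy)
  stopifnot(vial_size_mg > 0, dose_mg >= 0)
  vials <- dose_mg / vial_size_mg
  if (policy == "whole_vial") vials <- ceiling(vials)
  vials * vial_price
}

drug_cost_per_cycle <- function(spec, profile, policy) {
  dose <- dose_per_administration(spec, profile)
  spec$mix_weight * spec$admins_per_cycle *
    administration_cost(dose, spec$vial_size_mg, spec$vial_price, policy)
}

#' On-treatment fraction per cycle for one drug
#'
#' The fraction of the cohort accruing this drug's acquisition cost in
#' each cycle, per the drug's duration rule, always capped at
#' `max_cycles`.
#'
#' @param spec A [drug_spec()].
#' @param trace A `cohort_trace`.
#' @param settings A [model_settings()].
#' @return Numeric vector over cycles `1..n_cycles`.
#' @export
on_treatment_weight <- function(spec, trace, settings) {
  k <- seq_len(settings$n_cycles)
  pfs <- trace$pfs[-1]
  tk <- eval_times(settings, k)
  dur <- spec$duration
  w <- switch(dur$rule,
    to_progression = pfs,
    median_cap = pfs * (k <= round(dur$median_months / settings$cycle_months)),
    tot_loglogistic = pmin(pfs, 1 / (1 + (tk / dur$median_months)^dur$shape)),
    fixed_course = rep(1, length(k)),
    stop(sprintf("unknown duration rule '%s'", dur$rule), call. = FALSE))
  w * (k <= spec$max_cycles)
}

state_weight <- function(which, trace, drugs_active) {
  pfs <- trace$pfs[-1]; pd <- trace$pd[-1]
  switch(which,
         alive = pfs + pd,
         pfs = pfs,
         pd = pd,
         on_treatment = pfs * (drugs_active > 0),
         stop(sprintf("unknown accrual state '%s'", which), call. = FALSE))
}

#' Per-cycle undiscounted cost components for one arm
#'
#' Drug acquisition accrues on each drug's on-treatment fraction; tests
#' and routine follow-up on their configured states; best supportive care
#' on progressed patients scaled by the BSC proportion; terminal care on
#' incident deaths; adverse-event management once, in the first cycle.
#'
#' @param arm An internal arm object (see [build_arm()]).
#' @param trace The arm's `cohort_trace`.
#' @param settings A [model_settings()].
#' @param econ Economic inputs (costs, accrual rules, policies).
#' @return Matrix `n_cycles x categories` of undiscounted costs.
#' @export
cycle_cost_components <- function(arm, trace, settings, econ) {
  k <- seq_len(settings$n_cycles)
  n <- length(k)
  cost_of <- function(item) econ$costs[[item]]$base
  wmat <- vapply(arm$drugs, on_treatment_weight, numeric(n),
                 trace = trace, settings = settings)
  if (!is.null(arm$treatment_stop_cycle)) {
    wmat[k > arm$treatment_stop_cycle, ] <- 0
  }
  active <- if (length(arm$drugs)) rowSums(wmat > 0) else numeric(n)
  drug_cols <- vapply(seq_along(arm$drugs), function(i) {
    drug_cost_per_cycle(arm$drugs[[i]], econ$profile, econ$vial_policy) *
      wmat[, i]
  }, numeric(n))
  colnames(drug_cols) <- vapply(arm$drugs, `[[`, "", "name")
  fu_state <- state_weight(econ$accrual$follow_up, trace, active)
  tests_state <- state_weight(econ$accrual$tests, trace, active)
  if (!is.null(arm$cured_frac)) {
    # cured patients keep periodic examinations (tests) but exit
    # follow-up and treatment accrual
    fu_state <- pmax(fu_state - arm$cured_frac, 0)
  }
  ae_cost <- sum(arm$ae$incidence * vapply(arm$ae$cost_item, cost_of, 0))
  comp <- cbind(
    drug_cols,
    tests = cost_of("tests_per_cycle") * tests_state,
    follow_up = cost_of("followup_per_cycle") * fu_state,
    bsc = cost_of("bsc_per_cycle") * econ$bsc_proportion *
      state_weight("pd", trace, active),
    terminal = cost_of("terminal_care") * trace$new_deaths[-1],
    ae = c(ae_cost, rep(0, n - 1)))
  comp
}

#' Accrue discounted costs and QALYs for one arm
#'
#' Costs: sum over cycles of the discounted cost components.  QALYs: state
#' occupancy times state utility times cycle length, discounted, minus a
#' one-time incidence-weighted adverse-event disutility (one cycle's
#' duration, applied in cycle 1).
#'
#' @inheritParams cycle_cost_components
#' @return An `arm_result` with `cost`, `qaly`, undiscounted `life_years`
#'   and a per-category cost `breakdown`.
#' @export
accumulate <- function(arm, trace, settings, econ) {
  k <- seq_len(settings$n_cycles)
  d <- discount_factor(k, settings$discount_rate,
                       settings$cycle_length_days)
  comp <- cycle_cost_components(arm, trace, settings, econ)
  breakdown <- colSums(comp * d)
  u <- econ$utilities
  qaly <- sum(d * settings$cycle_years *
                (u$pfs$base * trace$pfs[-1] + u$pd$base * trace$pd[-1]))
  ae_dis <- sum(arm$ae$incidence) * u$ae_disutility$base *
    settings$cycle_years * d[1]
  structure(list(strategy = arm$label,
                 cost = sum(breakdown),
                 qaly = qaly - ae_dis,
                 life_years = life_years(trace, settings),
                 breakdown = breakdown,
                 ae_disutility = ae_dis),
            class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("<arm_result> %s: cost = %.2f, QALYs = %.4f, LY = %.3f\n",
              x$strategy, x$cost, x$qaly, x$life_years))
  invisible(x)
}

#' Compare two strategies
#'
#' Incremental cost, incremental QALYs, the ICER (computed from unrounded
#' internals), net monetary benefit per arm at the willingness-to-pay
#' threshold, and dominance flags.
#'
#' @param intervention,comparator `arm_result` objects.
#' @param wtp Willingness-to-pay threshold.
#' @return A `cea_comparison` list.
#' @export
compare <- function(intervention, comparator, wtp) {
  dc <- intervention$cost - comparator$cost
  de <- intervention$qaly - comparator$qaly
  status <- if (de > 0 && dc < 0) "dominant"
            else if (de < 0 && dc > 0) "dominated"
            else "tradeoff"
  icer <- if (abs(de) < 1e-12 || status != "tradeoff") NA_real_ else dc / de
  structure(list(
    intervention = intervention$strategy,
    comparator = comparator$strategy,
    delta_cost = dc, delta_qaly = de, icer = icer, status = status,
    wtp = wtp,
    nmb = c(intervention = wtp * intervention$qaly - intervention$cost,
            comparator = wtp * comparator$qaly - comparator$cost),
    cost_effective = (status == "dominant") ||
      (status == "tradeoff" && de > 0 && dc / de < wtp) ||
      (status == "tradeoff" && de < 0 && dc / de > wtp)
  ), class = "cea_comparison")
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat(sprintf("<cea_comparison> %s vs %s\n", x$intervention, x$comparator))
  cat(sprintf("  dCost = %.2f  dQALY = %.4f  ICER = %s  [%s]\n",
              x$delta_cost, x$delta_qaly,
              if (is.na(x$icer)) "undefined" else sprintf("%.2f", x$icer),
              x$status))
  cat(sprintf("  cost-effective at WTP %.0f: %s\n", x$wtp,
              x$cost_effective))
  invisible(x)
}
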