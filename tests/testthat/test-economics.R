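test_that("dosing rules reproduce hand arithmetic", {
  prof <- patient_profile(weight = 65, bsa = 1.72, crcl = 70)
  ev <- drug_spec("ev", list(rule = "per_kg", mg_per_kg = 1.25,
                             cap_mg = 125), 30, 1593.2)
  expect_equal(dose_per_administration(ev, prof), 81.25)
  expect_equal(dose_per_administration(ev, patient_profile(weight = 120)),
               125)   # cap binds
  carbo <- drug_spec("carbo", list(rule = "calvert", auc = 5), 100, 9.2)
  expect_equal(dose_per_administration(carbo, prof), 5 * (70 + 25))
  gem <- drug_spec("gem", list(rule = "per_bsa", mg_per_m2 = 1000),
                   1000, 48.1)
  expect_equal(dose_per_administration(gem, prof), 1720)
  pem <- drug_spec("pem", list(rule = "flat", mg = 200), 100, 2548.8)
  expect_equal(dose_per_administration(pem, prof), 200)
  bad <- drug_spec("x", list(rule = "per_mol"), 10, 1)
  expect_error(dose_per_administration(bad, prof), "unknown dosing rule")
})

test_that("whole-vial pricing rounds up; linear pricing is exact", {
  expect_equal(administration_cost(81.25, 30, 1593.2, "whole_vial"),
               3 * 1593.2)
  expect_equal(administration_cost(200, 100, 2548.8, "whole_vial"),
               5097.6)
  # dose at an exact vial multiple: identical under both policies
  expect_equal(administration_cost(90, 30, 1593.2, "whole_vial"),
               administration_cost(90, 30, 1593.2, "linear"))
  expect_equal(administration_cost(81.25, 30, 1593.2, "linear"),
               81.25 / 30 * 1593.2)
})

test_that("discount factors use the exact day-count exponent", {
  expect_equal(discount_factor(0:50, 0), rep(1, 51))
  expect_equal(discount_factor(0, 0.05), 1)
  expect_equal(discount_factor(261, 0.05), 0.481, tolerance = 1e-3)
  expect_equal(discount_factor(261, 0.05),
               (1.05)^(-(261 * 21) / 365), tolerance = 1e-15)
})

test_that("treatment stops at each drug's cap and duration rule", {
  cfg <- cached_config()
  s <- settings_from_config(cfg)
  arm <- build_arm("chemo", cfg)
  tr <- build_occupancy(arm$survival$pfs, arm$survival$os, s)
  gem <- arm$drugs[[1]]
  w <- on_treatment_weight(gem, tr, s)
  expect_true(all(w[7:length(w)] == 0))   # beyond the 6-cycle course
  expect_true(all(w[1:6] == 1))           # fixed course treats everyone
  # pembrolizumab: capped at 35 cycles and never above PFS occupancy
  armE <- build_arm("ev_pemb", cfg)
  trE <- build_occupancy(armE$survival$pfs, armE$survival$os, s)
  wp <- on_treatment_weight(armE$drugs[[2]], trE, s)
  expect_true(all(wp[36:length(wp)] == 0))
  expect_true(all(wp <= trE$pfs[-1] + 1e-12))
  # median-truncation alternative stops at round(median / cycle length)
  pem_med <- armE$drugs[[2]]
  pem_med$duration <- list(rule = "median_cap", median_months = 8.5)
  wm <- on_treatment_weight(pem_med, trE, s)
  expect_equal(sum(wm > 0), 12)
})

test_that("first-cycle adverse-event cost is the incidence-weighted sum", {
  cfg <- cached_config()
  s <- settings_from_config(cfg)
  econ <- econ_from_config(cfg)
  arm <- build_arm("chemo", cfg)
  tr <- build_occupancy(arm$survival$pfs, arm$survival$os, s)
  comp <- cycle_cost_components(arm, tr, s, econ)
  expected <- sum(c(0, 0.314, 0, 0.300, 0.090, 0.194, 0.065) *
                  c(73.6, 533.3, 155.0, 84.5, 84.5, 1057.2, 1057.2))
  expect_equal(unname(comp[1, "ae"]), expected, tolerance = 1e-12)
  expect_equal(0.314 * 533.3, 167.5, tolerance = 1e-3)  # anemia share
  expect_true(all(comp[-1, "ae"] == 0))
})

test_that("cost breakdown sums to the total for both arms", {
  run <- run_model(cached_config())
  for (a in run$arms) {
    expect_equal(sum(a$breakdown), a$cost, tolerance = 1e-6)
    expect_true(all(a$breakdown >= 0))
  }
})

test_that("QALYs vanish with zero utilities and are bounded by life-years", {
  cfg <- cached_config()
  for (u in c("pfs", "pd", "ae_disutility")) {
    cfg <- cfg_set(cfg, sprintf("utilities.%s.base", u), 0)
    cfg <- cfg_set(cfg, sprintf("utilities.%s.min", u), 0)
  }
  res0 <- evaluate_arm("ev_pemb", cfg)
  expect_equal(res0$qaly, 0)
  run <- run_model(cached_config())
  for (a in run$arms) {
    expect_gt(a$qaly, 0)
    expect_lt(a$qaly, a$life_years * 0.84)
  }
})

test_that("costs are linear in prices; utilities untouched", {
  cfg <- cached_config()
  run1 <- run_model(cfg)
  for (nm in names(cfg$costs)) {
    cfg <- cfg_set(cfg, sprintf("costs.%s.base", nm),
                   2 * cfg$costs[[nm]]$base)
    cfg <- cfg_set(cfg, sprintf("costs.%s.max", nm),
                   2.2 * cfg$costs[[nm]]$max)
  }
  run2 <- run_model(cfg)
  for (nm in names(run1$arms)) {
    expect_equal(run2$arms[[nm]]$cost, 2 * run1$arms[[nm]]$cost,
                 tolerance = 1e-9)
    expect_equal(run2$arms[[nm]]$qaly, run1$arms[[nm]]$qaly)
  }
})

test_that("discounting only shrinks totals", {
  cfg <- cached_config()
  run5 <- run_model(cfg)
  cfg0 <- cfg_set(cfg, "settings.discount_rate.base", 0)
  run0 <- run_model(cfg0)
  for (nm in names(run5$arms)) {
    expect_gt(run0$arms[[nm]]$cost, run5$arms[[nm]]$cost)
    expect_gt(run0$arms[[nm]]$qaly, run5$arms[[nm]]$qaly)
    expect_lte(run5$arms[[nm]]$qaly, run5$arms[[nm]]$life_years)
  }
})

test_that("comparison arithmetic, dominance and the rounding caveat", {
  mk <- function(cost, qaly) {
    structure(list(strategy = "x", cost = cost, qaly = qaly,
                   life_years = 5, breakdown = c(total = cost)),
              class = "arm_result")
  }
  # dividing the published rounded increments illustrates the rounding
  # gap: 352,050.58 / 1.52 differs from the unrounded-ratio convention
  cmp <- compare(mk(375420.24, 3.22), mk(23369.66, 1.70), 38133)
  expect_equal(cmp$delta_cost / round(cmp$delta_qaly, 2), 231612.2,
               tolerance = 1e-1)
  expect_equal(cmp$icer, cmp$delta_cost / cmp$delta_qaly)
  same <- compare(mk(100, 1), mk(100, 1), 38133)
  expect_true(is.na(same$icer))
  dom <- compare(mk(50, 2), mk(100, 1), 38133)
  expect_equal(dom$status, "dominant")
  expect_true(dom$cost_effective)
  expect_true(is.na(dom$icer))
  dtd <- compare(mk(200, 1), mk(100, 2), 38133)
  expect_equal(dtd$status, "dominated")
  expect_false(dtd$cost_effective)
  expect_equal(cmp$nmb[["intervention"]], 38133 * 3.22 - 375420.24)
})

test_that("shared cost categories cancel from the increment on equal traces", {
  cfg <- cached_config()
  cfg$arms$chemo$survival <- cfg$arms$ev_pemb$survival
  base <- run_model(cfg)
  bumped <- cfg_set(cfg, "costs.tests_per_cycle.base", 358.4 + 100)
  bumped <- cfg_set(bumped, "costs.tests_per_cycle.max", 700)
  run2 <- run_model(bumped)
  expect_equal(run2$comparison$delta_cost, base$comparison$delta_cost,
               tolerance = 1e-9)
})
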