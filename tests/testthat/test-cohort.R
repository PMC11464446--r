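base_settings <- function(...) model_settings(...)

test_that("occupancy conserves the cohort and respects monotonicity", {
  s <- base_settings()
  d <- fitted_dists()
  for (arm in list(c("ev_pfs", "ev_os"), c("ch_pfs", "ch_os"))) {
    tr <- build_occupancy(d[[arm[1]]], d[[arm[2]]], s)
    expect_equal(nrow(tr), s$n_cycles + 1)
    expect_equal(tr$pfs + tr$pd + tr$dead, rep(1, nrow(tr)),
                 tolerance = 1e-9)
    expect_true(all(diff(tr$dead) >= -1e-12))
    expect_true(all(diff(tr$pfs) <= 1e-12))
    expect_true(all(tr$pfs >= 0 & tr$pd >= 0 & tr$dead >= 0))
    expect_equal(unlist(tr[1, c("pfs", "pd", "dead")]),
                 c(pfs = 1, pd = 0, dead = 0))
  }
})

test_that("identical PFS and OS laws leave no progressed state", {
  s <- base_settings()
  d <- fitted_dists()$ev_os
  tr <- build_occupancy(d, d, s)
  expect_equal(max(abs(tr$pd)), 0)
})

test_that("most of the chemotherapy cohort dies within the 15-year horizon", {
  s <- base_settings()
  d <- fitted_dists()
  tr <- build_occupancy(d$ch_pfs, d$ch_os, s)
  expect_gt(tr$dead[nrow(tr)], 0.90)
})

test_that("trace occupancy equals direct survival evaluation", {
  s <- base_settings()
  d <- fitted_dists()
  tr <- build_occupancy(d$ev_pfs, d$ev_os, s)
  k <- c(1, 2, 50, 261)
  t_eval <- (k - 1) * s$cycle_months   # "start" timing
  expect_equal(tr$pfs[k + 1],
               pmin(survival_at(d$ev_pfs, t_eval),
                    survival_at(d$ev_os, t_eval)), tolerance = 1e-12)
  expect_equal(tr$dead[k + 1], 1 - survival_at(d$ev_os, t_eval),
               tolerance = 1e-12)
  s_end <- base_settings(timing = "end")
  tr_end <- build_occupancy(d$ev_pfs, d$ev_os, s_end)
  expect_equal(tr_end$pfs[2], survival_at(d$ev_pfs, s$cycle_months),
               tolerance = 1e-12)
})

test_that("a cohort microsimulation reproduces the trace occupancy", {
  # comonotone event times (shared uniform) realise the partitioned
  # structure: a subject progresses no later than it dies
  s <- base_settings()
  d <- fitted_dists()
  n <- 10000
  set.seed(123)
  u <- stats::runif(n)
  t_pfs <- quantile_surv(d$ev_pfs, u)
  t_os <- quantile_surv(d$ev_os, u)
  tr <- build_occupancy(d$ev_pfs, d$ev_os, s)
  for (k in c(1, 26, 261)) {
    tk <- (k - 1) * s$cycle_months
    for (st in c("pfs", "dead")) {
      p_sim <- if (st == "pfs") mean(pmin(t_pfs, t_os) > tk)
               else mean(t_os <= tk)
      p_mod <- tr[[st]][k + 1]
      se <- sqrt(max(p_sim * (1 - p_sim), 1e-6) / n)
      expect_lt(abs(p_mod - p_sim), 2 * se + 1e-9)
    }
  }
})

test_that("background mortality floor behaves as a hazard floor", {
  s0 <- base_settings()
  d <- fitted_dists()
  tr0 <- build_occupancy(d$ev_pfs, d$ev_os, s0)
  # zero floor: identity
  expect_equal(apply_mortality_floor(c(0.01, 0.2), 0), c(0.01, 0.2))
  # floored trace dies weakly faster, and QALY-bearing occupancy shrinks
  s2 <- base_settings(background_mortality = 0.02)
  tr2 <- build_occupancy(d$ev_pfs, d$ev_os, s2)
  expect_true(all(tr2$dead >= tr0$dead - 1e-12))
  expect_lt(sum(tr2$pfs + tr2$pd), sum(tr0$pfs + tr0$pd))
  expect_equal(tr2$pfs + tr2$pd + tr2$dead, rep(1, nrow(tr2)),
               tolerance = 1e-9)
  # a floor above every model hazard forces geometric decay at the floor
  q_ann <- 1 - (1 - 0.2)^(365 / 21)
  q_cyc <- 1 - (1 - q_ann)^(21 / 365)
  expect_equal(q_cyc, 0.2, tolerance = 1e-12)
  s3 <- base_settings(timing = "end", background_mortality = q_ann)
  tr3 <- build_occupancy(d$ev_os, d$ev_os, s3)
  expect_equal(tr3$dead[2:6], 1 - (1 - 0.2)^(1:5), tolerance = 1e-9)
  expect_error(base_settings(background_mortality = 1), "annual probability")
})

test_that("incident transitions difference the trace and telescope", {
  toy <- structure(
    data.frame(cycle = 0:2, time_months = c(0, 0.69, 1.38),
               pfs = c(1, 0.8, 0.55), pd = c(0, 0.1, 0.2),
               dead = c(0, 0.1, 0.25), new_deaths = c(0, 0.1, 0.15)),
    class = c("cohort_trace", "data.frame"))
  inc <- incident_transitions(toy)
  expect_equal(inc$new_deaths, c(0.1, 0.15))
  expect_equal(inc$new_progressions, c(0.2, 0.25))
  s <- base_settings()
  d <- fitted_dists()
  tr <- build_occupancy(d$ch_pfs, d$ch_os, s)
  inc <- incident_transitions(tr)
  expect_equal(sum(inc$new_deaths), tr$dead[nrow(tr)], tolerance = 1e-12)
  bad <- toy; bad$dead <- c(0, 0.3, 0.2)
  expect_error(incident_transitions(bad), "monotone")
})

test_that("restricted life expectancy matches integrating the OS curve", {
  s <- base_settings()
  d <- fitted_dists()
  tr <- build_occupancy(d$ch_pfs, d$ch_os, s)
  ly <- life_years(tr, s)
  os_integral <- stats::integrate(function(t) survival_at(d$ch_os, t),
                                  0, s$n_cycles * s$cycle_months,
                                  rel.tol = 1e-10)$value * 30.4375 / 365
  expect_lt(abs(ly - os_integral), s$cycle_years)
})

test_that("trace exports to CSV", {
  s <- model_settings(horizon_years = 1)
  d <- fitted_dists()
  tr <- build_occupancy(d$ch_pfs, d$ch_os, s)
  path <- tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- utils::read.csv(path)
  expect_equal(back$pfs, tr$pfs, tolerance = 1e-12)
})
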