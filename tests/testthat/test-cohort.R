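test_that("occupancy starts at (1,0,0) and respects closed forms", {
  os <- surv_spec("exponential", c(rate = 0.1))
  pfs <- surv_spec("exponential", c(rate = 0.2))
  st <- toy_settings(mpc = 21 / 30.4375)
  tr <- occupancy(toy_strategy(os, pfs), st)
  expect_equal(unlist(tr[1, c("pfs", "pd", "dead")]),
               c(pfs = 1, pd = 0, dead = 0))
  # pd(t) = exp(-0.1 t) - exp(-0.2 t) exactly
  t <- tr$time_surv_months
  expect_equal(tr$pd, exp(-0.1 * t) - exp(-0.2 * t), tolerance = 1e-12)
  expect_equal(nrow(tr), 174)
})

test_that("cumulative death hits 0.5 at the log-logistic median", {
  os <- surv_spec("loglogistic", c(shape = 1.5932, scale = 15.1363))
  pfs <- surv_spec("loglogistic", c(shape = 1.5899, scale = 7.6197))
  st <- econ_settings(0.05, 38042.49, cycle_length_days = 21,
                      horizon_years = 10,
                      months_per_cycle = 15.1363 / 22)   # cycle 22 = median
  tr <- occupancy(toy_strategy(os, pfs), st)
  expect_equal(tr$dead[23], 0.5, tolerance = 1e-12)
})

test_that("trace conservation and monotone death hold for all fixtures", {
  for (nm in fixture_names()) {
    cfg <- load_config(nm)
    st <- config_settings(cfg)
    for (arm in c("intervention", "comparator")) {
      tr <- occupancy(config_strategy(cfg, arm), st)
      expect_equal(nrow(tr), 174)
      expect_true(all(abs(tr$pfs + tr$pd + tr$dead - 1) < 1e-9))
      expect_true(all(diff(tr$dead) >= -1e-12))
      expect_true(all(tr$pfs >= 0 & tr$pfs <= 1 & tr$pd >= 0 & tr$pd <= 1))
    }
  }
})

test_that("undiscounted unit-utility QALYs equal restricted mean survival", {
  mu <- 0.05    # per month
  os <- surv_spec("exponential", c(rate = mu))
  stg <- toy_strategy(os, os)
  st <- econ_settings(0, 1000, months_per_cycle = 21 / 30.4375,
                      half_cycle_correction = TRUE)
  ut <- utility_inputs(1, 1)
  q <- accumulate_qalys(occupancy(stg, st), ut, st)
  mu_y <- mu * 12
  expect_equal(q, (1 - exp(-mu_y * 10)) / mu_y, tolerance = 0.01)
})

test_that("discounted exponential QALYs match the continuous closed form", {
  mu <- 0.05; r <- 0.05
  os <- surv_spec("exponential", c(rate = mu))
  st <- econ_settings(r, 1000, months_per_cycle = 21 / 30.4375,
                      half_cycle_correction = TRUE)
  ut <- utility_inputs(0.8, 0.8)
  q <- accumulate_qalys(occupancy(toy_strategy(os, os), st), ut, st)
  a <- mu * 12 + log(1 + r)
  expect_lt(abs(q / (0.8 * (1 - exp(-a * 10)) / a) - 1), 0.01)
})

test_that("QALYs fall with the discount rate and rise with utilities", {
  cfg <- load_config("china_itt")
  st1 <- config_settings(cfg)
  st2 <- st1; st2$discount_rate_annual <- 2 * st1$discount_rate_annual
  stg <- config_strategy(cfg, "intervention")
  ut <- config_utilities(cfg)
  tr <- occupancy(stg, st1)
  expect_lt(accumulate_qalys(tr, ut, st2), accumulate_qalys(tr, ut, st1))
  ut2 <- utility_inputs(ut$u_pfs + 0.05, ut$u_pd, ut$ae_disutilities)
  expect_gt(accumulate_qalys(tr, ut2, st1), accumulate_qalys(tr, ut, st1))
  # cost side also falls with discounting
  expect_lt(accumulate_costs(tr, stg, st2), accumulate_costs(tr, stg, st1))
})

test_that("zero unit costs give zero total cost", {
  os <- surv_spec("exponential", c(rate = 0.1))
  stg <- toy_strategy(os, os)
  st <- toy_settings()
  expect_equal(as.numeric(accumulate_costs(occupancy(stg, st), stg, st)), 0)
})

test_that("end-of-life cost is bounded by its discounted unit cost", {
  os <- surv_spec("exponential", c(rate = 0.3))  # nearly everyone dies
  stg <- toy_strategy(os, os, eol = 1460.30)
  st <- toy_settings()
  tot <- as.numeric(accumulate_costs(occupancy(stg, st), stg, st))
  expect_lt(tot, 1460.30)
  expect_gt(tot, 0.8 * 1460.30)
})

test_that("adverse-event costs accrue once at the trial incidences", {
  inc <- c(anemia = 0.0502, decreased_platelet_count = 0.1124,
           decreased_neutrophil_count = 0.1185,
           hand_foot_syndrome = 0.0301, decreased_appetite = 0.0281)
  cost <- c(anemia = 669.45, decreased_platelet_count = 1054.22,
            decreased_neutrophil_count = 544.19,
            hand_foot_syndrome = 12.97, decreased_appetite = 102.73)
  expected <- sum(inc * cost)   # independent arithmetic
  os <- surv_spec("exponential", c(rate = 0.1))
  stg <- toy_strategy(os, os, ae_incidence = inc, ae_costs = cost)
  st <- toy_settings()
  tot <- accumulate_costs(occupancy(stg, st), stg, st)
  expect_equal(as.numeric(tot), expected, tolerance = 1e-9)
  expect_equal(unname(attr(tot, "components")["adverse_events"]), expected,
               tolerance = 1e-9)
  expect_equal(expected, 219.864, tolerance = 1e-3)
})

test_that("total cost is linear: doubling every unit cost doubles it", {
  cfg <- load_config("china_itt")
  st <- config_settings(cfg)
  stg1 <- config_strategy(cfg, "intervention")
  cfg2 <- cfg
  for (p in c("arms.intervention.drug_costs_per_cycle.tislelizumab",
              "arms.intervention.drug_costs_per_cycle.oxaliplatin",
              "arms.intervention.drug_costs_per_cycle.capecitabine",
              "arms.intervention.drug_costs_per_cycle.fluorouracil",
              "arms.intervention.drug_costs_per_cycle.cisplatin",
              "shared_costs.subsequent_per_cycle.ramucirumab_paclitaxel",
              "shared_costs.best_supportive_care_per_cycle",
              "shared_costs.end_of_life", "shared_costs.laboratory_per_cycle",
              "shared_costs.ct_per_assessment",
              "shared_costs.administration.per_unit")) {
    cfg2 <- set_param(cfg2, p, 2 * get_param(cfg, p))
  }
  for (ae in names(cfg$shared_costs$ae_costs)) {
    p <- paste0("shared_costs.ae_costs.", ae)
    cfg2 <- set_param(cfg2, p, 2 * get_param(cfg, p))
  }
  stg2 <- config_strategy(cfg2, "intervention")
  tr <- occupancy(stg1, st)
  c1 <- as.numeric(accumulate_costs(tr, stg1, st))
  c2 <- as.numeric(accumulate_costs(tr, stg2, st))
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
})

test_that("run_strategy returns consistent accumulators and trace", {
  cfg <- load_config("china_itt")
  run <- run_strategy(config_strategy(cfg, "intervention"),
                      config_utilities(cfg), config_settings(cfg))
  expect_s3_class(run, "psm_run")
  expect_equal(sum(run$trace$disc_cost), run$cost, tolerance = 1e-9)
  expect_equal(sum(run$trace$disc_qaly), run$qaly, tolerance = 1e-9)
  expect_equal(as.numeric(sum(run$components)), run$cost, tolerance = 1e-9)
})

test_that("subsequent-treatment attribution modes are ordered sensibly", {
  cfg <- load_config("china_itt")
  st <- config_settings(cfg)
  ut <- config_utilities(cfg)
  cost_for <- function(mode) {
    cfg$arms$intervention$subsequent_attribution <- mode
    run_strategy(config_strategy(cfg, "intervention"), ut, st)$cost
  }
  c_pd <- cost_for("per_pd_cycle")
  c_fd <- cost_for("fixed_duration")
  c_ot <- cost_for("one_time")
  # a bounded 6-cycle course costs less than paying every progressed cycle
  expect_lt(c_fd, c_pd)
  # charging the course undiscounted at progression costs at least as much
  # as spreading it (discounting), but far less than per-cycle-forever
  expect_gt(c_ot, c_fd - 1e-9)
  expect_lt(c_ot, c_pd)
})
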