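test_that("parameter ranges validate and substitute inconsistent bounds", {
  rg <- param_range("a.b", 10, 8, 12, "gamma")
  expect_false(rg$substituted)
  rg2 <- param_range("a.b", 10, 12, 8, "gamma")   # inconsistent
  expect_true(rg2$substituted)
  expect_equal(c(rg2$low, rg2$high), c(8, 12))
  expect_error(param_range("u", 1.4, 1, 2, "beta"), "beta")
})

test_that("the published inconsistent rows are flagged on loading", {
  rgs <- config_ranges(load_config("china_itt"))
  subbed <- vapply(rgs, function(r) r$substituted, TRUE)
  paths <- vapply(rgs, function(r) r$path, "")
  expect_true(any(subbed))
  expect_true(grepl("best_supportive_care",
                    paste(paths[subbed], collapse = " ")))
  expect_true(sum(subbed) >= 4)   # BSC + three scrambled AE-risk rows
})

test_that("moment-matched samplers have the requested mean and sd", {
  rg <- param_range("x", 355.78, 284.62, 426.94, "gamma")
  s <- build_distribution(rg)
  set.seed(1)
  x <- s(1e6)
  expect_lt(abs(mean(x) / 355.78 - 1), 0.005)
  expect_lt(abs(sd(x) / ((426.94 - 284.62) / 3.92) - 1), 0.01)
  # beta stays in [0,1] and respects a degenerate sd
  rb <- build_distribution(param_range("u", 0.797, 0.64, 0.96, "beta"))
  set.seed(2)
  u <- rb(1e5)
  expect_true(all(u >= 0 & u <= 1))
  expect_lt(abs(mean(u) - 0.797), 0.005)
  expect_equal(build_distribution(param_range("u", 0.5, 0.5, 0.5,
                                              "beta"))(5), rep(0.5, 5))
})

test_that("one-way sensitivity analysis is sorted and linear in pure costs", {
  cfg <- load_config("china_itt")
  base <- run_comparison(cfg)$comparison
  ranges <- list(
    param_range("shared_costs.end_of_life", 1460.30, 1168.24, 1752.36,
                "gamma"),
    param_range("arms.comparator.drug_costs_per_cycle.oxaliplatin",
                168.02, 134.42, 201.62, "gamma"),
    param_range("utilities.u_pfs", 0.797, 0.64, 0.96, "beta"),
    # zero-effect parameter: zero at baseline and both bounds
    param_range("shared_costs.ae_costs.hand_foot_syndrome", 0, 0, 0,
                "fixed"))
  cfg0 <- set_param(cfg, "shared_costs.ae_costs.hand_foot_syndrome", 0)
  tor <- owsa(cfg0, ranges)
  expect_true(all(diff(tor$span) <= 1e-9))
  expect_equal(tor$path[nrow(tor)], "shared_costs.ae_costs.hand_foot_syndrome")
  expect_equal(tor$span[nrow(tor)], 0)

  # comparator-only cost: ICER moves by exactly -(cost change)/deltaE
  i <- match("arms.comparator.drug_costs_per_cycle.oxaliplatin", tor$path)
  hi_cfg <- set_param(cfg0, tor$path[i], tor$high[i])
  dc0 <- run_comparison(cfg0)$comparison
  dc1 <- run_comparison(hi_cfg)$comparison
  change <- dc1$cost_comparator - dc0$cost_comparator
  expect_equal(tor$icer_at_high[i], dc0$icer - change / dc0$delta_qaly,
               tolerance = 1e-9)
  expect_equal(dc1$delta_qaly, dc0$delta_qaly, tolerance = 1e-12)

  # symmetric +/-20% pure-cost range: spans symmetric about the base ICER
  sym <- param_range("shared_costs.end_of_life", 1460.30,
                     0.8 * 1460.30, 1.2 * 1460.30, "gamma")
  tor2 <- owsa(cfg0, list(sym))
  base0 <- attr(tor2, "base_icer")
  expect_equal(tor2$icer_at_high - base0, base0 - tor2$icer_at_low,
               tolerance = 1e-6)
  expect_error(owsa(cfg0, list(param_range("no.such.path", 1, 0.5, 2,
                                           "gamma"))),
               "path")
})

test_that("PSA is reproducible under a fixed seed", {
  cfg <- load_config("china_itt")
  a <- psa(cfg, n = 25, seed = 42)
  b <- psa(cfg, n = 25, seed = 42)
  expect_identical(a$delta_cost, b$delta_cost)
  expect_identical(attr(a, "draws"), attr(b, "draws"))
  c2 <- psa(cfg, n = 25, seed = 43)
  expect_false(identical(a$delta_cost, c2$delta_cost))
})

test_that("degenerate PSA distributions reproduce the base case", {
  cfg <- load_config("china_itt")
  ranges <- list(param_range("utilities.u_pfs", 0.797, 0.797, 0.797,
                             "fixed"),
                 param_range("shared_costs.end_of_life", 1460.30, 1460.30,
                             1460.30, "fixed"))
  r <- psa(cfg, n = 3, seed = 1, ranges = ranges)
  base <- run_comparison(cfg)$comparison
  expect_equal(r$delta_cost, rep(base$delta_cost, 3), tolerance = 1e-12)
  expect_equal(r$delta_qaly, rep(base$delta_qaly, 3), tolerance = 1e-12)
})

test_that("CEAC has the right limits and stays within [0,1]", {
  cfg <- load_config("china_itt")
  r <- psa(cfg, n = 200, seed = 7)
  cc <- ceac(r, wtp_grid = c(0, 1e4, 38042.49, 1e6, 1e9))
  expect_true(all(cc$prob_cost_effective >= 0 &
                    cc$prob_cost_effective <= 1))
  expect_equal(cc$prob_cost_effective[1], mean(r$delta_cost < 0))
  expect_equal(cc$prob_cost_effective[5],
               mean(r$delta_qaly > 0 |
                      (r$delta_qaly == 0 & r$delta_cost < 0)),
               tolerance = 0.02)
  # monotone when all draws gain QALYs
  if (all(r$delta_qaly > 0)) {
    expect_true(all(diff(cc$prob_cost_effective) >= 0))
  }
})

test_that("price threshold matches a bisection oracle and inverts", {
  cfg <- load_config("china_itt")
  th <- price_threshold(cfg, price_range = c(0, 500))
  expect_false(is.na(th$threshold))
  icer_at <- function(p) {
    run_comparison(set_tislelizumab_price(cfg, p))$comparison$icer
  }
  lambda <- cfg$settings$wtp_per_qaly
  lo <- 0; hi <- 500
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (icer_at(mid) < lambda) lo <- mid else hi <- mid
  }
  expect_lt(abs(th$threshold - (lo + hi) / 2), 0.01)
  expect_lt(abs(icer_at(th$threshold) - lambda), 1)
})

test_that("no price threshold is reported when the QALY gain is negative", {
  cfg <- load_config("china_itt")
  # flip the arms' survival so the intervention loses QALYs
  tmp <- cfg$arms$intervention
  cfg$arms$intervention$os <- cfg$arms$comparator$os
  cfg$arms$intervention$pfs <- cfg$arms$comparator$pfs
  cfg$arms$comparator$os <- tmp$os
  cfg$arms$comparator$pfs <- tmp$pfs
  th <- price_threshold(cfg, price_range = c(0, 500))
  expect_true(is.na(th$threshold))
})

test_that("scenario analysis swaps regimens in both arms", {
  cfg <- load_config("china_itt")
  base <- run_comparison(cfg)$comparison
  same <- scenario_subsequent(cfg, "ramucirumab_paclitaxel")$comparison
  expect_equal(same$icer, base$icer, tolerance = 1e-12)
  # zero-cost BSC scenario: cheaper PD state, and the arm progressing more
  # saves more, raising the ICER here (comparator progresses more)
  cfg0 <- set_param(cfg,
                    "shared_costs.subsequent_per_cycle.best_supportive_care",
                    0)
  cfg0 <- set_param(cfg0, "shared_costs.best_supportive_care_per_cycle", 0)
  bsc <- scenario_subsequent(cfg0, "best_supportive_care")$comparison
  ram <- scenario_subsequent(cfg0, "ramucirumab_paclitaxel")$comparison
  expect_false(bsc$icer == ram$icer)
  expect_lt(bsc$delta_cost, ram$delta_cost + 1e-9)
  expect_error(scenario_subsequent(cfg, "chimeric_antigen"), "unknown")
})

test_that("china scenario ICERs stay in the published band", {
  cfg <- load_config("china_itt")
  regs <- c("ramucirumab_paclitaxel", "best_supportive_care", "paclitaxel",
            "docetaxel", "nab_paclitaxel", "irinotecan")
  icers <- vapply(regs, function(rg)
    scenario_subsequent(cfg, rg)$comparison$icer, 0)
  expect_true(all(icers > 20000 & icers < 60000))
})
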