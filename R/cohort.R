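#' Economic settings for the cohort model
#'
#' @param discount_rate_annual Annual discount rate (0.05 China, 0.03 US).
#' @param wtp_per_qaly Willingness-to-pay threshold lambda, $/QALY.
#' @param cycle_length_days Model cycle length in days (default 21).
#' @param horizon_years Simulation horizon (default 10 years, i.e. 174
#'   three-week cycles).
#' @param months_per_cycle Months of survival-curve time the model advances
#'   per cycle. The default 1.0 advances the monthly-parameterized fitted
#'   curves one month per cycle while calendar time (discounting, QALY and
#'   cost accrual) advances 21 days; this is the convention under which the
#'   packaged base-case results are defined. Set to `21/30.4375` for a
#'   strict calendar-time mapping.
#' @param half_cycle_correction Average adjacent cycle occupancies for
#'   continuous accruals (default off).
#' @return An `econ_settings` object.
#' @export
econ_settings <- function(discount_rate_annual, wtp_per_qaly,
                          cycle_length_days = 21, horizon_years = 10,
                          months_per_cycle = 1.0,
                          half_cycle_correction = FALSE) {
  stopifnot(discount_rate_annual >= 0, discount_rate_annual <= 1,
            horizon_years > 0, wtp_per_qaly > 0, cycle_length_days > 0,
            months_per_cycle > 0)
  n_cycles <- round(horizon_years * 365.25 / cycle_length_days)
  structure(list(cycle_length_days = cycle_length_days,
                 horizon_years = horizon_years,
                 discount_rate_annual = discount_rate_annual,
                 wtp_per_qaly = wtp_per_qaly,
                 months_per_cycle = months_per_cycle,
                 half_cycle_correction = isTRUE(half_cycle_correction),
                 n_cycles = n_cycles),
            class = "econ_settings")
}

#' Health-state utilities and adverse-event disutilities
#'
#' @param u_pfs Utility per year in the progression-free state (0.797).
#' @param u_pd Utility per year after progression (0.577).
#' @param ae_disutilities Named vector of utility decrements per adverse
#'   event (applied once, in the first cycle, scaled by one cycle length).
#' @return A `utility_inputs` object.
#' @export
utility_inputs <- function(u_pfs, u_pd, ae_disutilities = numeric(0)) {
  stopifnot(u_pfs >= 0, u_pfs <= 1, u_pd >= 0, u_pd <= 1,
            all(ae_disutilities >= 0))
  structure(list(u_pfs = u_pfs, u_pd = u_pd,
                 ae_disutilities = unlist(ae_disutilities)),
            class = "utility_inputs")
}

#' Per-arm strategy inputs
#'
#' All treatment, cost and adverse-event inputs for one model arm. Costs are
#' US dollars. Treatment rules: platinum/fluoropyrimidine doublets stop
#' after `max_chemo_cycles`; the oxaliplatin+capecitabine share may continue
#' capecitabine maintenance until progression; tislelizumab (when present)
#' stops at `tislelizumab_max_years` (use `Inf` for treatment until
#' progression).
#'
#' @param label Arm label.
#' @param os,pfs [surv_spec()] objects for overall and progression-free
#'   survival.
#' @param drug_costs Named list of per-cycle drug costs (`tislelizumab`
#'   optional; `oxaliplatin`, `capecitabine`, `fluorouracil`, `cisplatin`).
#' @param chemo_mix_oxcap Fraction of the arm on oxaliplatin+capecitabine
#'   (the remainder receives cisplatin+fluorouracil).
#' @param max_chemo_cycles Platinum/fluoropyrimidine cap (default 6 cycles).
#' @param tislelizumab_max_years Stopping time for tislelizumab, years.
#' @param capecitabine_maintenance Continue capecitabine for the ox+cap
#'   share after the chemotherapy cap (default TRUE).
#' @param p_subsequent Fraction receiving active subsequent treatment after
#'   progression (the remainder receives best supportive care).
#' @param subsequent_regimen Label of the subsequent regimen.
#' @param subsequent_cost_per_cycle Per-cycle cost of that regimen.
#' @param subsequent_attribution `"per_pd_cycle"` (default: the subsequent
#'   fraction accrues the regimen cost every progressed cycle),
#'   `"fixed_duration"` (a course of `subsequent_duration_cycles` from
#'   progression) or `"one_time"` (the whole course charged at progression).
#' @param subsequent_duration_cycles Course length for the non-default
#'   attribution modes (default 6).
#' @param bsc_cost_per_cycle Best-supportive-care cost per progressed cycle.
#' @param end_of_life_cost One-time terminal-care cost per death.
#' @param administration List: `list(mode = "per_unit", per_unit = x)` or
#'   `list(mode = "hours", first_hour = x, additional_hour = y)` (one
#'   administration event per on-treatment cycle).
#' @param laboratory_cost_per_cycle Routine laboratory cost, applied to all
#'   alive occupancy each cycle.
#' @param ct_cost_per_assessment Enhanced CT cost per scheduled tumor
#'   assessment, applied to alive occupancy.
#' @param assessment_schedule List with `interval_weeks_initial` (6),
#'   `initial_period_weeks` (48) and `interval_weeks_later` (9).
#' @param ae_incidence,ae_costs Named vectors over the same adverse events
#'   (grade >= 3, incidence > 3 percent); costs accrue once in cycle 1.
#' @return A `strategy_inputs` object.
#' @export
strategy_inputs <- function(label, os, pfs, drug_costs, chemo_mix_oxcap,
                            max_chemo_cycles = 6,
                            tislelizumab_max_years = Inf,
                            capecitabine_maintenance = TRUE,
                            p_subsequent, subsequent_regimen,
                            subsequent_cost_per_cycle,
                            subsequent_attribution = "per_pd_cycle",
                            subsequent_duration_cycles = 6,
                            bsc_cost_per_cycle, end_of_life_cost,
                            administration, laboratory_cost_per_cycle,
                            ct_cost_per_assessment,
                            assessment_schedule = list(
                              interval_weeks_initial = 6,
                              initial_period_weeks = 48,
                              interval_weeks_later = 9),
                            ae_incidence = numeric(0),
                            ae_costs = numeric(0)) {
  .check_spec(os); .check_spec(pfs)
  subsequent_attribution <- match.arg(subsequent_attribution,
                                      c("per_pd_cycle", "fixed_duration",
                                        "one_time"))
  drug_costs <- lapply(drug_costs, as.numeric)
  costs <- c(unlist(drug_costs), subsequent_cost_per_cycle,
             bsc_cost_per_cycle, end_of_life_cost,
             laboratory_cost_per_cycle, ct_cost_per_assessment,
             unlist(ae_costs), unlist(administration[names(administration)
                                                     != "mode"]))
  if (any(costs < 0)) stop("all costs must be >= 0", call. = FALSE)
  stopifnot(chemo_mix_oxcap >= 0, chemo_mix_oxcap <= 1,
            p_subsequent >= 0, p_subsequent <= 1,
            all(ae_incidence >= 0 & ae_incidence <= 1))
  ae_incidence <- unlist(ae_incidence); ae_costs <- unlist(ae_costs)
  if (length(ae_incidence) && !all(names(ae_incidence) %in% names(ae_costs))) {
    stop("missing cost entry for adverse event(s): ",
         paste(setdiff(names(ae_incidence), names(ae_costs)), collapse = ", "),
         call. = FALSE)
  }
  structure(list(label = label, os = os, pfs = pfs, drug_costs = drug_costs,
                 chemo_mix_oxcap = chemo_mix_oxcap,
                 max_chemo_cycles = max_chemo_cycles,
                 tislelizumab_max_years = tislelizumab_max_years,
                 capecitabine_maintenance = isTRUE(capecitabine_maintenance),
                 p_subsequent = p_subsequent,
                 subsequent_regimen = subsequent_regimen,
                 subsequent_cost_per_cycle = subsequent_cost_per_cycle,
                 subsequent_attribution = subsequent_attribution,
                 subsequent_duration_cycles = subsequent_duration_cycles,
                 bsc_cost_per_cycle = bsc_cost_per_cycle,
                 end_of_life_cost = end_of_life_cost,
                 administration = administration,
                 laboratory_cost_per_cycle = laboratory_cost_per_cycle,
                 ct_cost_per_assessment = ct_cost_per_assessment,
                 assessment_schedule = assessment_schedule,
                 ae_incidence = ae_incidence, ae_costs = ae_costs),
            class = "strategy_inputs")
}

#' Partitioned-survival state occupancy
#'
#' At cycle k the model reads state occupancy directly off the two marginal
#' curves: `pfs = min(S_PFS, S_OS)`, `dead = 1 - S_OS`, `pd` the residual.
#' The curves are evaluated at `k * months_per_cycle` months; calendar time
#' (used for discounting and accrual) advances `cycle_length_days` per
#' cycle.
#'
#' @param strategy A [strategy_inputs()].
#' @param settings An [econ_settings()].
#' @return Data frame (`cohort_trace`): `cycle`, `time_years`,
#'   `time_surv_months`, `pfs`, `pd`, `dead`, `inc_death`, `inc_prog`.
#' @export
occupancy <- function(strategy, settings) {
  k <- seq_len(settings$n_cycles) - 1
  t_surv <- k * settings$months_per_cycle
  t_yr <- k * settings$cycle_length_days / 365.25
  s_os <- surv_prob(strategy$os, t_surv)
  s_pfs <- surv_prob(strategy$pfs, t_surv)
  pfs <- pmin(s_pfs, s_os)
  dead <- 1 - s_os
  pd <- pmax(0, 1 - pfs - dead)
  tr <- data.frame(cycle = k, time_years = t_yr, time_surv_months = t_surv,
                   pfs = pfs, pd = pd, dead = dead,
                   inc_death = c(dead[1], diff(dead)),
                   inc_prog = pmax(0, c(0, -diff(pfs))))
  class(tr) <- c("cohort_trace", "data.frame")
  tr
}

.disc <- function(trace, settings) {
  (1 + settings$discount_rate_annual)^(-trace$time_years)
}

# continuous-accrual occupancy, optionally half-cycle corrected
.accrual_occ <- function(x, settings) {
  if (!settings$half_cycle_correction) return(x)
  n <- length(x)
  (x + c(x[-1], x[n])) / 2
}

#' Discounted quality-adjusted life years of a cohort trace
#'
#' `QALY = sum_k d(t_k) (u_pfs pfs_k + u_pd pd_k) dt` with
#' `d(t) = (1+r)^(-t)` evaluated at the cycle start and `dt` one cycle in
#' years, minus the adverse-event disutility decrement (incidence times
#' decrement times one cycle length), applied in the first cycle only.
#'
#' @param trace A trace from [occupancy()].
#' @param utilities A [utility_inputs()].
#' @param settings An [econ_settings()].
#' @param ae_incidence Named incidence vector for the arm (optional; names
#'   must match `utilities$ae_disutilities`).
#' @return Discounted QALYs (scalar).
#' @export
accumulate_qalys <- function(trace, utilities, settings,
                             ae_incidence = NULL) {
  d <- .disc(trace, settings)
  dt <- settings$cycle_length_days / 365.25
  pfs <- .accrual_occ(trace$pfs, settings)
  pd <- .accrual_occ(trace$pd, settings)
  q <- sum(d * (utilities$u_pfs * pfs + utilities$u_pd * pd)) * dt
  if (!is.null(ae_incidence) && length(utilities$ae_disutilities)) {
    common <- intersect(names(ae_incidence),
                        names(utilities$ae_disutilities))
    q <- q - sum(ae_incidence[common] *
                   utilities$ae_disutilities[common]) * dt
  }
  q
}

# cycle indices (0-based) of scheduled tumor assessments, from the weekly
# schedule mapped onto 21-day cycles in calendar time
.assessment_cycles <- function(schedule, settings) {
  wk_cycle <- settings$cycle_length_days / 7
  wk_max <- settings$n_cycles * wk_cycle
  wks <- c(seq(schedule$interval_weeks_initial, schedule$initial_period_weeks,
               by = schedule$interval_weeks_initial),
           seq(schedule$initial_period_weeks + schedule$interval_weeks_later,
               wk_max, by = schedule$interval_weeks_later))
  idx <- round(wks / wk_cycle)
  idx[idx < settings$n_cycles]
}

#' Discounted total cost of a strategy over a cohort trace
#'
#' Accrues, per cycle and discounted at the cycle start: first-line drug
#' costs on progression-free occupancy under the treatment-duration rules;
#' one administration event per on-treatment cycle; routine laboratory
#' costs on alive occupancy; CT costs at scheduled assessments on alive
#' occupancy; progressed-state costs (subsequent-treatment fraction times
#' regimen cost under the configured attribution mode, plus best supportive
#' care for the remainder); end-of-life cost on incident deaths; and
#' adverse-event management costs once, in the first cycle.
#'
#' @inheritParams accumulate_qalys
#' @param strategy A [strategy_inputs()].
#' @return Discounted total cost (scalar) with attribute `"components"`, a
#'   named vector of discounted cost components.
#' @export
accumulate_costs <- function(trace, strategy, settings) {
  d <- .disc(trace, settings)
  k <- trace$cycle
  pfs <- .accrual_occ(trace$pfs, settings)
  pd <- .accrual_occ(trace$pd, settings)
  alive <- pfs + pd
  dc <- strategy$drug_costs
  # presence of the key marks the arm as containing tislelizumab; a zero
  # cost (e.g. during price simulation) must not alter treatment rules
  has_tis <- !is.null(dc$tislelizumab)
  tis_cost <- if (has_tis) dc$tislelizumab else 0
  tis_on <- as.numeric(has_tis &
                         trace$time_years < strategy$tislelizumab_max_years)
  chemo_on <- as.numeric(k < strategy$max_chemo_cycles)
  mix <- strategy$chemo_mix_oxcap
  maint <- as.numeric(strategy$capecitabine_maintenance)

  drug <- tis_cost * pfs * tis_on +
    mix * ((dc$oxaliplatin + dc$capecitabine) * pfs * chemo_on +
             maint * dc$capecitabine * pfs * (1 - chemo_on)) +
    (1 - mix) * (dc$cisplatin + dc$fluorouracil) * pfs * chemo_on

  # on-treatment share: everyone while tislelizumab or doublet chemotherapy
  # runs, then the capecitabine-maintenance share
  on_trt <- pmax(tis_on, chemo_on, maint * mix *
                   as.numeric(chemo_on == 0))
  adm <- strategy$administration
  adm_unit <- if (identical(adm$mode, "hours")) {
    adm$first_hour + adm$additional_hour
  } else adm$per_unit
  admin <- adm_unit * pfs * on_trt

  lab <- strategy$laboratory_cost_per_cycle * alive

  ct <- numeric(settings$n_cycles)
  idx <- .assessment_cycles(strategy$assessment_schedule, settings)
  for (i in idx) ct[i + 1] <- ct[i + 1] + strategy$ct_cost_per_assessment
  ct <- ct * (1 - trace$dead)

  p_sub <- strategy$p_subsequent
  sub_c <- strategy$subsequent_cost_per_cycle
  ndur <- strategy$subsequent_duration_cycles
  sub <- switch(strategy$subsequent_attribution,
    per_pd_cycle = p_sub * sub_c * pd,
    fixed_duration = {
      roll <- as.numeric(stats::filter(trace$inc_prog, rep(1, ndur),
                                       sides = 1))
      roll[is.na(roll)] <- cumsum(trace$inc_prog)[is.na(roll)]
      p_sub * sub_c * pmin(trace$pd, roll)
    },
    one_time = p_sub * sub_c * ndur * trace$inc_prog)
  bsc <- (1 - p_sub) * strategy$bsc_cost_per_cycle * pd

  eol <- strategy$end_of_life_cost * trace$inc_death

  ae <- numeric(settings$n_cycles)
  if (length(strategy$ae_incidence)) {
    ae[1] <- sum(strategy$ae_incidence *
                   strategy$ae_costs[names(strategy$ae_incidence)])
  }

  comp <- c(drug = sum(d * drug), administration = sum(d * admin),
            laboratory = sum(d * lab), imaging = sum(d * ct),
            subsequent = sum(d * sub), bsc = sum(d * bsc),
            end_of_life = sum(d * eol), adverse_events = sum(d * ae))
  total <- sum(comp)
  attr(total, "components") <- comp
  attr(total, "per_cycle") <- d * (drug + admin + lab + ct + sub + bsc +
                                     eol + ae)
  total
}

#' Run one strategy end-to-end
#'
#' @inheritParams accumulate_costs
#' @param utilities A [utility_inputs()].
#' @return A `psm_run`: discounted `cost`, discounted `qaly`, the full
#'   `trace` (with discounted per-cycle cost and QALY increments) and the
#'   cost `components`.
#' @export
run_strategy <- function(strategy, utilities, settings) {
  tr <- occupancy(strategy, settings)
  stopifnot(abs(tr$pfs + tr$pd + tr$dead - 1) < 1e-9 |
              tr$pfs + tr$pd + tr$dead <= 1 + 1e-9)
  qaly <- accumulate_qalys(tr, utilities, settings, strategy$ae_incidence)
  cost <- accumulate_costs(tr, strategy, settings)
  d <- .disc(tr, settings)
  dt <- settings$cycle_length_days / 365.25
  tr$disc_cost <- attr(cost, "per_cycle")
  tr$disc_qaly <- d * (utilities$u_pfs * .accrual_occ(tr$pfs, settings) +
                         utilities$u_pd * .accrual_occ(tr$pd, settings)) * dt
  # the one-off AE disutility decrement belongs to the first cycle
  if (length(strategy$ae_incidence) &&
      length(utilities$ae_disutilities)) {
    common <- intersect(names(strategy$ae_incidence),
                        names(utilities$ae_disutilities))
    tr$disc_qaly[1] <- tr$disc_qaly[1] -
      sum(strategy$ae_incidence[common] *
            utilities$ae_disutilities[common]) * dt
  }
  structure(list(label = strategy$label, cost = as.numeric(cost),
                 qaly = qaly, trace = tr,
                 components = attr(cost, "components")),
            class = "psm_run")
}

#' @export
print.psm_run <- function(x, ...) {
  cat("<psm_run> ", x$label, "\n", sep = "")
  cat(sprintf("  discounted cost $%.2f | discounted QALYs %.4f\n",
              x$cost, x$qaly))
  cat("  cost components ($): ",
      paste(sprintf("%s %.0f", names(x$components), x$components),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Export a cohort trace as delimited text
#'
#' @param run A `psm_run` (or a trace data frame).
#' @param path Output file (tab-delimited).
#' @export
write_trace <- function(run, path) {
  tr <- if (inherits(run, "psm_run")) run$trace else run
  utils::write.table(format(tr, digits = 10), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(tr)
}
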