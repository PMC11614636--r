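# independent product-limit estimator (naive, for oracle comparisons)
naive_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    n_at <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / n_at)
    surv[i] <- s
  }
  data.frame(time = ut, survival = surv)
}

# evaluate a km_curve (step function) at arbitrary times
km_surv_at <- function(curve, t) {
  co <- curve$coords
  vapply(t, function(x) {
    i <- which(co$time <= x)
    if (length(i) == 0) 1 else co$survival[max(i)]
  }, 0)
}

# small all-zero-cost strategy around given survival specs, for engine tests
toy_strategy <- function(os, pfs, label = "toy",
                         p_subsequent = 0.5, sub_cost = 0, bsc = 0,
                         eol = 0, lab = 0, ct = 0, admin = 0,
                         drug = list(oxaliplatin = 0, capecitabine = 0,
                                     fluorouracil = 0, cisplatin = 0),
                         ae_incidence = numeric(0),
                         ae_costs = numeric(0), ...) {
  strategy_inputs(
    label = label, os = os, pfs = pfs, drug_costs = drug,
    chemo_mix_oxcap = 0.9, p_subsequent = p_subsequent,
    subsequent_regimen = "toy", subsequent_cost_per_cycle = sub_cost,
    bsc_cost_per_cycle = bsc, end_of_life_cost = eol,
    administration = list(mode = "per_unit", per_unit = admin),
    laboratory_cost_per_cycle = lab, ct_cost_per_assessment = ct,
    ae_incidence = ae_incidence, ae_costs = ae_costs, ...)
}

toy_settings <- function(r = 0.05, wtp = 38042.49, mpc = 1.0, ...) {
  econ_settings(discount_rate_annual = r, wtp_per_qaly = wtp,
                months_per_cycle = mpc, ...)
}
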