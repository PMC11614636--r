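.schema_top <- c("country", "population", "currency", "settings",
                 "utilities", "shared_costs", "assessment_schedule",
                 "tislelizumab_mg_per_cycle", "arms", "psa_ranges",
                 "sources")
.schema_settings <- c("cycle_length_days", "horizon_years",
                      "discount_rate_annual", "wtp_per_qaly",
                      "months_per_cycle", "half_cycle_correction")
.schema_utilities <- c("u_pfs", "u_pd", "ae_disutilities")
.schema_shared <- c("subsequent_per_cycle", "best_supportive_care_per_cycle",
                    "end_of_life", "laboratory_per_cycle",
                    "ct_per_assessment", "administration", "ae_costs")
.schema_arm <- c("label", "os", "pfs", "drug_costs_per_cycle", "chemo_mix",
                 "max_chemo_cycles", "tislelizumab_max_years",
                 "capecitabine_maintenance", "p_subsequent",
                 "subsequent_regimen", "subsequent_attribution",
                 "subsequent_duration_cycles", "ae_incidence")

#' Names of the packaged model configurations
#'
#' Four fixtures are shipped: `china_itt`, `china_tap5`, `us_itt`,
#' `us_tap5` — the two payer perspectives crossed with the intent-to-treat
#' population and the PD-L1 TAP >= 5 percent subgroup.
#'
#' @return Character vector of fixture names.
#' @export
fixture_names <- function() c("china_itt", "china_tap5", "us_itt", "us_tap5")

.reject_unknown <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
}

#' Load and validate a model configuration
#'
#' @param name Either the name of a packaged fixture (see
#'   [fixture_names()]) or a path to a YAML configuration file.
#' @return A validated `model_config` list.
#' @export
load_config <- function(name) {
  path <- if (name %in% fixture_names()) {
    system.file("extdata", paste0(name, ".yaml"), package = "ceapsm",
                mustWork = TRUE)
  } else {
    if (!file.exists(name)) stop("no such fixture or file: ", name,
                                 call. = FALSE)
    name
  }
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' Validate a model configuration
#'
#' Rejects unknown keys, checks that every cost is nonnegative, every
#' probability/utility lies in `[0, 1]`, the chemotherapy mix sums to one
#' and both arms are fully specified.
#'
#' @param cfg A configuration list.
#' @return The configuration, classed `model_config`, invisibly valid.
#' @export
validate_config <- function(cfg) {
  .reject_unknown(cfg, .schema_top, "config")
  need <- setdiff(.schema_top, c("psa_ranges", "sources", "currency"))
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("missing config key(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!is.null(cfg$currency) && cfg$currency != "USD") {
    stop("currency must be USD", call. = FALSE)
  }
  cfg$country <- match.arg(cfg$country, c("china", "us"))
  cfg$population <- match.arg(cfg$population, c("itt", "tap_ge_5"))
  .reject_unknown(cfg$settings, .schema_settings, "settings")
  .reject_unknown(cfg$utilities, .schema_utilities, "utilities")
  .reject_unknown(cfg$shared_costs, .schema_shared, "shared_costs")
  sc <- cfg$shared_costs
  costs <- c(unlist(sc$subsequent_per_cycle),
             sc$best_supportive_care_per_cycle, sc$end_of_life,
             sc$laboratory_per_cycle, sc$ct_per_assessment,
             unlist(sc$ae_costs),
             unlist(sc$administration[names(sc$administration) != "mode"]))
  if (any(costs < 0)) stop("negative cost in shared_costs", call. = FALSE)
  for (u in c(cfg$utilities$u_pfs, cfg$utilities$u_pd,
              unlist(cfg$utilities$ae_disutilities))) {
    if (u < 0 || u > 1) stop("utility/disutility outside [0,1]",
                             call. = FALSE)
  }
  if (!all(c("intervention", "comparator") %in% names(cfg$arms))) {
    stop("arms must contain 'intervention' and 'comparator'", call. = FALSE)
  }
  for (an in c("intervention", "comparator")) {
    arm <- cfg$arms[[an]]
    .reject_unknown(arm, .schema_arm, paste0("arms$", an))
    if (any(unlist(arm$drug_costs_per_cycle) < 0)) {
      stop("negative drug cost in arm ", an, call. = FALSE)
    }
    mixsum <- sum(unlist(arm$chemo_mix))
    if (abs(mixsum - 1) > 1e-6) {
      stop("chemo_mix must sum to 1 in arm ", an, call. = FALSE)
    }
    for (p in c(arm$p_subsequent, unlist(arm$ae_incidence),
                unlist(arm$chemo_mix))) {
      if (p < 0 || p > 1) stop("fraction outside [0,1] in arm ", an,
                               call. = FALSE)
    }
    # constructing the spec validates family and parameters
    surv_spec(arm$os$family, arm$os$params)
    surv_spec(arm$pfs$family, arm$pfs$params)
  }
  if (!is.null(cfg$psa_ranges)) {
    for (rg in cfg$psa_ranges) {
      .reject_unknown(rg, c("path", "low", "high", "distribution"),
                      "psa_ranges entry")
    }
  }
  class(cfg) <- c("model_config", "list")
  cfg
}

#' Write a configuration back to YAML
#'
#' @param cfg A `model_config`.
#' @param path Output path.
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  yaml::write_yaml(out, path, precision = 12)
  invisible(cfg)
}

#' Extract [econ_settings()] from a configuration
#' @param cfg A `model_config`.
#' @export
config_settings <- function(cfg) {
  s <- cfg$settings
  econ_settings(discount_rate_annual = s$discount_rate_annual,
                wtp_per_qaly = s$wtp_per_qaly,
                cycle_length_days = s$cycle_length_days,
                horizon_years = s$horizon_years,
                months_per_cycle = s$months_per_cycle,
                half_cycle_correction = isTRUE(s$half_cycle_correction))
}

#' Extract [utility_inputs()] from a configuration
#' @param cfg A `model_config`.
#' @export
config_utilities <- function(cfg) {
  u <- cfg$utilities
  utility_inputs(u$u_pfs, u$u_pd, unlist(u$ae_disutilities))
}

#' Build the [strategy_inputs()] for one arm of a configuration
#'
#' @param cfg A `model_config`.
#' @param arm `"intervention"` or `"comparator"`.
#' @export
config_strategy <- function(cfg, arm = c("intervention", "comparator")) {
  arm <- match.arg(arm)
  a <- cfg$arms[[arm]]
  sc <- cfg$shared_costs
  sub_cost <- sc$subsequent_per_cycle[[a$subsequent_regimen]]
  if (is.null(sub_cost)) {
    stop("no cost entry for subsequent regimen '", a$subsequent_regimen,
         "'", call. = FALSE)
  }
  strategy_inputs(
    label = a$label,
    os = surv_spec(a$os$family, a$os$params),
    pfs = surv_spec(a$pfs$family, a$pfs$params),
    drug_costs = a$drug_costs_per_cycle,
    chemo_mix_oxcap = a$chemo_mix$oxaliplatin_capecitabine,
    max_chemo_cycles = a$max_chemo_cycles,
    tislelizumab_max_years = if (is.null(a$tislelizumab_max_years)) Inf else
      a$tislelizumab_max_years,
    capecitabine_maintenance = isTRUE(a$capecitabine_maintenance),
    p_subsequent = a$p_subsequent,
    subsequent_regimen = a$subsequent_regimen,
    subsequent_cost_per_cycle = sub_cost,
    subsequent_attribution = if (is.null(a$subsequent_attribution))
      "per_pd_cycle" else a$subsequent_attribution,
    subsequent_duration_cycles = if (is.null(a$subsequent_duration_cycles))
      6 else a$subsequent_duration_cycles,
    bsc_cost_per_cycle = sc$best_supportive_care_per_cycle,
    end_of_life_cost = sc$end_of_life,
    administration = sc$administration,
    laboratory_cost_per_cycle = sc$laboratory_per_cycle,
    ct_cost_per_assessment = sc$ct_per_assessment,
    assessment_schedule = cfg$assessment_schedule,
    ae_incidence = unlist(a$ae_incidence),
    ae_costs = unlist(sc$ae_costs))
}

#' Get or set a configuration value by dotted path
#'
#' Paths address nested configuration entries, e.g.
#' `"arms.intervention.drug_costs_per_cycle.tislelizumab"` or
#' `"utilities.u_pfs"`. Setting one component of a `chemo_mix` block
#' automatically renormalizes its complement so the mix keeps summing to
#' one.
#'
#' @param cfg A `model_config`.
#' @param path Dotted path string.
#' @param value Replacement value (for `set_param`).
#' @return `get_param`: the value. `set_param`: the modified configuration.
#' @export
get_param <- function(cfg, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- cfg
  for (k in keys) {
    if (is.null(node[[k]])) stop("no parameter at path '", path, "'",
                                 call. = FALSE)
    node <- node[[k]]
  }
  node
}

#' @rdname get_param
#' @export
set_param <- function(cfg, path, value) {
  if (is.atomic(value)) value <- unname(value)
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- cfg
  for (k in keys) {
    if (is.null(node[[k]])) stop("no parameter at path '", path, "'",
                                 call. = FALSE)
    node <- node[[k]]
  }
  cfg[[keys]] <- value
  n <- length(keys)
  if (n >= 2 && keys[n - 1] == "chemo_mix") {
    mix_path <- keys[seq_len(n - 1)]
    mix <- cfg[[mix_path]]
    other <- setdiff(names(mix), keys[n])
    if (length(other) == 1) {
      mix[[other]] <- 1 - value
      cfg[[mix_path]] <- mix
    }
  }
  cfg
}

#' Reprice tislelizumab in a configuration
#'
#' @param cfg A `model_config`.
#' @param price_per_100mg Price in dollars per 100 mg; the per-cycle cost is
#'   `price_per_100mg * tislelizumab_mg_per_cycle / 100` (200 mg every
#'   three weeks by default).
#' @return Modified configuration.
#' @export
set_tislelizumab_price <- function(cfg, price_per_100mg) {
  stopifnot(price_per_100mg >= 0)
  per_cycle <- price_per_100mg * cfg$tislelizumab_mg_per_cycle / 100
  cfg$arms$intervention$drug_costs_per_cycle$tislelizumab <- per_cycle
  cfg
}
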