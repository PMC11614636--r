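#' Incremental cost-effectiveness comparison of two strategies
#'
#' Computes `delta_cost = c1 - c0`, `delta_qaly = e1 - e0`, the incremental
#' cost-effectiveness ratio `ICER = delta_cost / delta_qaly` (reported only
#' in the north-east quadrant; off-quadrant results are labelled
#' `"dominant"` or `"dominated"`, since the ratio is misleading there), and
#' the net-benefit indices at willingness-to-pay `lambda`:
#' `INHB = delta_qaly - delta_cost / lambda` and
#' `INMB = delta_qaly * lambda - delta_cost = lambda * INHB`.
#'
#' @param cost_intervention,qaly_intervention Discounted cost and QALYs of
#'   the intervention arm (mu_C1, mu_E1).
#' @param cost_comparator,qaly_comparator Same for the comparator
#'   (mu_C0, mu_E0).
#' @param wtp Willingness-to-pay threshold lambda (> 0), $/QALY.
#' @return A `cea_comparison` object.
#' @examples
#' compare_strategies(110, 3, 10, 1, wtp = 100)  # ICER 50, INHB 1, INMB 100
#' @export
compare_strategies <- function(cost_intervention, qaly_intervention,
                               cost_comparator, qaly_comparator, wtp) {
  if (wtp <= 0) stop("wtp must be > 0", call. = FALSE)
  dc <- cost_intervention - cost_comparator
  de <- qaly_intervention - qaly_comparator
  dominance <- NA_character_
  icer <- NA_real_
  if (dc == 0 && de == 0) {
    # identical strategies: undefined ICER, zero net benefit
  } else if (de > 0 && dc > 0) {
    icer <- dc / de
  } else if (de <= 0 && dc >= 0) {
    dominance <- "dominated"
  } else if (de >= 0 && dc <= 0) {
    dominance <- "dominant"
  } else {
    icer <- dc / de   # SW quadrant: ratio of savings to losses
  }
  inhb <- de - dc / wtp
  inmb <- de * wtp - dc
  structure(list(cost_intervention = cost_intervention,
                 qaly_intervention = qaly_intervention,
                 cost_comparator = cost_comparator,
                 qaly_comparator = qaly_comparator,
                 delta_cost = dc, delta_qaly = de,
                 icer = icer, dominance = dominance,
                 inhb = inhb, inmb = inmb, wtp = wtp),
            class = "cea_comparison")
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat("<cea_comparison>\n")
  cat(sprintf("  intervention: cost $%.2f, QALYs %.4f\n",
              x$cost_intervention, x$qaly_intervention))
  cat(sprintf("  comparator:   cost $%.2f, QALYs %.4f\n",
              x$cost_comparator, x$qaly_comparator))
  cat(sprintf("  delta cost $%.2f | delta QALYs %.4f\n",
              x$delta_cost, x$delta_qaly))
  if (!is.na(x$dominance)) {
    cat("  ICER:", x$dominance, "\n")
  } else if (!is.na(x$icer)) {
    cat(sprintf("  ICER $%.2f/QALY\n", x$icer))
  } else {
    cat("  ICER undefined (identical strategies)\n")
  }
  cat(sprintf("  at lambda $%.2f: INHB %.4f QALYs, INMB $%.2f\n",
              x$wtp, x$inhb, x$inmb))
  invisible(x)
}

#' Run the base-case comparison for a model configuration
#'
#' Runs both arms of the configured partitioned-survival model
#' deterministically and compares them.
#'
#' @param config A model configuration from [load_config()].
#' @return A `cea_result`: the `comparison` ([compare_strategies()]) plus
#'   both `psm_run` objects and the configuration.
#' @export
run_comparison <- function(config) {
  st <- config_settings(config)
  ut <- config_utilities(config)
  a1 <- run_strategy(config_strategy(config, "intervention"), ut, st)
  a0 <- run_strategy(config_strategy(config, "comparator"), ut, st)
  cmp <- compare_strategies(a1$cost, a1$qaly, a0$cost, a0$qaly,
                            st$wtp_per_qaly)
  structure(list(comparison = cmp, intervention = a1, comparator = a0,
                 country = config$country, population = config$population),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("Base case [%s / %s]\n", x$country, x$population))
  print(x$comparison)
  invisible(x)
}

#' @export
summary.cea_result <- function(object, ...) {
  cmp <- object$comparison
  data.frame(country = object$country, population = object$population,
             cost_intervention = cmp$cost_intervention,
             qaly_intervention = cmp$qaly_intervention,
             cost_comparator = cmp$cost_comparator,
             qaly_comparator = cmp$qaly_comparator,
             delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly,
             icer = if (!is.na(cmp$dominance)) NA_real_ else cmp$icer,
             dominance = cmp$dominance,
             inhb = cmp$inhb, inmb = cmp$inmb, wtp = cmp$wtp)
}

#' Write one comparison row as delimited text
#'
#' @param result A `cea_result` (or list of them).
#' @param path Output file (tab-delimited).
#' @export
write_comparison <- function(result, path) {
  if (inherits(result, "cea_result")) result <- list(result)
  tab <- do.call(rbind, lapply(result, summary))
  utils::write.table(format(tab, digits = 10), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(tab)
}
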