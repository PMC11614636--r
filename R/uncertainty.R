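# a range's path may list several space-separated dotted paths that share
# one underlying parameter (e.g. a drug unit cost present in both arms);
# all of them are set to the sampled value
.set_param_multi <- function(cfg, path, value) {
  for (p in strsplit(path, " ", fixed = TRUE)[[1]]) {
    cfg <- set_param(cfg, p, value)
  }
  cfg
}

.first_path <- function(path) strsplit(path, " ", fixed = TRUE)[[1]][1]

#' Parameter range for sensitivity analysis
#'
#' Low/high bounds around a baseline, plus the sampling distribution used in
#' probabilistic sensitivity analysis. Ranges violating
#' `low <= baseline <= high` are recorded and replaced by +/- 20 percent of
#' the baseline (the replacement is flagged in the returned object).
#'
#' @param path Dotted configuration path (see [set_param()]).
#' @param baseline Baseline value (usually read from the configuration).
#' @param low,high Bounds.
#' @param distribution `"gamma"` (costs), `"beta"` (probabilities and
#'   utilities) or `"fixed"`.
#' @return A `param_range` object.
#' @export
param_range <- function(path, baseline, low, high,
                        distribution = c("gamma", "beta", "fixed")) {
  distribution <- match.arg(distribution)
  substituted <- FALSE
  if (!(low <= baseline && baseline <= high)) {
    low <- 0.8 * baseline
    high <- 1.2 * baseline
    substituted <- TRUE
  }
  if (distribution == "beta" && (baseline < 0 || baseline > 1)) {
    stop("beta distribution requires a [0,1] baseline at ", path,
         call. = FALSE)
  }
  structure(list(path = path, baseline = baseline, low = low, high = high,
                 distribution = distribution, substituted = substituted),
            class = "param_range")
}

#' Assemble the sensitivity-analysis ranges of a configuration
#'
#' Reads the `psa_ranges` block of the configuration and attaches baselines
#' from the corresponding paths, applying the +/- 20 percent substitution
#' rule of [param_range()] where the recorded bounds are inconsistent with
#' the baseline.
#'
#' @param cfg A `model_config`.
#' @return List of [param_range()] objects.
#' @export
config_ranges <- function(cfg) {
  lapply(cfg$psa_ranges, function(rg) {
    param_range(rg$path, get_param(cfg, .first_path(rg$path)), rg$low,
                rg$high, rg$distribution)
  })
}

#' One-way (deterministic) sensitivity analysis
#'
#' Each parameter is set to its low and high bound in turn, all others held
#' at baseline, and the incremental cost-effectiveness ratio recomputed.
#' Entries are returned sorted by span (tornado order).
#'
#' @param cfg A `model_config`.
#' @param ranges List of [param_range()]; defaults to [config_ranges()].
#' @return Data frame (`owsa_result`): `path`, `low`, `high`,
#'   `icer_at_low`, `icer_at_high`, `span`, plus the baseline ICER as
#'   attribute `"base_icer"`.
#' @export
owsa <- function(cfg, ranges = config_ranges(cfg)) {
  base <- run_comparison(cfg)
  icer_of <- function(c) {
    cmp <- run_comparison(c)$comparison
    if (!is.na(cmp$dominance)) {
      if (cmp$dominance == "dominant") -Inf else Inf
    } else cmp$icer
  }
  rows <- lapply(ranges, function(rg) {
    lo <- icer_of(.set_param_multi(cfg, rg$path, rg$low))
    hi <- icer_of(.set_param_multi(cfg, rg$path, rg$high))
    data.frame(path = rg$path, low = rg$low, high = rg$high,
               icer_at_low = lo, icer_at_high = hi,
               span = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base$comparison$icer
  class(out) <- c("owsa_result", "data.frame")
  out
}

#' Build a sampler for a parameter range
#'
#' Gamma and beta samplers are parameterized by the method of moments with
#' mean equal to the baseline and standard deviation `(high - low) / 3.92`
#' (the bounds are read as a 95 percent central interval). A zero standard
#' deviation, or `distribution = "fixed"`, yields a point mass.
#'
#' @param range A [param_range()].
#' @return Function of `n` returning `n` draws.
#' @export
build_distribution <- function(range) {
  m <- range$baseline
  sd <- (range$high - range$low) / 3.92
  if (range$distribution == "fixed" || sd == 0) {
    return(function(n) rep(m, n))
  }
  if (range$distribution == "gamma") {
    if (m <= 0) stop("gamma requires positive baseline at ", range$path,
                     call. = FALSE)
    shape <- m^2 / sd^2
    rate <- m / sd^2
    return(function(n) stats::rgamma(n, shape = shape, rate = rate))
  }
  # beta
  if (m <= 0 || m >= 1) {
    stop("beta requires baseline in (0,1) at ", range$path, call. = FALSE)
  }
  v <- min(sd^2, 0.95 * m * (1 - m))   # keep the moment match feasible
  k <- m * (1 - m) / v - 1
  function(n) stats::rbeta(n, shape1 = m * k, shape2 = (1 - m) * k)
}

#' Probabilistic sensitivity analysis
#'
#' Draws all parameters jointly from their [build_distribution()] samplers
#' and re-runs both arms end-to-end for every draw. Survival-curve
#' parameters are held fixed (no published uncertainty for them); they can
#' be varied through user-supplied ranges if desired.
#'
#' @param cfg A `model_config`.
#' @param n Number of Monte Carlo draws (10,000 in the packaged analyses).
#' @param seed Random seed (recorded in the result).
#' @param ranges List of [param_range()]; defaults to [config_ranges()].
#' @return A `psa_result` data frame: per draw, `cost1`, `qaly1`, `cost0`,
#'   `qaly0`, `delta_cost`, `delta_qaly`, `inmb`; sampled parameters in
#'   attribute `"draws"`, seed and WTP in attributes.
#' @export
psa <- function(cfg, n = 10000, seed = 1L, ranges = config_ranges(cfg)) {
  stopifnot(n >= 1)
  set.seed(seed)
  samplers <- lapply(ranges, build_distribution)
  paths <- vapply(ranges, function(r) r$path, "")
  draws <- vapply(samplers, function(s) s(n), numeric(n))
  if (n == 1) draws <- matrix(draws, nrow = 1)
  colnames(draws) <- paths
  out <- matrix(NA_real_, nrow = n, ncol = 4)
  for (i in seq_len(n)) {
    ci <- cfg
    for (j in seq_along(paths)) {
      ci <- .set_param_multi(ci, paths[j], draws[i, j])
    }
    st <- config_settings(ci)
    ut <- config_utilities(ci)
    a1 <- run_strategy(config_strategy(ci, "intervention"), ut, st)
    a0 <- run_strategy(config_strategy(ci, "comparator"), ut, st)
    out[i, ] <- c(a1$cost, a1$qaly, a0$cost, a0$qaly)
  }
  res <- data.frame(draw = seq_len(n), cost1 = out[, 1], qaly1 = out[, 2],
                    cost0 = out[, 3], qaly0 = out[, 4])
  res$delta_cost <- res$cost1 - res$cost0
  res$delta_qaly <- res$qaly1 - res$qaly0
  res$inmb <- res$delta_qaly * cfg$settings$wtp_per_qaly - res$delta_cost
  attr(res, "draws") <- draws
  attr(res, "seed") <- seed
  attr(res, "wtp") <- cfg$settings$wtp_per_qaly
  class(res) <- c("psa_result", "data.frame")
  res
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with
#' positive incremental net monetary benefit
#' (`delta_qaly * lambda - delta_cost > 0`).
#'
#' @param samples A `psa_result` (or data frame with `delta_cost`,
#'   `delta_qaly`).
#' @param wtp_grid Lambda grid; defaults to 201 points from 0 to twice the
#'   threshold recorded in the samples.
#' @return Data frame `wtp`, `prob_cost_effective` (class `ceac_curve`).
#' @export
ceac <- function(samples, wtp_grid = NULL) {
  stopifnot(nrow(samples) > 0)
  if (is.null(wtp_grid)) {
    w <- attr(samples, "wtp")
    if (is.null(w)) w <- 50000
    wtp_grid <- seq(0, 2 * w, length.out = 201)
  }
  prob <- vapply(wtp_grid, function(l) {
    mean(samples$delta_qaly * l - samples$delta_cost > 0)
  }, 0)
  structure(data.frame(wtp = wtp_grid, prob_cost_effective = prob),
            class = c("ceac_curve", "data.frame"))
}

#' Tislelizumab price at which the ICER equals the threshold
#'
#' Total cost is affine in the unit price, so the threshold solves
#' `delta_cost(p) = lambda * delta_qaly` exactly from two model
#' evaluations; the result is clipped to the searched price grid.
#'
#' @param cfg A `model_config`.
#' @param wtp Willingness-to-pay threshold; defaults to the configured one.
#' @param price_range Price grid bounds, $ per 100 mg (0-500 China,
#'   0-2500 US).
#' @return List: `threshold` ($/100 mg, or `NA` when `delta_qaly <= 0`),
#'   `clipped` flag, `slope` ($ of incremental cost per $/100 mg),
#'   `delta_cost_at_zero`, `delta_qaly`, `wtp`.
#' @export
price_threshold <- function(cfg, wtp = cfg$settings$wtp_per_qaly,
                            price_range = c(0, 500)) {
  r0 <- run_comparison(set_tislelizumab_price(cfg, 0))$comparison
  if (r0$delta_qaly <= 0) {
    return(list(threshold = NA_real_, clipped = FALSE, slope = NA_real_,
                delta_cost_at_zero = r0$delta_cost,
                delta_qaly = r0$delta_qaly, wtp = wtp,
                reason = "no finite threshold: delta QALY <= 0"))
  }
  p1 <- max(price_range)
  r1 <- run_comparison(set_tislelizumab_price(cfg, p1))$comparison
  slope <- (r1$delta_cost - r0$delta_cost) / p1
  thr <- (wtp * r0$delta_qaly - r0$delta_cost) / slope
  clipped <- thr < min(price_range) || thr > max(price_range)
  thr <- min(max(thr, min(price_range)), max(price_range))
  list(threshold = thr, clipped = clipped, slope = slope,
       delta_cost_at_zero = r0$delta_cost, delta_qaly = r0$delta_qaly,
       wtp = wtp)
}

#' Scenario analysis over subsequent treatments
#'
#' Swaps the subsequent-treatment regimen (hence its per-cycle cost) in
#' both arms and re-runs the deterministic comparison.
#'
#' @param cfg A `model_config`.
#' @param regimen One of the regimens priced in
#'   `shared_costs$subsequent_per_cycle` (e.g. `"ramucirumab_paclitaxel"`,
#'   `"paclitaxel"`, `"docetaxel"`, `"nab_paclitaxel"`, `"irinotecan"`,
#'   `"best_supportive_care"`).
#' @return A `cea_result`.
#' @export
scenario_subsequent <- function(cfg, regimen) {
  if (is.null(cfg$shared_costs$subsequent_per_cycle[[regimen]])) {
    stop("unknown subsequent regimen '", regimen, "'", call. = FALSE)
  }
  cfg$arms$intervention$subsequent_regimen <- regimen
  cfg$arms$comparator$subsequent_regimen <- regimen
  run_comparison(cfg)
}

#' Tornado plot of a one-way sensitivity analysis
#'
#' @param x An `owsa_result`.
#' @param top Number of parameters displayed (default 15).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot_tornado <- function(x, top = 15, ...) {
  x <- utils::head(x, top)
  x <- x[nrow(x):1, ]
  base <- attr(x, "base_icer")
  lo <- pmin(x$icer_at_low, x$icer_at_high) - base
  hi <- pmax(x$icer_at_low, x$icer_at_high) - base
  old <- graphics::par(mar = c(5, 16, 2, 2))
  on.exit(graphics::par(old))
  yy <- seq_len(nrow(x))
  graphics::plot(0, type = "n", xlim = range(c(lo, hi)) * 1.05,
                 ylim = c(0.5, nrow(x) + 0.5), yaxt = "n",
                 xlab = "ICER change from base case ($/QALY)", ylab = "",
                 main = "One-way sensitivity analysis", ...)
  graphics::rect(lo, yy - 0.4, hi, yy + 0.4, col = "steelblue")
  graphics::abline(v = 0, lty = 2)
  graphics::axis(2, at = yy, labels = x$path, las = 1, cex.axis = 0.6)
  invisible(x)
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param x A `ceac_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_ceac <- function(x, ...) {
  graphics::plot(x$wtp, x$prob_cost_effective, type = "l", ylim = c(0, 1),
                 xlab = "Willingness to pay ($/QALY)",
                 ylab = "Probability cost-effective",
                 main = "Cost-effectiveness acceptability curve", ...)
  invisible(x)
}

#' Incremental cost-effectiveness plane scatter of PSA draws
#'
#' @param x A `psa_result`.
#' @param wtp Threshold line to draw; defaults to the recorded one.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_ce_plane <- function(x, wtp = attr(x, "wtp"), ...) {
  graphics::plot(x$delta_qaly, x$delta_cost, pch = 16, cex = 0.3,
                 col = grDevices::adjustcolor("steelblue", 0.4),
                 xlab = "Incremental QALYs", ylab = "Incremental cost ($)",
                 main = "Cost-effectiveness plane", ...)
  graphics::abline(h = 0, v = 0, col = "grey")
  if (!is.null(wtp)) graphics::abline(a = 0, b = wtp, lty = 2)
  invisible(x)
}
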