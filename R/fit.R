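#' Right-censored log-likelihood of a survival spec
#'
#' `sum(event * log f(t) + (1 - event) * log S(t))`.
#'
#' @param spec A [surv_spec()].
#' @param times Positive event/censoring times (months).
#' @param events Event indicators (1 event, 0 censored).
#' @return Log-likelihood value.
#' @export
surv_loglik <- function(spec, times, events) {
  f <- surv_dens(spec, times)
  s <- surv_prob(spec, times)
  ll <- sum(log(pmax(f[events == 1], 1e-300))) +
    sum(log(pmax(s[events == 0], 1e-300)))
  ll
}

# map between unconstrained optimizer space and the natural parameter space:
# positive parameters are optimized on the log scale
.to_natural <- function(family, theta) {
  layout <- .family_params[[family]]
  out <- theta
  out[layout] <- exp(theta[layout])
  names(out) <- names(layout)
  out
}

.to_working <- function(family, params) {
  layout <- .family_params[[family]]
  out <- params
  out[layout] <- log(params[layout])
  out
}

# moment-based starting values on the natural scale, plus deterministic
# alternative starts for the ill-conditioned heavy-tailed families
.start_values <- function(family, times, events) {
  tu <- times[events == 1]
  if (length(tu) < 2) tu <- times
  ml <- mean(log(tu)); sl <- stats::sd(log(tu))
  if (!is.finite(sl) || sl <= 0) sl <- 1
  m <- mean(tu); v <- stats::var(tu); if (!is.finite(v) || v <= 0) v <- m^2
  base <- switch(family,
    exponential = list(c(rate = sum(events) / sum(times))),
    gamma = list(c(shape = m^2 / v, rate = m / v)),
    generalized_gamma = list(
      c(mu = ml, sigma = sl, Q = 0.01),
      c(mu = ml, sigma = sl, Q = -0.5),
      c(mu = ml, sigma = sl, Q = 1),
      c(mu = ml, sigma = sl, Q = -1)),
    gompertz = list(c(shape = 1e-3, rate = sum(events) / sum(times)),
                    c(shape = 0.05, rate = 0.5 * sum(events) / sum(times))),
    weibull = list(c(shape = 1.2 / sl, scale = exp(ml + 0.5772 * sl))),
    weibull_ph = list({
      sh <- 1.2 / sl
      c(shape = sh, scale = exp(ml + 0.5772 * sl)^(-sh))
    }),
    loglogistic = list(c(shape = pi / (sqrt(3) * sl), scale = exp(ml))),
    lognormal = list(c(meanlog = ml, sdlog = sl))
  )
  # add scaled variants of the first start as extra multistart points
  extra <- lapply(c(0.5, 2), function(fac) {
    st <- base[[1]]
    layout <- .family_params[[family]]
    st[layout] <- st[layout] * fac
    st
  })
  c(base, extra)
}

#' Fit a parametric survival distribution by maximum likelihood
#'
#' Maximizes the right-censored log-likelihood over the chosen family with a
#' multi-start quasi-Newton search on log-transformed positive parameters
#' (relative convergence tolerance 1e-8; the heavy-tailed families are
#' ill-conditioned, hence the multiple deterministic starting points). The
#' exponential family is solved in closed form (`rate = events / total time`).
#'
#' @param times Positive event/censoring times in months.
#' @param events Event indicators (1 = event, 0 = censored).
#' @param family One of [surv_families()].
#' @return A `parsurv_fit` object: the fitted [surv_spec()], the achieved
#'   `log_likelihood`, `n_params`, `n_obs`, `aic`, `bic` and a `converged`
#'   flag. Non-convergence is flagged, never silently dropped.
#' @export
fit_parametric <- function(times, events, family) {
  family <- match.arg(family, surv_families())
  events <- as.integer(events)
  if (length(times) != length(events)) stop("length mismatch", call. = FALSE)
  if (any(times <= 0)) stop("all times must be > 0", call. = FALSE)
  if (!any(events == 1)) {
    stop("all observations censored: cannot estimate", call. = FALSE)
  }
  k <- length(.family_params[[family]])
  if (sum(events) < k) {
    stop("need at least ", k, " uncensored observations for family '",
         family, "'", call. = FALSE)
  }
  n <- length(times)

  if (family == "exponential") {
    rate <- sum(events) / sum(times)
    spec <- surv_spec("exponential", c(rate = rate))
    ll <- surv_loglik(spec, times, events)
    return(.new_fit(spec, ll, k, n, converged = TRUE))
  }

  negll <- function(theta) {
    pars <- .to_natural(family, theta)
    spec <- try(surv_spec(family, pars), silent = TRUE)
    if (inherits(spec, "try-error")) return(1e10)
    v <- -suppressWarnings(surv_loglik(spec, times, events))
    if (!is.finite(v)) 1e10 else v
  }

  best <- NULL
  for (st in .start_values(family, times, events)) {
    th0 <- .to_working(family, st)
    opt <- try(stats::optim(th0, negll, method = "BFGS",
                            control = list(reltol = 1e-8, maxit = 500)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    opt2 <- try(stats::optim(opt$par, negll, method = "Nelder-Mead",
                             control = list(reltol = 1e-8, maxit = 2000)),
                silent = TRUE)
    if (!inherits(opt2, "try-error") && opt2$value < opt$value) opt <- opt2
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("optimization failed for family '", family, "'",
                          call. = FALSE)
  spec <- surv_spec(family, .to_natural(family, best$par))
  .new_fit(spec, -best$value, k, n,
           converged = best$convergence == 0 && best$value < 1e9)
}

.new_fit <- function(spec, ll, k, n, converged) {
  ic <- information_criteria(ll, k, n)
  structure(list(spec = spec, log_likelihood = ll, n_params = k, n_obs = n,
                 aic = ic[["aic"]], bic = ic[["bic"]], converged = converged),
            class = "parsurv_fit")
}

#' @export
print.parsurv_fit <- function(x, ...) {
  cat("<parsurv_fit> family:", x$spec$family,
      if (!x$converged) "(NOT CONVERGED)", "\n")
  cat("  params:", paste(sprintf("%s=%.5g", names(x$spec$params),
                                 x$spec$params), collapse = ", "), "\n")
  cat(sprintf("  logLik %.4f on %d obs | AIC %.3f | BIC %.3f\n",
              x$log_likelihood, x$n_obs, x$aic, x$bic))
  invisible(x)
}

#' @export
coef.parsurv_fit <- function(object, ...) object$spec$params

#' @export
logLik.parsurv_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_params,
            nobs = object$n_obs, class = "logLik")
}

#' Akaike and Bayesian information criteria
#'
#' `AIC = -2 LL + 2 k`; `BIC = -2 LL + k log(n)`.
#'
#' @param log_likelihood Achieved maximum log-likelihood.
#' @param n_params Number of free parameters `k >= 1`.
#' @param n_obs Number of observations `n >= 1`.
#' @return Named vector `c(aic, bic)`.
#' @export
information_criteria <- function(log_likelihood, n_params, n_obs) {
  stopifnot(n_params >= 1, n_obs >= 1)
  c(aic = -2 * log_likelihood + 2 * n_params,
    bic = -2 * log_likelihood + n_params * log(n_obs))
}

#' Fit all (or several) families to one dataset
#'
#' @inheritParams fit_parametric
#' @param families Families to fit; defaults to all eight.
#' @return List of `parsurv_fit` objects (failed fits are dropped with a
#'   warning).
#' @export
fit_all_families <- function(times, events, families = surv_families()) {
  fits <- list()
  for (fam in families) {
    f <- try(fit_parametric(times, events, fam), silent = TRUE)
    if (inherits(f, "try-error")) {
      warning("fit failed for family '", fam, "'", call. = FALSE)
    } else {
      fits[[fam]] <- f
    }
  }
  fits
}

#' Select the best-fitting survival model
#'
#' Minimal AIC wins; ties are broken by minimal BIC, then by fewer
#' parameters. Only converged fits are considered.
#'
#' @param fits List of `parsurv_fit` objects.
#' @return The winning [surv_spec()], with the full selection report (family,
#'   parameters, logLik, AIC, BIC) attached as attribute `"report"`.
#' @export
select_best <- function(fits) {
  if (length(fits) == 0) stop("no fits supplied", call. = FALSE)
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(fits) == 0) stop("no converged fits", call. = FALSE)
  report <- data.frame(
    family = vapply(fits, function(f) f$spec$family, ""),
    n_params = vapply(fits, function(f) as.integer(f$n_params), 0L),
    log_likelihood = vapply(fits, function(f) f$log_likelihood, 0),
    aic = vapply(fits, function(f) f$aic, 0),
    bic = vapply(fits, function(f) f$bic, 0),
    row.names = NULL)
  ord <- order(report$aic, report$bic, report$n_params)
  best <- fits[[ord[1]]]$spec
  attr(best, "report") <- report[ord, ]
  best
}

#' Write a plain-text fit report
#'
#' One row per candidate family: family, parameters, log-likelihood, AIC,
#' BIC, convergence flag.
#'
#' @param fits List of `parsurv_fit` objects.
#' @param path Output file (tab-delimited).
#' @return The report data frame, invisibly.
#' @export
write_fit_report <- function(fits, path) {
  rep <- data.frame(
    family = vapply(fits, function(f) f$spec$family, ""),
    params = vapply(fits, function(f)
      paste(sprintf("%s=%.6g", names(f$spec$params), f$spec$params),
            collapse = ";"), ""),
    log_likelihood = vapply(fits, function(f) f$log_likelihood, 0),
    aic = vapply(fits, function(f) f$aic, 0),
    bic = vapply(fits, function(f) f$bic, 0),
    converged = vapply(fits, function(f) f$converged, TRUE),
    row.names = NULL)
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rep)
}
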