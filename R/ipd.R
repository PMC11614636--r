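#' Digitized Kaplan-Meier curve with number-at-risk table
#'
#' Container for the coordinates read off a published KM plot plus its
#' number-at-risk table. Coordinates must start at (0, 1) and be
#' nonincreasing in survival; small digitization non-monotonicities
#' (increases up to `1e-3`) are tolerated and repaired by isotonic clipping
#' when the curve is used for reconstruction.
#'
#' @param coords Data frame or matrix with columns `time` (months) and
#'   `survival`.
#' @param risk_table Data frame or matrix with columns `time` (months) and
#'   `n_risk` (nonincreasing integer counts).
#' @param total_events Optional total number of events, if published.
#' @return An object of class `km_curve`.
#' @export
km_curve <- function(coords, risk_table, total_events = NULL) {
  coords <- as.data.frame(coords)
  names(coords)[1:2] <- c("time", "survival")
  risk_table <- as.data.frame(risk_table)
  names(risk_table)[1:2] <- c("time", "n_risk")
  if (nrow(coords) < 2) stop("need at least two coordinates", call. = FALSE)
  if (is.unsorted(coords$time)) stop("coordinate times must be sorted",
                                     call. = FALSE)
  if (coords$time[1] > risk_table$time[1]) {
    stop("first risk time must not exceed first coordinate time",
         call. = FALSE)
  }
  if (any(coords$survival < 0 | coords$survival > 1)) {
    stop("survival outside [0,1]", call. = FALSE)
  }
  rises <- diff(coords$survival)
  if (any(rises > 1e-3)) {
    stop("non-monotone survival input (increase > 1e-3)", call. = FALSE)
  }
  if (any(diff(risk_table$n_risk) > 0)) {
    stop("risk-table counts must be nonincreasing", call. = FALSE)
  }
  structure(list(coords = coords, risk_table = risk_table,
                 total_events = total_events), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> ", nrow(x$coords), " coordinates, ",
      nrow(x$risk_table), " risk-table entries, n0 = ",
      x$risk_table$n_risk[1], "\n", sep = "")
  invisible(x)
}

#' Reconstruct pseudo individual-patient data from a digitized KM curve
#'
#' Deterministic reconstruction of event and censoring times from KM
#' coordinates and a number-at-risk table. Within each inter-risk-time
#' interval the number censored is solved iteratively so that the implied
#' number at risk matches the published table, censoring times are spread
#' evenly across the interval, and event counts at each digitized drop are
#' chosen so the product-limit estimate tracks the digitized survival.
#' After the last risk time, remaining steps are treated as events and any
#' survivors are administratively censored at the final coordinate, so that
#' events + censorings always equal the initial number at risk. If
#' `total_events` is present on the curve, event counts are rescaled to
#' match it in a final adjustment pass.
#'
#' @param curve A [km_curve()] with at least two risk-table entries.
#' @return Data frame with columns `time` and `event` (1 event, 0 censored),
#'   one row per reconstructed subject.
#' @export
reconstruct_ipd <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  co <- curve$coords
  # isotonic repair of digitization noise
  co$survival <- cummin(co$survival)
  rt <- curve$risk_table
  if (nrow(rt) < 2) stop("need at least two risk-table entries",
                         call. = FALSE)

  K <- nrow(co)
  J <- nrow(rt)
  # interval j covers coordinates with time in (rt$time[j], rt$time[j+1]]:
  # published at-risk counts are read as post-event at the landmark, so an
  # event exactly at a risk time belongs to the preceding interval
  j_of_k <- findInterval(co$time, rt$time, left.open = TRUE)
  j_of_k <- pmin(pmax(j_of_k, 1L), J)

  ev_time <- numeric(0); ev_n <- integer(0)
  cn_time <- numeric(0); cn_n <- integer(0)
  n_cur <- rt$n_risk[1]
  km_prod <- 1          # product-limit estimate at the last processed event
  s_prev <- 1           # digitized survival at the last processed event

  for (j in seq_len(J)) {
    has_next <- j < J
    target_next <- if (has_next) rt$n_risk[j + 1] else NA_integer_
    idx <- which(j_of_k == j)
    c_guess <- 0L
    max_iter <- if (has_next) 40L else 1L
    repeat {
      # censor times spread evenly over the interval
      t_lo <- rt$time[j]
      t_hi <- if (has_next) rt$time[j + 1] else max(co$time)
      cens_t <- if (c_guess > 0) {
        t_lo + seq_len(c_guess) * (t_hi - t_lo) / (c_guess + 1)
      } else numeric(0)
      n <- n_cur; kmp <- km_prod; sp <- s_prev
      d_here <- integer(length(idx)); t_here <- co$time[idx]
      used_cens <- 0L
      for (ii in seq_along(idx)) {
        k <- idx[ii]
        # censorings occurring before this coordinate leave the risk set
        nc <- sum(cens_t <= co$time[k]) - used_cens
        n <- n - nc; used_cens <- used_cens + nc
        if (n <= 0) break
        d <- round(n * (1 - co$survival[k] / kmp))
        d <- max(0L, min(as.integer(d), n))
        if (d > 0) {
          kmp <- kmp * (1 - d / n)
          n <- n - d
        }
        d_here[ii] <- d
      }
      n <- n - (c_guess - used_cens)   # censorings after the last coordinate
      if (!has_next || n == target_next || max_iter <= 1L) {
        # commit
        keep <- d_here > 0
        ev_time <- c(ev_time, t_here[keep]); ev_n <- c(ev_n, d_here[keep])
        if (c_guess > 0) { cn_time <- c(cn_time, cens_t); cn_n <- c(cn_n, rep(1L, c_guess)) }
        n_cur <- n; km_prod <- kmp
        break
      }
      adj <- n - target_next
      c_new <- c_guess + as.integer(adj)
      if (c_new < 0) {
        if (c_guess == 0) {
          # risk table wants more subjects than survive the digitized drops:
          # irreconcilable; proceed with zero censoring
          keep <- d_here > 0
          ev_time <- c(ev_time, t_here[keep]); ev_n <- c(ev_n, d_here[keep])
          n_cur <- n; km_prod <- kmp
          warning("risk table inconsistent in interval ", j,
                  " (implied censoring negative)", call. = FALSE)
          break
        }
        c_new <- 0L
      }
      if (c_new == c_guess) max_iter <- 1L else c_guess <- c_new
      max_iter <- max_iter - 1L
    }
  }
  # survivors at the end are administratively censored at the last coordinate
  if (n_cur > 0) {
    cn_time <- c(cn_time, rep(max(co$time), n_cur))
    cn_n <- c(cn_n, rep(1L, n_cur))
    n_cur <- 0L
  }
  ipd <- rbind(
    data.frame(time = rep(ev_time, ev_n), event = 1L),
    data.frame(time = cn_time[rep(seq_along(cn_n), cn_n)], event = 0L)
  )
  ipd <- ipd[order(ipd$time, -ipd$event), , drop = FALSE]
  ipd$time <- pmax(ipd$time, 1e-9)
  rownames(ipd) <- NULL

  if (!is.null(curve$total_events) && sum(ipd$event) > 0) {
    # final adjustment: rescale event counts toward the published total by
    # flipping the latest events to censorings (or vice versa is impossible
    # deterministically, so only downscaling is applied)
    excess <- sum(ipd$event) - curve$total_events
    if (excess > 0) {
      flip <- utils::tail(which(ipd$event == 1L), excess)
      ipd$event[flip] <- 0L
    }
  }
  ipd
}

#' Product-limit (Kaplan-Meier) estimate with risk table
#'
#' Wraps the standard product-limit estimator and packages the result as a
#' [km_curve()] with a number-at-risk table on a regular grid.
#'
#' @param ipd Data frame with columns `time`, `event`.
#' @param risk_interval Risk-table spacing in months (default 3).
#' @return A [km_curve()].
#' @export
km_estimate <- function(ipd, risk_interval = 3) {
  stopifnot(nrow(ipd) > 0)
  fit <- survival::survfit(survival::Surv(ipd$time, ipd$event) ~ 1,
                           conf.type = "none")
  coords <- data.frame(time = c(0, fit$time), survival = c(1, fit$surv))
  rtimes <- seq(0, max(ipd$time) + 1e-9, by = risk_interval)
  # post-event counts at each landmark (subjects still under observation
  # just after it), matching the convention of published at-risk tables
  # and of reconstruct_ipd; censorings exactly at a landmark remain counted
  n_risk <- vapply(rtimes, function(t) {
    sum(ipd$time > t + 1e-12) +
      sum(abs(ipd$time - t) < 1e-12 & ipd$event == 0)
  }, 0)
  risk <- data.frame(time = rtimes, n_risk = n_risk)
  km_curve(coords, risk)
}

#' Read a digitized KM curve from delimited text files
#'
#' @param coords_path Two-column file (time, survival), with header.
#' @param risk_path Two-column file (time, n_risk), with header.
#' @param total_events Optional published event total.
#' @return A [km_curve()].
#' @export
read_km_curve <- function(coords_path, risk_path, total_events = NULL) {
  co <- utils::read.table(coords_path, header = TRUE, sep = "\t")
  rt <- utils::read.table(risk_path, header = TRUE, sep = "\t")
  km_curve(co, rt, total_events)
}

#' Write a KM curve to delimited text files
#'
#' @param curve A [km_curve()].
#' @param coords_path,risk_path Output paths (tab-delimited, with header).
#' @export
write_km_curve <- function(curve, coords_path, risk_path) {
  utils::write.table(curve$coords, coords_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(curve$risk_table, risk_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(curve)
}

#' Read / write individual-patient data as two-column delimited text
#'
#' @param path File path (tab-delimited `time`, `event`, with header).
#' @return `read_ipd` returns a data frame with columns `time` and `event`.
#' @export
read_ipd <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' @rdname read_ipd
#' @param ipd Data frame with columns `time`, `event`.
#' @export
write_ipd <- function(ipd, path) {
  utils::write.table(ipd[, c("time", "event")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(ipd)
}
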