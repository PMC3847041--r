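# The three kinetic models fitted by the pipeline, plus trace utilities:
#   - constant baseline followed by linear growth (junction assembly rate),
#   - single exponential decay to a plateau (junction disassembly tau),
#   - constant baseline followed by a rising double exponential (spheroid
#     roundness; the fast time constant summarizes formation speed).
# Breakpoints are profiled over sample times; exponential time constants use
# multi-start 1-D/2-D optimization with the linear parameters profiled out.

#' Construct a time-stamped scalar trace
#'
#' @param times strictly increasing time stamps (min or h, caller's choice).
#' @param values finite numeric values (intensity, count, roundness, ...).
#' @param event_time optional event time stamp (e.g. chelator addition).
#' @return an `IntensityTrace`.
#' @export
intensity_trace <- function(times, values, event_time = NULL) {
  stopifnot(length(times) == length(values))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!all(is.finite(values))) stop("values must be finite")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 event_time = event_time),
            class = "IntensityTrace")
}

#' @export
print.IntensityTrace <- function(x, ...) {
  cat(sprintf("IntensityTrace: %d points, t = %g..%g%s\n",
              length(x$times), min(x$times), max(x$times),
              if (!is.null(x$event_time))
                sprintf(", event at %g", x$event_time) else ""))
  invisible(x)
}

new_fit_result <- function(model, params, rss, converged,
                           n = NA_integer_) {
  structure(list(model = model, params = params, rss = rss,
                 converged = converged, n = n),
            class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf("FitResult[%s]%s rss=%.4g\n  %s\n", x$model,
              if (x$converged) "" else " (not converged)", x$rss,
              paste(names(x$params), signif(unlist(x$params), 4),
                    sep = "=", collapse = "  ")))
  invisible(x)
}

#' Normalize a trace to its pre-event baseline (percent)
#'
#' @param trace an `IntensityTrace`.
#' @param event_time event time; defaults to `trace$event_time`.
#' @return the trace with values divided by the pre-event mean, times 100.
#' @export
normalize_to_baseline <- function(trace, event_time = NULL) {
  stopifnot(inherits(trace, "IntensityTrace"))
  event_time <- event_time %||% trace$event_time %||%
    stop("no event time given")
  pre <- trace$values[trace$times < event_time]
  if (length(pre) < 2) stop("need at least 2 pre-event samples")
  m <- mean(pre)
  if (m <= 0) stop("pre-event mean is not positive")
  intensity_trace(trace$times, 100 * trace$values / m, event_time)
}

#' Fit a constant baseline followed by a linear rise
#'
#' Least-squares fit of `f(t) = b` for `t <= t0` and `b + m (t - t0)` after,
#' with the breakpoint `t0` profiled over the sample times (exhaustive
#' discrete search, each candidate solved in closed form). The slope `m` is
#' the assembly rate.
#'
#' @param trace an `IntensityTrace` (at least 6 samples).
#' @return a `FitResult` with params baseline, breakpoint, slope.
#' @export
fit_baseline_linear <- function(trace) {
  stopifnot(inherits(trace, "IntensityTrace"))
  t <- trace$times; y <- trace$values
  n <- length(t)
  if (n < 6) stop("need at least 6 samples")
  cand <- t[2:(n - 1)]
  best <- NULL
  for (t0 in cand) {
    ramp <- pmax(t - t0, 0)
    X <- cbind(1, ramp)
    co <- qr.coef(qr(X), y)
    rss <- sum((y - X %*% co)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(t0 = t0, b = co[1], m = co[2], rss = rss)
  }
  new_fit_result("baseline_linear",
                 list(baseline = unname(best$b), breakpoint = best$t0,
                      slope = unname(best$m)),
                 best$rss, converged = TRUE, n = n)
}

# profiled RSS of I(t) = plateau + A exp(-t_rel / tau): linear in
# (plateau, A) for fixed tau
.exp_profile <- function(ltau, t_rel, y) {
  e <- exp(-t_rel / exp(ltau))
  X <- cbind(1, e)
  co <- tryCatch(qr.coef(qr(X), y), error = function(e) c(NA, NA))
  if (any(!is.finite(co))) return(list(rss = Inf, co = co))
  list(rss = sum((y - X %*% co)^2), co = co)
}

#' Fit an exponential decay to a plateau
#'
#' Least-squares fit of `I(t) = plateau + A exp(-(t - fit_start)/tau)` on
#' samples with `t >= fit_start`. The linear parameters are profiled out and
#' `tau` is optimized from multiple log-spaced initializations (exponential
#' fits are initialization-sensitive); the best-RSS solution is kept. A
#' genotype-specific onset lag is handled by shifting `fit_start` (the decay
#' for a lagged construct is fitted from event + lag).
#'
#' @param trace an `IntensityTrace` (at least 4 samples past `fit_start`).
#' @param fit_start fit onset, minutes; defaults to `trace$event_time`.
#' @return a `FitResult` with params plateau, amplitude, tau, fit_start.
#'   `converged` is FALSE when the decay amplitude is not positive (e.g. a
#'   rising or constant trace leaves tau unidentifiable).
#' @export
fit_exp_decay <- function(trace, fit_start = NULL) {
  stopifnot(inherits(trace, "IntensityTrace"))
  fit_start <- fit_start %||% trace$event_time %||% min(trace$times)
  sel <- trace$times >= fit_start - 1e-9
  if (sum(sel) < 4) stop("need at least 4 samples at t >= fit_start")
  t_rel <- trace$times[sel] - fit_start
  y <- trace$values[sel]
  dt <- median(diff(trace$times))
  lo <- log(dt / 50); hi <- log(diff(range(t_rel)) * 1e3)
  best <- NULL
  for (tau0 in c(1, 5, 20, 80) * dt) {
    o <- tryCatch(
      optim(log(tau0), function(p) .exp_profile(p, t_rel, y)$rss,
            method = "L-BFGS-B", lower = lo, upper = hi),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best))
    return(new_fit_result("exp_decay", list(), Inf, FALSE, length(y)))
  # local Brent polish around the multi-start winner
  pol <- stats::optimize(function(p) .exp_profile(p, t_rel, y)$rss,
                         interval = pmin(pmax(best$par + c(-0.7, 0.7), lo),
                                         hi),
                         tol = 1e-12)
  if (pol$objective <= best$value)
    best <- list(par = pol$minimum, value = pol$objective)
  prof <- .exp_profile(best$par, t_rel, y)
  tau <- exp(best$par)
  amp <- unname(prof$co[2]); plateau <- unname(prof$co[1])
  scale <- max(abs(y)) + 1e-12
  converged <- is.finite(amp) && amp > 1e-6 * scale &&
    best$par > lo + 1e-6 && best$par < hi - 1e-6
  new_fit_result("exp_decay",
                 list(plateau = plateau, amplitude = amp, tau = tau,
                      fit_start = fit_start),
                 prof$rss, converged, length(y))
}

# profiled RSS for the baseline + rising double exponential. For fixed
# (t0, tau_f, tau_s) the model is linear in (plateau, A_f, A_s):
#   t <= t0: plateau - A_f - A_s     (continuity fixes the baseline)
#   t >  t0: plateau - A_f e_f - A_s e_s
.dexp_profile <- function(par, t, y, t0) {
  tf <- exp(par[1]); ts <- exp(par[2])
  post <- t > t0
  ef <- ifelse(post, exp(-(t - t0) / tf), 1)
  es <- ifelse(post, exp(-(t - t0) / ts), 1)
  X <- cbind(1, -ef, -es)
  co <- tryCatch(qr.coef(qr(X), y), error = function(e) rep(NA, 3))
  if (any(!is.finite(co))) return(list(rss = Inf, co = co))
  list(rss = sum((y - X %*% co)^2), co = co)
}

#' Fit a constant baseline followed by a rising double exponential
#'
#' Least-squares fit of roundness-type trajectories: `R(t) = b` up to the
#' breakpoint, then `plateau - A_f exp(-(t-t0)/tau_fast) -
#' A_s exp(-(t-t0)/tau_slow)`, fitted on samples with `t <= t_max` (the
#' published analysis window is 20 h). The breakpoint is profiled over
#' sample times; `(tau_fast, tau_slow)` are optimized from a small grid of
#' starts with the amplitudes and plateau profiled out; continuity at the
#' breakpoint ties the baseline to `plateau - A_f - A_s`. The fast time
#' constant is the formation time constant.
#'
#' @param trace an `IntensityTrace` (at least 10 samples within `t_max`).
#' @param t_max upper fit limit in the trace's time unit (default 20).
#' @return a `FitResult` with params baseline, breakpoint, plateau,
#'   amp_fast, tau_fast, amp_slow, tau_slow. `converged` is FALSE for
#'   flat traces or when `tau_fast`/`tau_slow` are within 5 percent of each
#'   other (not separately identifiable).
#' @export
fit_baseline_double_exp <- function(trace, t_max = 20) {
  stopifnot(inherits(trace, "IntensityTrace"))
  sel <- trace$times <= t_max + 1e-9
  t <- trace$times[sel]; y <- trace$values[sel]
  n <- length(t)
  if (n < 10) stop("need at least 10 samples with t <= t_max")
  span <- diff(range(t))
  cand_all <- t[t <= min(t) + 0.6 * span &
                  seq_len(n) >= 2 & seq_len(n) <= n - 4]
  cand <- cand_all
  if (length(cand) > 25)
    cand <- cand[round(seq(1, length(cand), length.out = 25))]
  starts <- expand.grid(tf = span * c(0.02, 0.08, 0.25),
                        ts = span * c(0.15, 0.5, 1.5))
  starts <- starts[starts$tf < starts$ts, ]
  run_t0 <- function(t0, par_starts) {
    best <- NULL
    for (s in seq_len(nrow(par_starts))) {
      o <- tryCatch(
        optim(log(as.numeric(par_starts[s, ])),
              function(p) .dexp_profile(p, t, y, t0)$rss,
              method = "Nelder-Mead",
              control = list(reltol = 1e-12, maxit = 500)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    best
  }
  best <- NULL
  for (t0 in cand) {
    o <- run_t0(t0, starts)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) {
      best <- o; best$t0 <- t0
    }
  }
  # dense local refinement: try every sample time skipped near the winner
  if (!is.null(best) && length(cand) < length(cand_all)) {
    step <- max(diff(cand))
    near <- setdiff(cand_all[abs(cand_all - best$t0) <= step], cand)
    for (t0 in near) {
      o <- run_t0(t0, as.data.frame(t(exp(best$par))))
      if (!is.null(o) && o$value < best$value) {
        best <- o; best$t0 <- t0
      }
    }
  }
  if (is.null(best))
    return(new_fit_result("baseline_double_exp", list(), Inf, FALSE, n))
  # polish the winner
  o <- optim(best$par, function(p) .dexp_profile(p, t, y, best$t0)$rss,
             method = "Nelder-Mead",
             control = list(reltol = 1e-14, maxit = 2000))
  prof <- .dexp_profile(o$par, t, y, best$t0)
  taus <- exp(o$par); amps <- unname(prof$co[2:3])
  ord <- order(taus)
  taus <- taus[ord]; amps <- amps[ord]
  plateau <- unname(prof$co[1])
  scale <- diff(range(y)) + 1e-12
  flat <- sum(abs(amps)) < 1e-3 * scale
  unident <- taus[2] / taus[1] < 1.05
  if (unident && !flat)
    warning("tau_fast and tau_slow are not separately identifiable")
  new_fit_result("baseline_double_exp",
                 list(baseline = plateau - sum(amps), breakpoint = best$t0,
                      plateau = plateau,
                      amp_fast = amps[1], tau_fast = taus[1],
                      amp_slow = amps[2], tau_slow = taus[2]),
                 prof$rss, converged = !flat && !unident, n = n)
}
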