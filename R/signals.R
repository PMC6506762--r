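#' Time-series trace
#'
#' A validated, regular container for one measured channel: time in seconds
#' from the experiment origin (strictly increasing after averaging of
#' duplicated timestamps) and the measured value.  At least four samples
#' are required so that a cubic smoothing spline is well defined.
#'
#' @param time sample times, s.
#' @param value measured values (channel units).
#' @param channel channel label, e.g. `"temperature"`, `"ppfd"`.
#' @return A data frame of class `eb_trace` with columns `time`, `value`.
#' @export
eb_trace <- function(time, value, channel = "temperature") {
  if (length(time) != length(value))
    stop("eb_trace: time and value lengths differ")
  if (anyNA(time) || anyNA(value))
    stop("eb_trace: missing values are not allowed")
  if (is.unsorted(time))
    stop("eb_trace: time must be non-decreasing")
  if (anyDuplicated(time)) {        # average duplicated timestamps
    value <- as.numeric(tapply(value, time, mean))
    time <- sort(unique(time))
  }
  if (length(time) < 4)
    stop("eb_trace: at least 4 distinct samples are required, got ",
         length(time))
  structure(data.frame(time = as.numeric(time), value = as.numeric(value)),
            channel = channel, class = c("eb_trace", "data.frame"))
}

as_eb_trace <- function(x, channel = "temperature") {
  if (inherits(x, "eb_trace")) return(x)
  if (is.data.frame(x) && all(c("time", "value") %in% names(x)))
    return(eb_trace(x$time, x$value, channel))
  stop("cannot interpret object as a trace")
}

#' Smooth a noisy trace into a differentiable function of time
#'
#' Fits a cubic smoothing spline (generalized cross-validation selects the
#' smoothing parameter unless one is supplied) and returns an object that
#' evaluates both the smoothed value and its first time-derivative at any
#' time inside the observed span.  This is the form required by the ODE
#' solver: the reference temperature and every environmental channel enter
#' the differenced energy-balance model as smooth functions of time.
#'
#' Evaluation outside the observed span is an error, never a silent
#' extrapolation.
#'
#' A step in the driving light leaves a kink (slope discontinuity) in a
#' reference's temperature trace.  A single spline smeared across such a
#' kink produces a locally biased derivative, which the differenced model
#' amplifies by the reference's areal heat capacity; passing the known
#' switch times as `breaks` fits an independent spline per segment and
#' removes that bias.
#'
#' @param trace an [eb_trace()] (or data frame with `time`/`value`).
#' @param smoothing optional smoothing parameter passed to
#'   [stats::smooth.spline()] as `spar` (roughly 0--1.5; larger is
#'   smoother).  `NULL` (default) selects it by generalized
#'   cross-validation.
#' @param nknots number of spline knots per segment; defaults to one knot
#'   per 10 s of record (at least 10, at most the number of samples) so
#'   that fast thermal transients are resolved even on long records.
#' @param breaks optional interior event times (s) at which the smoothed
#'   curve may have a slope discontinuity.
#' @param exp_trend fit an exponential-plus-linear trend per segment
#'   before splining the residual (default when `breaks` are given).
#'   Segments that start at a driver step are first-order relaxations
#'   whose curvature peaks exactly where a natural spline is constrained
#'   flat; absorbing that shape first keeps the derivative unbiased at
#'   the segment boundaries.
#' @return An object of class `smooth_signal` with elements `value(t)`,
#'   `deriv(t)`, `domain` (c(t_min, t_max)) and `residual_sd` (K, the
#'   standard deviation of the fit residuals).
#' @examples
#' tr <- eb_trace(0:100, sin(0:100 / 20) + rnorm(101, 0, 0.01))
#' sig <- smooth_signal(tr)
#' sig$value(50); sig$deriv(50)
#' @export
smooth_signal <- function(trace, smoothing = NULL, nknots = NULL,
                          breaks = NULL, exp_trend = !is.null(breaks)) {
  trace <- as_eb_trace(trace)
  t <- trace$time; y <- trace$value
  n <- length(t)
  breaks <- breaks[breaks > t[1] & breaks < t[n]]
  edges <- c(t[1], sort(unique(breaks)), t[n])
  seg_id <- pmin(findInterval(t, edges, rightmost.closed = TRUE),
                 length(edges) - 1)
  # segments too short to smooth are merged into their neighbour
  while (min(tabulate(seg_id)) < 8 && length(edges) > 2) {
    short <- which.min(tabulate(seg_id))
    edges <- edges[-(short + (short < length(edges) - 1))]
    seg_id <- pmin(findInterval(t, edges, rightmost.closed = TRUE),
                   length(edges) - 1)
  }
  fit_segment <- function(ti, yi) {
    t0 <- ti[1]; span <- ti[length(ti)] - t0
    # A segment that starts at a driver step is a first-order relaxation:
    # its curvature is largest exactly where a natural spline is forced
    # flat (the segment edge).  Absorb that structure with an
    # exponential-plus-linear basis first, and spline only the residual;
    # the derivative then stays unbiased at the segment boundaries.
    base_val <- function(x) 0; base_der <- function(x) 0
    if (exp_trend && length(ti) >= 12 && span > 30) {
      rss_tau <- function(tau) {
        X <- cbind(1, ti - t0, exp(-(ti - t0) / tau))
        sum(stats::lm.fit(X, yi)$residuals^2)
      }
      tau_hat <- stats::optimize(rss_tau, c(5, 2 * span))$minimum
      X <- cbind(1, ti - t0, exp(-(ti - t0) / tau_hat))
      cf <- stats::lm.fit(X, yi)$coefficients
      cf[is.na(cf)] <- 0
      base_val <- function(x)
        cf[1] + cf[2] * (x - t0) + cf[3] * exp(-(x - t0) / tau_hat)
      base_der <- function(x)
        cf[2] - cf[3] / tau_hat * exp(-(x - t0) / tau_hat)
      yi <- yi - base_val(ti)
    }
    nk <- if (is.null(nknots))
      max(10, min(length(ti), ceiling(span / 10) + 4))
    else min(nknots, length(ti))
    nk <- min(nk, length(ti))
    fit <- if (!is.null(smoothing)) {
      stopifnot(smoothing >= 0)
      stats::smooth.spline(ti, yi, nknots = nk, spar = smoothing,
                           keep.data = FALSE)
    } else if (exp_trend && length(ti) >= 12 && span > 30) {
      # the exponential-plus-linear basis already carries the physics of
      # a step-response segment; what remains is dominated by sensor
      # noise, so the residual spline gets only a few degrees of freedom
      # rather than letting cross-validation chase the noise
      stats::smooth.spline(ti, yi, nknots = nk,
                           df = min(8, length(ti) - 4),
                           keep.data = FALSE)
    } else {
      stats::smooth.spline(ti, yi, nknots = nk, cv = FALSE,
                           keep.data = FALSE)
    }
    yhat <- predict(fit, ti)$y
    # interpolating natural cubic through the smoothed residual: fast
    # C-level evaluation of value and (consistent) first derivative
    fr <- stats::splinefun(ti, yhat, method = "natural")
    list(f = function(x, deriv = 0) {
           if (deriv == 0) fr(x) + base_val(x)
           else fr(x, deriv = 1L) + base_der(x)
         },
         yhat = yhat + base_val(ti), spar = fit$spar)
  }
  segs <- lapply(seq_len(length(edges) - 1), function(s)
    fit_segment(t[seg_id == s], y[seg_id == s]))
  dom <- c(t[1], t[n])
  chk <- function(x) {
    if (any(x < dom[1] - 1e-9) || any(x > dom[2] + 1e-9))
      stop("smooth_signal: evaluation outside domain [", dom[1], ", ",
           dom[2], "] s")
    x
  }
  seg_of <- function(x) pmin(findInterval(x, edges, rightmost.closed = TRUE),
                             length(edges) - 1)
  eval_seg <- function(x, deriv) {
    s <- seg_of(chk(x))
    out <- numeric(length(x))
    for (si in unique(s))
      out[s == si] <- segs[[si]]$f(x[s == si], deriv = deriv)
    out
  }
  yhat_all <- unlist(lapply(seq_along(segs), function(s) segs[[s]]$yhat))
  structure(list(
    value = function(tt) eval_seg(tt, 0L),
    deriv = function(tt) eval_seg(tt, 1L),
    domain = dom,
    residual_sd = stats::sd(y[order(seg_id)] - yhat_all),
    spar = segs[[1]]$spar,
    breaks = edges[-c(1, length(edges))],
    channel = attr(trace, "channel")
  ), class = "smooth_signal")
}

#' @export
print.smooth_signal <- function(x, ...) {
  cat("<smooth_signal>", x$channel, "on [", x$domain[1], ",", x$domain[2],
      "] s; residual sd =", signif(x$residual_sd, 3),
      "; spar =", signif(x$spar, 3), "\n")
  invisible(x)
}

# exact (noise-free) signal from known values: linear interpolation with a
# consistent derivative; used by the forward simulator where the
# environmental drivers are known functions rather than measurements
exact_signal <- function(time, value, channel = "driver") {
  f <- stats::approxfun(time, value, rule = 2)
  dy <- diff(value) / diff(time)
  df <- stats::approxfun(time[-length(time)], dy, method = "constant",
                         rule = 2)
  structure(list(
    value = f,
    deriv = function(tt) df(tt),
    domain = range(time),
    residual_sd = 0,
    spar = NA_real_,
    channel = channel
  ), class = "smooth_signal")
}
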