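#' High-pass filter and z-normalise a response trace
#'
#' Butterworth high-pass (default 0.2 Hz, order 5, zero-phase via
#' forward-backward filtering), then z-normalisation (subtract the trace
#' mean, divide by its s.d.).
#'
#' @param trace a [response_trace].
#' @param hp_cutoff_hz high-pass cutoff (Hz); `NULL` skips filtering.
#' @param order filter order.
#' @return the filtered, z-scored [response_trace].
#' @export
preprocess <- function(trace, hp_cutoff_hz = 0.2, order = 5) {
  stopifnot(inherits(trace, "response_trace"))
  y <- trace$values
  if (length(y) < 3 * (order + 1))
    stop("trace shorter than the filter warm-up", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("degenerate trace: zero variance", call. = FALSE)
  if (!is.null(hp_cutoff_hz)) {
    wn <- hp_cutoff_hz / (trace$rate_hz / 2)
    if (wn >= 1) stop("cutoff must be below the Nyquist frequency", call. = FALSE)
    bf <- signal::butter(order, wn, type = "high")
    y <- signal::filtfilt(bf, y)
  }
  if (stats::sd(y) == 0)
    stop("degenerate trace after filtering: zero variance", call. = FALSE)
  trace$values <- (y - mean(y)) / stats::sd(y)
  trace
}

#' Smoothed response with pointwise uncertainty
#'
#' Posterior mean and s.d. of a response on a regular (optionally warped)
#' time grid, as produced by [smooth_response].
#'
#' @param mean,sd numeric vectors of equal length; `sd >= 0`.
#' @param times grid times (s).
#' @param condition_label condition name.
#' @param discarded flag set when the response set is non-responsive.
#' @return An object of class `smoothed_response`.
#' @export
smoothed_response <- function(mean, sd, times, condition_label = "",
                              discarded = FALSE) {
  if (length(mean) != length(sd) || length(mean) != length(times))
    stop("mean, sd and times must have equal length", call. = FALSE)
  if (any(sd < 0)) stop("sd must be non-negative", call. = FALSE)
  structure(list(mean = mean, sd = sd, times = times,
                 rate_hz = 1 / mean(diff(times)),
                 condition_label = condition_label,
                 discarded = isTRUE(discarded)),
            class = "smoothed_response")
}

#' @export
print.smoothed_response <- function(x, ...) {
  cat(sprintf("<smoothed_response> '%s': %d grid points%s, mean range [%.3g, %.3g]\n",
              x$condition_label, length(x$mean),
              if (x$discarded) " [DISCARDED]" else "", min(x$mean), max(x$mean)))
  invisible(x)
}

#' @export
plot.smoothed_response <- function(x, ...) {
  graphics::plot(x$times, x$mean, type = "l", xlab = "time (s)", ylab = "response",
                 main = x$condition_label, ...)
  graphics::polygon(c(x$times, rev(x$times)),
                    c(x$mean + 3 * x$sd, rev(x$mean - 3 * x$sd)),
                    border = NA, col = grDevices::adjustcolor("grey50", 0.3))
  graphics::lines(x$times, x$mean)
  invisible(x)
}

# GP regression with an RBF kernel on scattered (t, y) observations.
# Returns posterior mean and s.d. of the latent mean on grid `tout`.
gp_posterior <- function(t_obs, y_obs, tout, variance, lengthscale, noise_var) {
  k <- function(a, b) variance * exp(-outer(a, b, "-")^2 / (2 * lengthscale^2))
  K <- k(t_obs, t_obs)
  diag(K) <- diag(K) + noise_var + 1e-8
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), y_obs))
  Ks <- k(tout, t_obs)
  mu <- drop(Ks %*% alpha)
  V <- forwardsolve(t(L), t(Ks))
  var_post <- pmax(variance - colSums(V^2), 0)
  list(mean = mu, sd = sqrt(var_post))
}

#' Gaussian-process smoothing of trial responses
#'
#' Fits a GP regression with a radial-basis-function kernel (kernel variance
#' 1.1, lengthscale 0.05 s by default) to all trials of each stimulus
#' condition and evaluates the posterior mean and s.d. on a 50 Hz grid, with
#' a finer grid (default 125 Hz) inside `warp_window` to capture fast
#' kinetics during the moving-bar epoch. Responses whose posterior-mean s.d.
#' across time stays below 0.1 for every condition are flagged `discarded`
#' (non-responsive).
#'
#' @param traces_by_condition named list; each element is a list of
#'   [response_trace] trials for one condition.
#' @param kernel_variance,lengthscale RBF kernel parameters (lengthscale in
#'   seconds).
#' @param out_rate_hz output grid rate (Hz).
#' @param warp_window optional `c(t0, t1)` (s) refined at `warp_rate_hz`.
#' @param warp_rate_hz grid rate inside `warp_window`.
#' @param noise_var observation noise variance; `NULL` estimates it from
#'   between-trial variance (falls back to half the lag-1 squared difference
#'   for single trials).
#' @param discard_sd_threshold the non-responsiveness threshold (0.1).
#' @return named list of [smoothed_response], one per condition, all sharing
#'   the same `discarded` flag.
#' @export
smooth_response <- function(traces_by_condition, kernel_variance = 1.1,
                            lengthscale = 0.05, out_rate_hz = 50,
                            warp_window = NULL, warp_rate_hz = 125,
                            noise_var = NULL, discard_sd_threshold = 0.1) {
  if (length(traces_by_condition) == 0L)
    stop("missing condition: no traces supplied", call. = FALSE)
  if (any(vapply(traces_by_condition, length, integer(1)) == 0L))
    stop("missing condition: empty trial list", call. = FALSE)
  fits <- lapply(names(traces_by_condition), function(cond) {
    trials <- traces_by_condition[[cond]]
    t_obs <- unlist(lapply(trials, function(tr)
      (seq_along(tr$values) - 0.5) / tr$rate_hz))
    y_obs <- unlist(lapply(trials, function(tr) tr$values))
    dur <- max(t_obs)
    grid <- seq(1 / (2 * out_rate_hz), dur, by = 1 / out_rate_hz)
    if (!is.null(warp_window)) {
      fine <- seq(warp_window[1], warp_window[2], by = 1 / warp_rate_hz)
      grid <- sort(unique(c(grid[grid < warp_window[1] | grid > warp_window[2]], fine)))
    }
    nv <- noise_var
    if (is.null(nv)) {
      if (length(trials) >= 2L) {
        ymat <- try(do.call(cbind, lapply(trials, `[[`, "values")), silent = TRUE)
        nv <- if (inherits(ymat, "try-error")) NULL else mean(apply(ymat, 1, stats::var))
      }
      if (is.null(nv) || !is.finite(nv) || nv <= 0)
        nv <- max(mean(diff(y_obs[order(t_obs)])^2) / 2, 1e-6)
    }
    post <- gp_posterior(t_obs, y_obs, grid, kernel_variance, lengthscale, nv)
    smoothed_response(post$mean, post$sd, grid, condition_label = cond)
  })
  names(fits) <- names(traces_by_condition)
  max_sd <- max(vapply(fits, function(f) stats::sd(f$mean), numeric(1)))
  if (max_sd < discard_sd_threshold)
    fits <- lapply(fits, function(f) { f$discarded <- TRUE; f })
  fits
}

#' d-prime between two smoothed responses
#'
#' \deqn{d' = (\mu_1 - \mu_2) / \sqrt{0.5 (\sigma_1^2 + \sigma_2^2)}}
#' where \eqn{\mu_i} is the peak of the posterior mean inside `window` and
#' \eqn{\sigma_i} the posterior s.d. at that peak.
#'
#' @param r1,r2 [smoothed_response] objects (not discarded).
#' @param window optional `c(t0, t1)` restricting the peak search (the epoch
#'   of bar presentation); default the full grid.
#' @return the d-prime statistic.
#' @export
d_prime <- function(r1, r2, window = NULL) {
  stopifnot(inherits(r1, "smoothed_response"), inherits(r2, "smoothed_response"))
  if (r1$discarded || r2$discarded)
    stop("d-prime on a discarded (non-responsive) response", call. = FALSE)
  pk <- function(r) {
    sel <- if (is.null(window)) rep(TRUE, length(r$times))
           else r$times >= window[1] & r$times <= window[2]
    if (!any(sel)) stop("window outside the response grid", call. = FALSE)
    i <- which(sel)[which.max(r$mean[sel])]
    c(mu = r$mean[i], sigma = r$sd[i])
  }
  a <- pk(r1); b <- pk(r2)
  denom <- sqrt(0.5 * (a["sigma"]^2 + b["sigma"]^2))
  if (denom == 0) {
    if (a["mu"] == b["mu"]) return(0)
    stop("d-prime undefined: zero pooled s.d.", call. = FALSE)
  }
  unname((a["mu"] - b["mu"]) / denom)
}
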