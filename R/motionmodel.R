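#' Predicted response container
#' @param values numeric vector over time.
#' @param dt seconds per bin.
#' @param stim_label,rf_label metadata.
#' @return An object of class `predicted_response`.
#' @export
predicted_response <- function(values, dt, stim_label = "", rf_label = "") {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("predicted response must be finite", call. = FALSE)
  structure(list(values = values, dt = dt, stim_label = stim_label,
                 rf_label = rf_label),
            class = "predicted_response")
}

#' @export
print.predicted_response <- function(x, ...) {
  cat(sprintf("<predicted_response> rf '%s' x stim '%s': %d bins @ dt %g s, peak %.4g\n",
              x$rf_label, x$stim_label, length(x$values), x$dt, max(x$values)))
  invisible(x)
}

# Linearly resample RF onto the (dx, dt) grid of a stimulus, preserving the
# discrete weight sum (weights are rescaled by the bin-size ratios so the
# convolution approximates the same continuous integral).
resample_rf <- function(rf, dx, dt) {
  if (abs(rf$dx - dx) < 1e-12 && abs(rf$dt - dt) < 1e-12) return(rf)
  xs_old <- stim_space(rf)
  xs_new <- seq(xs_old[1], xs_old[length(xs_old)], by = dx)
  lag_old <- rf_lags(rf)
  lag_new <- seq(dt / 2, rf$lag_span_s, by = dt)
  w1 <- t(apply(rf$weights, 1L, function(row)
    stats::approx(lag_old, row, xout = lag_new, rule = 2)$y))
  if (length(lag_new) == 1L) w1 <- matrix(w1, ncol = 1L)
  w2 <- apply(w1, 2L, function(col)
    stats::approx(xs_old, col, xout = xs_new, rule = 2)$y)
  if (length(xs_new) == 1L) w2 <- matrix(w2, nrow = 1L)
  w2 <- w2 * (dx / rf$dx) * (dt / rf$dt)
  spacetime_rf(w2, dx = dx, dt = dt, origin_um = xs_new[1],
               center_um = rf$center_um, polarity = rf$polarity,
               ipl_depth = rf$ipl_depth, label = rf$label)
}

#' Linear convolution prediction of a response
#'
#' For each spatial bin, the RF's lag kernel at that bin is convolved
#' (causally) with the stimulus time course at the same physical location,
#' and the results are summed over space:
#' \deqn{r(t) = \sum_x \sum_{l} W[x, l] \, S[x, t - l]}
#' The stimulus is zero before onset (zero padding); RF bins outside the
#' stimulus extent see zero contrast. Grids are aligned by physical
#' coordinates; if `dx`/`dt` differ the RF is resampled (requires
#' `resample = TRUE`).
#'
#' @param rf a [spacetime_rf].
#' @param stim a [spacetime_stim].
#' @param resample allow resampling the RF onto the stimulus grid.
#' @return a [predicted_response] with `length(values) == ncol(stim$values)`.
#' @export
conv_predict <- function(rf, stim, resample = TRUE) {
  if (abs(rf$dx - stim$dx) > 1e-12 || abs(rf$dt - stim$dt) > 1e-12) {
    if (!resample)
      stop("RF and stimulus grids differ (dx/dt); enable resample", call. = FALSE)
    rf <- resample_rf(rf, stim$dx, stim$dt)
  }
  xs_rf <- stim_space(rf)
  xs_st <- stim_space(stim)
  # map RF rows onto stimulus rows by physical position (bin-centre match)
  idx <- round((xs_rf - stim$origin_um) / stim$dx) + 1L
  keep <- idx >= 1L & idx <= nrow(stim$values) &
    abs(stim$origin_um + (idx - 1) * stim$dx - xs_rf) < stim$dx / 2 + 1e-9
  W <- rf$weights[keep, , drop = FALSE]
  S <- stim$values[idx[keep], , drop = FALSE]
  nt <- ncol(S); nl <- ncol(W)
  out <- numeric(nt)
  if (nrow(W) > 0L) {
    M <- crossprod(W, S)          # nl x nt: M[l, s] = sum_x W[x,l] S[x,s]
    for (l in seq_len(nl)) {
      # lag bin l reaches back (l-1) stimulus bins
      if (l <= nt) out[l:nt] <- out[l:nt] + M[l, 1:(nt - l + 1L)]
    }
  }
  predicted_response(out, dt = stim$dt, stim_label = stim$label,
                     rf_label = rf$label)
}

#' Preference index between two responses
#'
#' `(peak1 - peak2) / (peak1 + peak2)` with peaks the maxima over time.
#'
#' @param resp1,resp2 [predicted_response] (or any object with `$values`).
#' @return dimensionless index in \[-1, 1\] when both peaks are >= 0.
#' @export
preference_index <- function(resp1, resp2) {
  p1 <- max(resp1$values); p2 <- max(resp2$values)
  if (p1 + p2 == 0) stop("preference index undefined: both peaks are zero", call. = FALSE)
  (p1 - p2) / (p1 + p2)
}

#' Radial direction selectivity tuning of an RF
#'
#' For each velocity, generates a pair of stimuli anchored to the RF centre
#' and returns the [preference_index] of the first over the second. Pairings:
#' \describe{
#' \item{originate_vs_terminate}{bar onset edge at the RF centre moving
#'   outward over `span_um`, vs. a bar starting `span_um` into the surround
#'   moving inward and stopping at the centre (same region, reversed time).}
#' \item{left_vs_right}{pass-through bars spanning surround-centre-surround
#'   in the two directions.}
#' \item{loom_vs_recede}{expanding vs. contracting spot centred on the RF;
#'   the velocity is the diameter expansion rate.}
#' \item{motion_vs_random}{ordered 7-bar apparent motion originating at the
#'   centre vs. the mean peak of random orderings of the same bars, at
#'   apparent velocity `v` (dwell = pitch / v).}
#' }
#' Off RFs are polarity-flipped before peak-taking so peaks are positive.
#'
#' @param rf a [spacetime_rf].
#' @param velocities vector of velocities (um/s), > 0.
#' @param pairing one of the pairings above.
#' @param span_um motion span on each side of the centre (um).
#' @param bar_w_um bar width (um).
#' @param n_random random orderings averaged in `motion_vs_random`.
#' @param seed seed for the random orderings.
#' @return An object of class `velocity_tuning`: data.frame with `velocity_um_s`
#'   and `preference`.
#' @export
rds_tuning <- function(rf, velocities,
                       pairing = c("originate_vs_terminate", "left_vs_right",
                                   "loom_vs_recede", "motion_vs_random"),
                       span_um = 150, bar_w_um = 20, n_random = 10, seed = 1) {
  pairing <- match.arg(pairing)
  if (length(velocities) == 0L) stop("velocity list must be non-empty", call. = FALSE)
  if (any(velocities <= 0)) stop("velocities must be positive", call. = FALSE)
  flip <- if (rf$polarity == "Off") -1 else 1
  peak_of <- function(stim) {
    stim <- pad_stimulus(stim, after_s = rf$lag_span_s)
    v <- conv_predict(rf, stim)$values * flip
    max(v)
  }
  c0 <- rf$center_um
  pref <- vapply(velocities, function(v) {
    if (pairing == "originate_vs_terminate") {
      # exact time-reverse pair over [c0, c0 + span + bar]: the originating
      # bar body appears at the centre edge and moves outward; the
      # terminating bar arrives from the surround and stops at the centre
      ext <- c(c0 - bar_w_um, c0 + span_um + 2 * bar_w_um)
      so <- make_moving_bar(bar_w_um, v, span_um, +1, start_um = c0 + bar_w_um,
                            dx = rf$dx, dt = rf$dt, extent_um = ext)
      st <- make_moving_bar(bar_w_um, v, span_um, -1, start_um = c0 + span_um,
                            dx = rf$dx, dt = rf$dt, extent_um = ext)
      (peak_of(so) - peak_of(st)) / (peak_of(so) + peak_of(st))
    } else if (pairing == "left_vs_right") {
      d <- 2 * span_um + bar_w_um
      sl <- make_moving_bar(bar_w_um, v, d, -1, start_um = c0 + span_um,
                            dx = rf$dx, dt = rf$dt,
                            extent_um = c0 + c(-span_um - bar_w_um, span_um + bar_w_um))
      sr <- make_moving_bar(bar_w_um, v, d, +1, start_um = c0 - span_um,
                            dx = rf$dx, dt = rf$dt,
                            extent_um = c0 + c(-span_um - bar_w_um, span_um + bar_w_um))
      (peak_of(sl) - peak_of(sr)) / (peak_of(sl) + peak_of(sr))
    } else if (pairing == "loom_vs_recede") {
      lo <- make_looming(10, 2 * span_um, v, dx = rf$dx, dt = rf$dt,
                         mode = "loom", center_um = c0)
      re <- make_looming(10, 2 * span_um, v, dx = rf$dx, dt = rf$dt,
                         mode = "recede", center_um = c0)
      (peak_of(lo) - peak_of(re)) / (peak_of(lo) + peak_of(re))
    } else {
      pitch <- bar_w_um
      dwell <- pitch / v
      ordd <- sequence_order(0:6, pitch_um = pitch, dwell_s = dwell)
      pm <- peak_of(make_apparent_sequence(ordd, bar_w_um = bar_w_um,
                                           dx = rf$dx, dt = rf$dt, origin_um = c0))
      pr <- mean(vapply(seq_len(n_random), function(i) {
        perm <- local_seed(seed + i, sample(0:6))
        peak_of(make_apparent_sequence(
          sequence_order(perm, pitch_um = pitch, dwell_s = dwell),
          bar_w_um = bar_w_um, dx = rf$dx, dt = rf$dt, origin_um = c0))
      }, numeric(1)))
      (pm - pr) / (pm + pr)
    }
  }, numeric(1))
  structure(data.frame(velocity_um_s = velocities, preference = pref,
                       pairing = pairing),
            class = c("velocity_tuning", "data.frame"))
}

# spatial centre/surround masks used by surround manipulations
rf_region_masks <- function(rf, boundary_um = NULL) {
  if (is.null(boundary_um)) {
    feats <- try(extract_features(rf), silent = TRUE)
    boundary_um <- if (inherits(feats, "try-error")) 2 * rf$dx else feats$fwhm_um
  }
  xs <- stim_space(rf)
  center <- abs(xs - rf$center_um) <= boundary_um
  list(center = center, surround = !center, boundary_um = boundary_um)
}

#' Scale the RF surround
#'
#' Multiplies the values of polarity opposite to the RF centre (negative for
#' On, positive for Off) in the surround region by `factor`; the centre
#' region is untouched. The default surround region is everything beyond one
#' centre FWHM from the RF centre.
#'
#' @param rf a [spacetime_rf].
#' @param factor scalar >= 0 (the paper's manipulations used 0.01, 0.5, 2, 3).
#' @param boundary_um centre/surround boundary distance (um); default the
#'   centre FWHM from [extract_features].
#' @return the modified [spacetime_rf].
#' @export
scale_surround <- function(rf, factor, boundary_um = NULL) {
  if (factor < 0) stop("factor must be >= 0", call. = FALSE)
  masks <- rf_region_masks(rf, boundary_um)
  pol <- if (rf$polarity == "On") 1 else -1
  opp <- (rf$weights * pol) < 0
  sel <- opp & matrix(masks$surround, nrow(rf$weights), ncol(rf$weights))
  rf$weights[sel] <- rf$weights[sel] * factor
  rf
}

#' Decompose a prediction into centre and surround contributions
#'
#' Runs [conv_predict] separately on the surround component (values of
#' polarity opposite to the centre, beyond the centre/surround boundary —
#' the same selection [scale_surround] manipulates) and on the remaining
#' centre component. The two masks partition the RF cells, so by linearity
#' the traces sum exactly to the full prediction, and a surround-free RF
#' has an identically zero surround trace.
#'
#' @param rf a [spacetime_rf].
#' @param stim a [spacetime_stim].
#' @param boundary_um centre/surround boundary (um); default the centre FWHM.
#' @return list with `center` and `surround` [predicted_response]s.
#' @export
decompose_center_surround <- function(rf, stim, boundary_um = NULL) {
  masks <- rf_region_masks(rf, boundary_um)
  if (any(masks$center & masks$surround))
    stop("centre and surround regions overlap", call. = FALSE)
  pol <- if (rf$polarity == "On") 1 else -1
  sur_cells <- ((rf$weights * pol) < 0) &
    matrix(masks$surround, nrow(rf$weights), ncol(rf$weights))
  rc <- rf; rc$weights[sur_cells] <- 0
  rs <- rf; rs$weights[!sur_cells] <- 0
  list(center = conv_predict(rc, stim), surround = conv_predict(rs, stim))
}

#' Pearson correlation between a prediction and an observed response
#'
#' Both series are aligned on the prediction's time grid (the observed
#' response is linearly resampled if its rate differs) and correlated over
#' the overlapping epoch.
#'
#' @param pred a [predicted_response].
#' @param observed a [smoothed_response] or [response_trace].
#' @return Pearson r.
#' @export
validate_prediction <- function(pred, observed) {
  obs_vals <- if (!is.null(observed$mean)) observed$mean else observed$values
  obs_rate <- if (!is.null(observed$rate_hz)) observed$rate_hz else 1 / observed$dt
  tp <- (seq_along(pred$values) - 0.5) * pred$dt
  to <- (seq_along(obs_vals) - 0.5) / obs_rate
  keep <- tp >= min(to) & tp <= max(to)
  if (sum(keep) < 3L) stop("no overlapping epoch to correlate", call. = FALSE)
  obs_on_pred <- stats::approx(to, obs_vals, xout = tp[keep])$y
  x <- pred$values[keep]
  if (stats::sd(x) == 0 || stats::sd(obs_on_pred) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  stats::cor(x, obs_on_pred)
}

#' Predicted peak amplitude vs. motion coherence of random sequences
#'
#' Draws `n` random orderings of `n_bars` bars, predicts the response of `rf`
#' to each (bars anchored at the RF centre, extending outward), and returns
#' the motion-coherence index and predicted peak per sequence.
#'
#' @param rf a [spacetime_rf].
#' @param n number of random sequences.
#' @param n_bars bars per sequence.
#' @param pitch_um bar pitch; `dwell_s` per-bar dwell.
#' @param dwell_s per-bar dwell time (s).
#' @param seed integer seed.
#' @return data.frame with `coherence` and `peak`.
#' @export
coherence_scan <- function(rf, n = 200, n_bars = 7, pitch_um = 20,
                           dwell_s = 1 / 30, seed = 1) {
  flip <- if (rf$polarity == "Off") -1 else 1
  res <- lapply(seq_len(n), function(i) {
    perm <- local_seed(seed * 1000 + i, sample(seq_len(n_bars) - 1L))
    ordr <- sequence_order(perm, pitch_um = pitch_um, dwell_s = dwell_s)
    stim <- make_apparent_sequence(ordr, n_bars = n_bars,
                                   bar_w_um = pitch_um, dx = rf$dx, dt = rf$dt,
                                   origin_um = rf$center_um)
    stim <- pad_stimulus(stim, after_s = rf$lag_span_s)
    data.frame(coherence = motion_coherence(ordr),
               peak = max(conv_predict(rf, stim)$values * flip))
  })
  do.call(rbind, res)
}
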