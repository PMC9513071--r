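#' Estimate a smooth space-time RF by penalised spline regression
#'
#' Regularised reverse-correlation: the response is modelled as the causal
#' convolution of the stimulus with an RF expanded on a tensor-product
#' B-spline basis over (space, lag), fitted by penalised least squares with
#' second-difference roughness penalties on the basis coefficients in both
#' dimensions. With a white-noise stimulus this is a smoothed
#' spike-triggered average. The penalty weight is chosen by generalised
#' cross-validation when `smoothness = NULL`.
#'
#' @param stim a [spacetime_stim]; must be mean-subtracted (background 0).
#' @param resp a [response_trace] aligned to the stimulus clock (resampled
#'   by linear interpolation if the rates differ).
#' @param smoothness penalty weight (>= 0) or `NULL` for GCV.
#' @param lag_span_s RF lag span (s).
#' @param basis_dim `c(space, lag)` B-spline basis sizes.
#' @param ipl_depth optional depth annotation carried onto the RF.
#' @return a [spacetime_rf] on the stimulus spatial grid with `dt = stim$dt`.
#' @export
estimate_rf <- function(stim, resp, smoothness = NULL, lag_span_s = 0.5,
                        basis_dim = c(space = 16, lag = 12),
                        ipl_depth = NA_real_) {
  stopifnot(inherits(stim, "spacetime_stim"), inherits(resp, "response_trace"))
  nl <- max(2L, round(lag_span_s / stim$dt))
  nt <- ncol(stim$values)
  y <- resp$values
  if (abs(resp$rate_hz - 1 / stim$dt) > 1e-9) {
    tr <- (seq_along(y) - 0.5) / resp$rate_hz
    ts <- (seq_len(nt) - 0.5) * stim$dt
    y <- stats::approx(tr, y, xout = ts, rule = 2)$y
  }
  if (length(y) < nt) stop("response shorter than the stimulus", call. = FALSE)
  y <- y[seq_len(nt)]
  if (nt <= nl) stop("insufficient data: response shorter than the lag span", call. = FALSE)
  nx <- nrow(stim$values)
  ks <- min(basis_dim[[1]], nx)
  kl <- min(basis_dim[[2]], nl)
  Bs <- bspline_basis(nx, ks)          # nx x ks
  Bl <- bspline_basis(nl, kl)          # nl x kl
  # features: F[t, (i-1)*kl + j] = sum_x sum_l Bs[x,i] Bl[l,j] S[x, t-l]
  Sb <- crossprod(stim$values, Bs)     # nt x ks : spatialy projected stimulus
  X <- matrix(0, nt, ks * kl)
  for (j in seq_len(kl)) {
    for (i in seq_len(ks)) {
      v <- numeric(nt)
      for (l in seq_len(nl)) if (l <= nt)
        v[l:nt] <- v[l:nt] + Bl[l, j] * Sb[1:(nt - l + 1L), i]
      X[, (i - 1L) * kl + j] <- v
    }
  }
  XtX <- crossprod(X); Xty <- crossprod(X, y)
  # roughness penalty plus a small ridge component so the fit shrinks to zero
  # (rather than to the bilinear nullspace) as smoothness grows
  P <- penalty_matrix(ks, kl) + 1e-3 * diag(ks * kl)
  fit_for <- function(lam) solve(XtX + lam * P + 1e-10 * diag(ks * kl), Xty)
  if (is.null(smoothness)) {
    lams <- 10^seq(-2, 6, length.out = 9) * mean(diag(XtX))
    gcv <- vapply(lams, function(lam) {
      A <- solve(XtX + lam * P + 1e-10 * diag(ks * kl), XtX)
      edf <- sum(diag(A))
      rss <- sum((y - X %*% fit_for(lam))^2)
      nt * rss / (nt - edf)^2
    }, numeric(1))
    smoothness <- lams[which.min(gcv)]
  }
  coefs <- matrix(fit_for(smoothness), nrow = kl)   # kl x ks (j fast)
  W <- Bs %*% t(Bl %*% coefs)                       # nx x nl
  polarity <- rf_polarity(W)
  Wp <- if (polarity == "On") W else -W
  pk <- which(Wp == max(Wp), arr.ind = TRUE)[1, ]
  spacetime_rf(W, dx = stim$dx, dt = stim$dt, origin_um = stim$origin_um,
               center_um = stim$origin_um + (pk[1] - 1) * stim$dx,
               polarity = polarity, ipl_depth = ipl_depth,
               label = sprintf("STA of '%s'", resp$condition_label))
}

# Polarity of an estimated RF: the centre leads the (opposite-polarity)
# surround in time, so the sign whose extremum occurs at the shorter lag
# wins; a clearly one-signed RF decides directly.
rf_polarity <- function(W) {
  mx <- max(W); mn <- min(W)
  if (mn >= 0) return("On")
  if (mx <= 0) return("Off")
  if (abs(mn) < 0.2 * mx) return("On")
  if (mx < 0.2 * abs(mn)) return("Off")
  t_pos <- which(W == mx, arr.ind = TRUE)[1, 2]
  t_neg <- which(W == mn, arr.ind = TRUE)[1, 2]
  if (t_pos <= t_neg) "On" else "Off"
}

# cubic B-spline design matrix over n evenly spaced points with k basis fns
bspline_basis <- function(n, k) {
  x <- seq_len(n)
  if (k >= n) return(diag(n))
  if (k <= 4L) {
    B <- stats::poly(x, degree = max(1L, k - 1L), raw = FALSE)
    return(cbind(1 / sqrt(n), B))
  }
  knots <- seq(1, n, length.out = k - 2L)
  splines::splineDesign(knots = c(rep(1, 3), knots, rep(n, 3)), x = x,
                        ord = 4L, outer.ok = TRUE)
}

# tensor roughness penalty: second differences along space and lag
penalty_matrix <- function(ks, kl) {
  D2 <- function(k) {
    if (k < 3L) return(diag(k) * 0)
    D <- diff(diag(k), differences = 2L)
    crossprod(D)
  }
  kronecker(D2(ks), diag(kl)) + kronecker(diag(ks), D2(kl))
}

#' RF feature set
#'
#' Container for the four RF features: centre-to-surround peak latency (s),
#' surround/centre strength ratio, biphasic index of the centre temporal
#' kernel, and centre FWHM (um) from a Gaussian fit of the spatial profile.
#'
#' @param latency_s,surround_strength,biphasic_index,fwhm_um the features.
#' @return An object of class `rf_features` (a one-row data.frame).
#' @export
rf_features <- function(latency_s, surround_strength, biphasic_index, fwhm_um) {
  if (!is.na(fwhm_um) && fwhm_um <= 0) stop("fwhm_um must be positive", call. = FALSE)
  if (!is.na(surround_strength) && surround_strength < 0)
    stop("surround_strength must be >= 0", call. = FALSE)
  structure(data.frame(latency_s = latency_s,
                       surround_strength = surround_strength,
                       biphasic_index = biphasic_index, fwhm_um = fwhm_um),
            class = c("rf_features", "data.frame"))
}

# parabolic interpolation of the extremum around index i of series y on grid g
parabolic_peak <- function(g, y, i) {
  if (i <= 1L || i >= length(y)) return(c(pos = g[i], val = y[i]))
  d <- (y[i - 1] - y[i + 1]) / (2 * (y[i - 1] - 2 * y[i] + y[i + 1]))
  if (!is.finite(d) || abs(d) > 1) d <- 0
  step <- g[2] - g[1]
  c(pos = g[i] + d * step,
    val = y[i] - 0.25 * (y[i - 1] - y[i + 1]) * d)
}

# log-quadratic Gaussian fit: returns c(mu, sigma, amp); exact for clean data
gaussian_fit <- function(x, y) {
  ymax <- max(y)
  sel <- y > 0.05 * ymax
  if (sum(sel) < 3L) return(c(mu = x[which.max(y)], sigma = NA_real_, amp = ymax))
  co <- stats::lm(log(y[sel]) ~ x[sel] + I(x[sel]^2))$coefficients
  if (!is.finite(co[3]) || co[3] >= 0)
    return(c(mu = x[which.max(y)], sigma = NA_real_, amp = ymax))
  sigma <- sqrt(-1 / (2 * co[3]))
  mu <- co[2] * sigma^2
  c(mu = unname(mu), sigma = unname(sigma), amp = exp(unname(co[1] + mu^2 / (2 * sigma^2))))
}

#' Extract RF features: latency, surround strength, biphasic index, FWHM
#'
#' Works on the polarity-corrected RF. The centre temporal kernel is the RF
#' at the spatial bin of maximal amplitude; the surround kernel is the RF at
#' the surround-region bin of maximal opposite-polarity amplitude. Latency
#' is the time between the two kernel peaks (parabolic sub-bin
#' interpolation); surround strength the ratio of surround and centre peak
#' amplitudes; biphasic index the |max / min| of the centre kernel, with the
#' minimum taken before the surround peak so the surround dip is not
#' mistaken for the centre rebound; FWHM comes from a Gaussian fit to the
#' spatial profile at the centre-peak time.
#'
#' @param rf a [spacetime_rf].
#' @param center_region,surround_region optional logical masks or `c(min,
#'   max)` um windows; defaults are centre within 1 FWHM of the centre, and
#'   flanks beyond 1.5 FWHM.
#' @return an [rf_features] row.
#' @export
extract_features <- function(rf, center_region = NULL, surround_region = NULL) {
  stopifnot(inherits(rf, "spacetime_rf"))
  pol <- if (rf$polarity == "On") 1 else -1
  W <- rf$weights * pol
  xs <- stim_space(rf)
  lags <- rf_lags(rf)
  # centre spatial bin and peak time
  pk <- which(W == max(W), arr.ind = TRUE)[1, ]
  if (max(W) <= 0) stop("degenerate RF: no centre peak", call. = FALSE)
  kc <- W[pk[1], ]
  cpk <- parabolic_peak(lags, kc, which.max(kc))
  # spatial profile at the centre-peak time -> FWHM
  prof <- W[, pk[2]]
  gf <- gaussian_fit(xs, pmax(prof, 0))
  fwhm <- if (is.na(gf["sigma"])) 2 * sqrt(2 * log(2)) * rf$dx
          else 2 * sqrt(2 * log(2)) * gf["sigma"]
  center_x <- gf[["mu"]]
  as_mask <- function(region, default) {
    if (is.null(region)) default
    else if (is.logical(region)) region
    else xs >= region[1] & xs <= region[2]
  }
  cmask <- as_mask(center_region, abs(xs - center_x) <= fwhm)
  smask <- as_mask(surround_region, abs(xs - center_x) >= 1.5 * fwhm)
  if (any(cmask & smask))
    stop("centre and surround regions must be disjoint", call. = FALSE)
  if (!any(smask)) {
    return(rf_features(NA_real_, 0, biphasic_from(kc), unname(fwhm)))
  }
  # surround kernel: surround-region bin with largest opposite-polarity dip
  sub <- W[smask, , drop = FALSE]
  sbin <- which.min(apply(sub, 1L, min))
  ksur <- -sub[sbin, ]
  if (max(ksur) <= 1e-12 * max(W)) {
    return(rf_features(NA_real_, 0, biphasic_from(kc), unname(fwhm)))
  }
  ipk <- which.max(ksur)
  cpk0 <- parabolic_peak(lags, kc, which.max(kc))
  if (max(ksur) < 0.02 * cpk0[["val"]]) {
    # flank dip is negligible (no genuine surround): report the tiny ratio
    # without attempting the surround-shape correction
    return(rf_features(NA_real_, unname(max(ksur) / cpk0[["val"]]),
                       biphasic_from(kc), unname(fwhm)))
  }
  spk <- parabolic_peak(lags, ksur, ipk)
  # The centre-bin trace carries the delayed surround dip (centre and
  # surround Gaussians overlap spatially). The flank kernel is an
  # uncontaminated copy of the surround time course, so subtract its shape
  # scaled to the centre-bin value at the surround peak, where the centre
  # kernel itself has decayed.
  kc_clean <- kc - (kc[ipk] / ksur[ipk]) * ksur * (kc[ipk] < 0)
  cpk <- parabolic_peak(lags, kc_clean, which.max(kc_clean))
  rf_features(latency_s = unname(spk["pos"] - cpk["pos"]),
              surround_strength = unname(spk["val"] / cpk["val"]),
              biphasic_index = biphasic_from(kc_clean),
              fwhm_um = unname(fwhm))
}

# |max/min| of the centre temporal kernel; Inf for a monophasic kernel
biphasic_from <- function(kc) {
  mn <- min(kc)
  if (mn >= 0) return(Inf)
  abs(max(kc) / mn)
}

#' RF trajectory: peak displacement and velocity between two lag windows
#'
#' Finds the (space, lag) peak of the polarity-corrected RF inside an early
#' and a late lag window and returns the spatial displacement
#' \eqn{x_2 - x_1} and the slope \eqn{(x_2 - x_1)/(t_2 - t_1)}. Peaks are
#' refined by parabolic interpolation in space. Lag runs into the past, so
#' the "early" window holds the older (larger-lag) part of the response;
#' velocities are reported in stimulus time (positive = peak moving toward
#' larger x as real time advances).
#'
#' @param rf a [spacetime_rf].
#' @param early_window,late_window `c(min, max)` lag windows (s), disjoint,
#'   `early_window` at larger lags.
#' @return list with `delta_distance_um` and `velocity_um_s`.
#' @export
rf_trajectory <- function(rf, early_window, late_window) {
  stopifnot(inherits(rf, "spacetime_rf"))
  if (max(late_window) > min(early_window))
    stop("windows must be disjoint with early_window at larger lags", call. = FALSE)
  pol <- if (rf$polarity == "On") 1 else -1
  W <- rf$weights * pol
  xs <- stim_space(rf)
  lags <- rf_lags(rf)
  peak_in <- function(win) {
    cols <- which(lags >= win[1] & lags <= win[2])
    if (length(cols) == 0L) stop("window outside the lag span", call. = FALSE)
    sub <- W[, cols, drop = FALSE]
    if (max(sub) - min(sub) < 1e-12)
      stop("undefined peak: RF flat inside the window", call. = FALSE)
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    px <- parabolic_peak(xs, sub[, ij[2]], ij[1])
    c(x = unname(px["pos"]), t = lags[cols[ij[2]]])
  }
  e <- peak_in(early_window)   # older part of the response
  l <- peak_in(late_window)    # most recent part
  dx <- l["x"] - e["x"]
  dt <- e["t"] - l["t"]        # elapsed stimulus time from early to late
  list(delta_distance_um = unname(dx), velocity_um_s = unname(dx / dt))
}
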