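# Independent oracles used across the suite. These deliberately re-derive
# quantities with naive, loop-based code so they share no path with the
# package implementation.

# frame-by-frame rasteriser for a moving bar: leading edge at
# start + dir * v * t, body extending width behind it; centre sampling
oracle_bar_frame <- function(xs, t, width, speed, direction, start) {
  lead <- start + direction * speed * t
  if (direction > 0) as.numeric(xs >= lead - width & xs < lead)
  else as.numeric(xs >= lead & xs < lead + width)
}

# dense triple-loop space-time convolution on aligned grids
oracle_conv <- function(rf, stim) {
  xs_rf <- rdsbc::stim_space(rf)
  out <- numeric(ncol(stim$values))
  for (t in seq_along(out)) {
    for (l in seq_len(ncol(rf$weights))) {
      ts <- t - l + 1L
      if (ts < 1L) next
      for (i in seq_len(nrow(rf$weights))) {
        j <- round((xs_rf[i] - stim$origin_um) / stim$dx) + 1L
        if (j >= 1L && j <= nrow(stim$values))
          out[t] <- out[t] + rf$weights[i, l] * stim$values[j, ts]
      }
    }
  }
  out
}

# exhaustive Eq-3 coherence: enumerate orderings recursively (independent of
# the package's permutation generator)
oracle_coherence <- function(positions_um) {
  sums <- c()
  rec <- function(prefix, rest) {
    if (length(rest) == 0L) {
      sums <<- c(sums, sum(abs(diff(prefix))))
      return(invisible())
    }
    for (i in seq_along(rest)) rec(c(prefix, rest[i]), rest[-i])
  }
  rec(numeric(0), positions_um)
  s <- sum(abs(diff(positions_um)))
  (s - max(sums)) / (min(sums) - max(sums))
}

# closed-form steady state of a finite passive cable, current I0 injected at
# the sealed far end (x measured from the soma end), sealed at both ends
oracle_cable_profile <- function(x_um, L_um, diam_um, R_m, R_i, I_nA) {
  a <- diam_um / 2 * 1e-4                      # cm
  lambda <- sqrt((R_m / R_i) * a / 2)          # cm
  r_a <- R_i / (pi * a^2)                      # Ohm / cm
  L <- L_um * 1e-4; x <- x_um * 1e-4
  # injection at x = L, no-flux at x = 0: V(x) = A cosh(x / lambda)
  A <- (I_nA * 1e-9) * r_a * lambda / sinh(L / lambda)
  A * cosh(x / lambda) * 1e3                   # mV
}

make_test_rf <- function(..., dx = 10, dt = 0.01, lag_span_s = 0.4,
                         extent_um = c(-200, 200)) {
  make_rf(syn_rf_params(...), dx = dx, dt = dt, lag_span_s = lag_span_s,
          extent_um = extent_um)
}
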