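#' Space-time stimulus container
#'
#' A 1-D contrast field over (space, time). Values are dimensionless contrast
#' in \[-1, 1\] with the mean-luminance background at 0 (50% contrast maps to
#' zero). Space bin `i` (1-based) has its centre at `origin_um + (i-1) * dx`;
#' time bin `k` covers the half-open interval `[(k-1) * dt, k * dt)` seconds
#' from stimulus onset and is sampled at its centre.
#'
#' @param values numeric matrix, rows = space bins, columns = time bins.
#' @param dx micrometres per space bin (> 0).
#' @param dt seconds per time bin (> 0).
#' @param origin_um physical coordinate (um) of the centre of space bin 1.
#' @param label free-text stimulus name.
#' @return An object of class `spacetime_stim`.
#' @export
spacetime_stim <- function(values, dx, dt, origin_um = 0, label = "") {
  values <- as.matrix(values)
  if (length(values) == 0L) stop("stimulus matrix must be non-empty", call. = FALSE)
  if (!is.numeric(dx) || length(dx) != 1L || !is.finite(dx) || dx <= 0)
    stop("dx must be a single positive number", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("stimulus values must be finite", call. = FALSE)
  if (any(values < -1 - 1e-12) || any(values > 1 + 1e-12))
    stop("stimulus contrast must lie in [-1, 1]", call. = FALSE)
  structure(
    list(values = values, dx = dx, dt = dt, origin_um = origin_um,
         label = as.character(label)),
    class = "spacetime_stim")
}

#' @export
print.spacetime_stim <- function(x, ...) {
  cat(sprintf("<spacetime_stim> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  %d space bins x %d time bins (dx = %g um, dt = %g s)\n",
              nrow(x$values), ncol(x$values), x$dx, x$dt))
  cat(sprintf("  extent: [%g, %g] um, duration %g s\n",
              x$origin_um, x$origin_um + (nrow(x$values) - 1) * x$dx,
              ncol(x$values) * x$dt))
  invisible(x)
}

#' @export
plot.spacetime_stim <- function(x, ...) {
  graphics::image(x = seq_len(ncol(x$values)) * x$dt,
                  y = stim_space(x),
                  z = t(x$values), xlab = "time (s)", ylab = "space (um)",
                  main = x$label, ...)
  invisible(x)
}

#' Spatial bin-centre coordinates of a stimulus or RF
#' @param x a `spacetime_stim` or `spacetime_rf`.
#' @return numeric vector of bin-centre positions in micrometres.
#' @export
stim_space <- function(x) x$origin_um + (seq_len(nrow(x$values %||% x$weights)) - 1) * x$dx

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bright moving-bar stimulus
#'
#' A positive-contrast bar of width `width_um` translating at constant speed.
#' The bar's leading edge (the edge facing the direction of motion) is at
#' `start_um + direction * speed_um_s * t`; the bar extends `width_um` behind
#' it. A space bin is lit when its centre lies under the bar (centre
#' sampling, no anti-aliasing); each time bin is sampled at its mid-time.
#'
#' @param width_um bar width (um), > 0.
#' @param speed_um_s bar speed (um/s), > 0.
#' @param distance_um distance travelled by the leading edge (um), > 0.
#' @param direction +1 (rightward) or -1 (leftward).
#' @param start_um leading-edge position at t = 0.
#' @param dx,dt grid resolution (um, s).
#' @param extent_um optional length-2 spatial extent `c(min, max)` of the
#'   grid; defaults to the region swept by the bar.
#' @return a [spacetime_stim].
#' @export
make_moving_bar <- function(width_um = 20, speed_um_s = 500, distance_um,
                            direction = +1, start_um = 0,
                            dx = 1, dt = 0.001, extent_um = NULL) {
  if (width_um <= 0 || speed_um_s <= 0 || distance_um <= 0)
    stop("bar geometry parameters must be positive", call. = FALSE)
  if (!direction %in% c(-1, 1)) stop("direction must be +1 or -1", call. = FALSE)
  duration <- distance_um / speed_um_s
  nt <- max(1L, ceiling(duration / dt - 1e-9))
  if (is.null(extent_um)) {
    swept <- range(c(start_um, start_um + direction * distance_um,
                     start_um - direction * width_um,
                     start_um + direction * distance_um - direction * width_um))
    extent_um <- swept
  }
  xs <- seq(floor(extent_um[1]), ceiling(extent_um[2]), by = dx)
  tt <- (seq_len(nt) - 0.5) * dt
  lead <- start_um + direction * speed_um_s * tt
  lo <- if (direction > 0) lead - width_um else lead
  hi <- if (direction > 0) lead else lead + width_um
  # outer comparison: lit if lo <= x < hi (trailing edge inclusive at lo)
  vals <- (outer(xs, lo, ">=") & outer(xs, hi, "<")) * 1
  spacetime_stim(vals, dx = dx, dt = dt, origin_um = xs[1],
                 label = sprintf("bar w=%g v=%g dir=%+d", width_um, speed_um_s, direction))
}

#' Binary 1-D noise stimulus
#'
#' `n_bars` adjacent bars, each independently flipping between -1 and +1
#' (100% contrast) at `rate_hz`. Frames of duration `1/rate_hz` are
#' subdivided into time bins of `dt`. One space bin per bar by default.
#'
#' @param n_bars number of bars.
#' @param bar_w_um bar width = spatial pitch (um).
#' @param rate_hz redraw rate (Hz).
#' @param duration_s total duration (s), > 0.
#' @param seed integer seed (required; the field is bit-reproducible).
#' @param dx spatial bin size; must divide `bar_w_um`. Default one bin/bar.
#' @param dt time bin size; default one bin per noise frame.
#' @param origin_um coordinate of the first bin centre.
#' @return a [spacetime_stim].
#' @export
make_1d_noise <- function(n_bars = 20, bar_w_um = 20, rate_hz = 20,
                          duration_s, seed, dx = bar_w_um, dt = 1 / rate_hz,
                          origin_um = 0) {
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  if (missing(seed)) stop("seed is required for make_1d_noise", call. = FALSE)
  if (bar_w_um %% dx > 1e-9 && abs(bar_w_um %% dx - dx) > 1e-9)
    stop("dx must divide bar_w_um", call. = FALSE)
  n_frames <- ceiling(duration_s * rate_hz - 1e-9)
  draw <- local_seed(seed, matrix(sample(c(-1, 1), n_bars * n_frames, replace = TRUE),
                                  nrow = n_bars))
  reps_t <- max(1L, round(1 / (rate_hz * dt)))
  reps_x <- max(1L, round(bar_w_um / dx))
  vals <- draw[rep(seq_len(n_bars), each = reps_x),
               rep(seq_len(n_frames), each = reps_t), drop = FALSE]
  nt <- min(ncol(vals), ceiling(duration_s / dt - 1e-9))
  spacetime_stim(vals[, seq_len(nt), drop = FALSE], dx = dx, dt = dt,
                 origin_um = origin_um,
                 label = sprintf("1d-noise %d bars @%g Hz", n_bars, rate_hz))
}

#' Looming / receding spot (1-D section)
#'
#' A bright spot centred at `center_um` whose diameter grows from
#' `start_diam_um` to `end_diam_um` at `expansion_um_s`. The rate applies to
#' the diameter (each edge moves at half the rate); set
#' `rate_on = "radius"` to apply it to each edge instead. `mode = "recede"`
#' is the exact time reverse of the loom.
#'
#' @param start_diam_um,end_diam_um initial/final spot diameter (um), end > start.
#' @param expansion_um_s expansion rate (um/s), > 0.
#' @param dx,dt grid resolution.
#' @param mode `"loom"` or `"recede"`.
#' @param center_um spot centre.
#' @param rate_on `"diameter"` (default) or `"radius"`.
#' @return a [spacetime_stim].
#' @export
make_looming <- function(start_diam_um = 10, end_diam_um = 600,
                         expansion_um_s = 800, dx = 1, dt = 0.001,
                         mode = c("loom", "recede"), center_um = 0,
                         rate_on = c("diameter", "radius")) {
  mode <- match.arg(mode)
  rate_on <- match.arg(rate_on)
  if (end_diam_um <= start_diam_um)
    stop("end_diam_um must exceed start_diam_um", call. = FALSE)
  if (expansion_um_s <= 0) stop("expansion_um_s must be positive", call. = FALSE)
  drate <- if (rate_on == "diameter") expansion_um_s else 2 * expansion_um_s
  duration <- (end_diam_um - start_diam_um) / drate
  nt <- max(1L, ceiling(duration / dt - 1e-9))
  half <- end_diam_um / 2
  xs <- seq(floor(center_um - half), ceiling(center_um + half), by = dx)
  tt <- (seq_len(nt) - 0.5) * dt
  diam <- start_diam_um + drate * tt
  vals <- outer(abs(xs - center_um), diam / 2, "<=") * 1
  if (mode == "recede") vals <- vals[, rev(seq_len(ncol(vals))), drop = FALSE]
  spacetime_stim(vals, dx = dx, dt = dt, origin_um = xs[1],
                 label = sprintf("%s %g->%g um", mode, start_diam_um, end_diam_um))
}

#' Bar-sequence presentation order
#'
#' The ordered list of bar indices shown one at a time in an apparent-motion
#' or random-sequence stimulus, together with the bar pitch and per-bar dwell
#' time. Indices are 0-based positions in the bar array and must be distinct.
#'
#' @param positions integer vector of distinct 0-based bar indices.
#' @param pitch_um centre-to-centre bar spacing (um).
#' @param dwell_s per-bar presentation time (s).
#' @return An object of class `sequence_order`.
#' @export
sequence_order <- function(positions, pitch_um = 20, dwell_s = 1 / 30) {
  positions <- as.integer(positions)
  if (length(positions) == 0L) stop("positions must be non-empty", call. = FALSE)
  if (anyDuplicated(positions)) stop("positions must be distinct", call. = FALSE)
  if (any(positions < 0L)) stop("positions are 0-based bar indices", call. = FALSE)
  if (pitch_um <= 0 || dwell_s <= 0) stop("pitch_um and dwell_s must be positive", call. = FALSE)
  structure(list(positions = positions, pitch_um = pitch_um, dwell_s = dwell_s),
            class = "sequence_order")
}

#' @export
print.sequence_order <- function(x, ...) {
  cat(sprintf("<sequence_order> %s (pitch %g um, dwell %g s)\n",
              paste(x$positions, collapse = " "), x$pitch_um, x$dwell_s))
  invisible(x)
}

#' Apparent-motion / random bar-sequence stimulus
#'
#' Presents one bar at a time: the bar at index `order$positions[i]` is lit
#' (+1) during `[(i-1) * dwell, i * dwell)`. Bar `j` occupies
#' `[origin + j * pitch - bar_w/2, origin + j * pitch + bar_w/2)`.
#'
#' @param order a [sequence_order].
#' @param n_bars size of the bar array (indices must fit).
#' @param bar_w_um bar width (um).
#' @param dx spatial bin (um); default one bin per bar pitch.
#' @param dt time bin (s).
#' @param origin_um centre of bar 0.
#' @return a [spacetime_stim].
#' @export
make_apparent_sequence <- function(order, n_bars = 7, bar_w_um = 20,
                                   dx = NULL, dt = 0.001, origin_um = 0) {
  stopifnot(inherits(order, "sequence_order"))
  if (any(order$positions >= n_bars))
    stop("sequence positions exceed the bar array", call. = FALSE)
  if (is.null(dx)) dx <- order$pitch_um
  span <- (n_bars - 1) * order$pitch_um
  xs <- seq(origin_um - bar_w_um / 2, origin_um + span + bar_w_um / 2, by = dx)
  nt_bar <- max(1L, round(order$dwell_s / dt))
  nt <- nt_bar * length(order$positions)
  vals <- matrix(0, nrow = length(xs), ncol = nt)
  centres <- origin_um + order$positions * order$pitch_um
  for (i in seq_along(order$positions)) {
    lit <- xs >= centres[i] - bar_w_um / 2 & xs < centres[i] + bar_w_um / 2
    vals[lit, ((i - 1) * nt_bar + 1):(i * nt_bar)] <- 1
  }
  spacetime_stim(vals, dx = dx, dt = dt, origin_um = xs[1],
                 label = sprintf("sequence %s", paste(order$positions, collapse = "")))
}

#' Motion-coherence index of a bar sequence
#'
#' For a sequence with spatial positions \eqn{x_1 \dots x_n} presented in
#' temporal order, with \eqn{S = \sum |x_{j} - x_{i}|} the sum of spatial
#' distances between temporally adjacent bars,
#' \deqn{k = (S - s_{max}) / (s_{min} - s_{max})}
#' where \eqn{s_{min}} and \eqn{s_{max}} are the minimum and maximum possible
#' adjacent-distance sums over all orderings of the same positions. A perfect
#' apparent-motion sequence has k = 1; the least coherent possible ordering
#' has k = 0. `s_min`/`s_max` are found by exhaustive enumeration, supported
#' for up to 8 bars (5040 orderings at n = 7).
#'
#' @param order a [sequence_order] with at least 2 positions.
#' @return coherence index in \[0, 1\].
#' @export
motion_coherence <- function(order) {
  stopifnot(inherits(order, "sequence_order"))
  x <- order$positions * order$pitch_um
  n <- length(x)
  if (n < 2L) stop("motion coherence is undefined for fewer than 2 positions", call. = FALSE)
  if (n > 8L) stop("exhaustive s_min/s_max search supported for up to 8 positions", call. = FALSE)
  s <- sum(abs(diff(x)))
  sums <- adjacent_sums_all(sort(x))
  s_min <- min(sums); s_max <- max(sums)
  if (s_max == s_min) return(1)  # n = 2 or coincident spacing: maximally coherent
  (s - s_max) / (s_min - s_max) + 0  # + 0 normalises IEEE negative zero
}

# adjacent-distance sums over all orderings of positions x (exhaustive)
adjacent_sums_all <- function(x) {
  perms <- permutations_all(length(x))
  apply(perms, 1L, function(p) sum(abs(diff(x[p]))))
}

# all permutations of 1..n as a matrix (n! rows); n <= 8
permutations_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (i in seq_len(n)) {
    rows <- (r + 1L):(r + nrow(sub))
    out[rows, 1L] <- i
    out[rows, -1L] <- matrix(c(seq_len(n)[-i])[sub], nrow(sub))
    r <- r + nrow(sub)
  }
  out
}

#' Pad a stimulus with blank frames
#'
#' Appends (and optionally prepends) zero-contrast frames. Trailing padding
#' lets delayed RF responses to the final stimulus frames play out in
#' convolution predictions; leading padding gives simulations a blank
#' lead-in.
#'
#' @param stim a [spacetime_stim].
#' @param before_s,after_s blank time (s) added before/after.
#' @return the padded [spacetime_stim].
#' @export
pad_stimulus <- function(stim, before_s = 0, after_s = 0) {
  nb <- round(before_s / stim$dt); na_ <- round(after_s / stim$dt)
  v <- cbind(matrix(0, nrow(stim$values), nb), stim$values,
             matrix(0, nrow(stim$values), na_))
  spacetime_stim(v, dx = stim$dx, dt = stim$dt, origin_um = stim$origin_um,
                 label = stim$label)
}

#' Apparent velocity of a bar sequence
#'
#' @param pitch_um centre-to-centre bar spacing (um).
#' @param dwell_s per-bar dwell time (s), > 0.
#' @return velocity in um/s (`pitch_um / dwell_s`).
#' @export
apparent_velocity <- function(pitch_um, dwell_s) {
  if (dwell_s <= 0) stop("dwell_s must be positive", call. = FALSE)
  pitch_um / dwell_s
}

# Run expr with a local RNG seed, restoring global state afterwards.
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}
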