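#' IPSP extraction by paired subtraction
#'
#' The IPSP of a recorded cell is the difference between its somatic trace
#' with the studied inhibition active and the trace from the identical
#' simulation with that inhibition inactive, restricted to a window after
#' the presynaptic cell's first spike (only the first spike is used). The
#' signed amplitude is the extremum of the difference trace: both the
#' maximum and the minimum are found and whichever has the greater absolute
#' value is taken, so depolarizing responses (baseline below the GABA-A
#' reversal) and hyperpolarizing responses keep their sign. Identically
#' zero difference traces are flagged excluded (cells untouched by the
#' toggled projection produce no IPSP, not a zero-amplitude one).
#'
#' @param trace_on,trace_off aligned numeric vectors sampled at `dt_ms`
#'   (one cell's somatic voltage from the paired runs).
#' @param presyn_spike_time first presynaptic spike time, ms.
#' @param window_ms length of the post-spike analysis window.
#' @param dt_ms sampling step.
#' @param cell optional cell id carried through.
#' @return an `ipsp_record`: `cell`, `baseline_mv` (OFF-trace voltage at
#'   the presynaptic spike), `t_ms` (time since spike), `diff_mv`,
#'   `amplitude_mv` (signed), `excluded` (flag).
#' @export
extract_ipsp <- function(trace_on, trace_off, presyn_spike_time,
                         window_ms = 100, dt_ms, cell = NA_integer_) {
  if (length(trace_on) != length(trace_off)) {
    stop("trace_on and trace_off are misaligned (different lengths)")
  }
  i0 <- as.integer(round(presyn_spike_time / dt_ms)) + 1L
  i1 <- min(length(trace_on),
            i0 + as.integer(round(window_ms / dt_ms)))
  if (i0 < 1 || i0 > length(trace_on)) {
    stop("presynaptic spike time outside the recorded traces")
  }
  d <- trace_on[i0:i1] - trace_off[i0:i1]
  mx <- max(d); mn <- min(d)
  amp <- if (abs(mx) >= abs(mn)) mx else mn
  excluded <- all(d == 0)
  structure(list(cell = cell,
                 baseline_mv = trace_off[i0],
                 t_ms = (seq_along(d) - 1) * dt_ms,
                 diff_mv = d,
                 amplitude_mv = if (excluded) NA_real_ else amp,
                 excluded = excluded),
            class = "ipsp_record")
}

#' Extract IPSPs for every recorded cell of a paired run
#'
#' @param pair result of [paired_ipsp_run()].
#' @param window_ms post-spike window.
#' @return data.frame: `cell`, `baseline_mv`, `amplitude_mv`, `excluded`.
#' @export
extract_ipsp_set <- function(pair, window_ms = 100) {
  n <- nrow(pair$trace_on)
  out <- lapply(seq_len(n), function(r) {
    rec <- extract_ipsp(pair$trace_on[r, ], pair$trace_off[r, ],
                        pair$presyn_spike, window_ms, pair$dt_ms,
                        cell = pair$recorded[r])
    data.frame(cell = rec$cell, baseline_mv = rec$baseline_mv,
               amplitude_mv = ifelse(rec$excluded, NA_real_,
                                     rec$amplitude_mv),
               excluded = rec$excluded)
  })
  do.call(rbind, out)
}

#' Double-exponential IPSP fit
#'
#' Least-squares fit of `V(t) = scale * (exp(-t/T1) - exp(-t/T2))` to a
#' difference trace whose onset is aligned to `t = 0`. The functional form
#' is symmetric under swapping T1 and T2 with a sign flip of `scale`; the
#' fit is reported with `T1 >= T2` (T1 the decay constant, T2 the rise).
#' Goodness of fit is `R^2 = 1 - SS_res / SS_tot`; fits with `R^2 < 0.80`
#' are rejected, as are optimizer failures.
#'
#' Initialisation: T2 from the empirical peak location (peak time of the
#' two-exponential waveform), T1 from the late-decay log-slope.
#'
#' @param t_ms time since onset, ms.
#' @param v voltage (or difference) samples; at least 10.
#' @return a `fit_result`: `T1`, `T2`, `scale`, `r_squared`, `accepted`,
#'   `message`.
#' @export
#' @examples
#' t <- seq(0, 80, by = 0.5)
#' v <- 0.1 * (exp(-t / 10.5) - exp(-t / 6.3))
#' f <- fit_double_exponential(t, v)
#' c(f$T1, f$T2) # close to 10.5, 6.3
fit_double_exponential <- function(t_ms, v) {
  if (length(t_ms) < 10) stop("need at least 10 samples to fit")
  if (length(t_ms) != length(v)) stop("t_ms and v lengths differ")
  s <- if (abs(max(v)) >= abs(min(v))) 1 else -1
  y <- s * v
  ipk <- which.max(y)
  tpk <- max(t_ms[ipk], t_ms[2])
  # late decay log-slope for the slow constant
  late <- t_ms > tpk & y > 0.05 * y[ipk]
  T1_0 <- if (sum(late) >= 3) {
    sl <- stats::coef(stats::lm(log(y[late]) ~ t_ms[late]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl else 2 * tpk
  } else 2 * tpk
  T2_0 <- max(tpk / 3, 0.5)
  T1_0 <- max(T1_0, T2_0 * 1.5)
  A_0 <- y[ipk] / max(exp(-tpk / T1_0) - exp(-tpk / T2_0), 1e-6)
  df <- data.frame(t = t_ms, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * (exp(-t / T1) - exp(-t / T2)), data = df,
                      start = list(A = A_0, T1 = T1_0, T2 = T2_0),
                      lower = c(-Inf, 1e-3, 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(T1 = NA_real_, T2 = NA_real_, scale = NA_real_,
                          r_squared = NA_real_, accepted = FALSE,
                          message = conditionMessage(fit)),
                     class = "fit_result"))
  }
  cf <- stats::coef(fit)
  T1 <- unname(cf["T1"]); T2 <- unname(cf["T2"]); A <- unname(cf["A"])
  # canonical order T1 >= T2 (swap flips the sign of the scale)
  if (T1 < T2) { tmp <- T1; T1 <- T2; T2 <- tmp; A <- -A }
  resid <- y - stats::predict(fit)
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(T1 = T1, T2 = T2, scale = s * A,
                 r_squared = r2,
                 accepted = isTRUE(r2 >= 0.80), message = "converged"),
            class = "fit_result")
}

#' One-sample z-test for equivalence with a reference value
#'
#' `z = (mean(x) - mu0) / (sd(x) / sqrt(n))`; a z-value inside the open
#' interval (-1.96, 1.96) indicates 95% confidence in equivalence of the
#' sample with the reference value.
#'
#' @param sample_values numeric sample (n >= 2, nonzero variance).
#' @param mu0 reference value.
#' @return a `ztest_result`: `z`, `equivalent`, `n`, `mean`, `sd`.
#' @export
#' @examples
#' one_sample_ztest(c(9, 10, 11), 10)$z # 0
one_sample_ztest <- function(sample_values, mu0) {
  n <- length(sample_values)
  if (n < 2) stop("need at least 2 sample values")
  s <- stats::sd(sample_values)
  if (s == 0) stop("zero sample variance")
  z <- (mean(sample_values) - mu0) / (s / sqrt(n))
  structure(list(z = z, equivalent = (z > -1.96 && z < 1.96),
                 n = n, mean = mean(sample_values), sd = s),
            class = "ztest_result")
}

#' Peri-event spike histogram
#'
#' Counts spikes of the selected cells in time bins relative to every
#' event. Bins are left-closed, right-open (`[a, b)`), so an offset equal
#' to a bin edge counts in the upper bin. Events whose window extends past
#' the recording edge are included with truncated windows (their
#' out-of-range bins simply collect nothing).
#'
#' @param raster list of per-cell spike-time vectors.
#' @param event_times reference events, ms (non-empty).
#' @param window length-2 window around each event, ms (e.g. `c(-50, 50)`).
#' @param binsize_ms bin width.
#' @param cells cell ids included (default all).
#' @return a `perievent_histogram`: `breaks` (bin edges, ms relative to
#'   the event), `counts`, `n_events`, `mids`.
#' @export
#' @examples
#' h <- perievent_histogram(list(c(110)), 100, c(-50, 50), 10)
#' h$counts[h$mids == 15] # 1
perievent_histogram <- function(raster, event_times, window = c(-50, 50),
                                binsize_ms = 5, cells = seq_along(raster)) {
  if (length(event_times) == 0) stop("empty event list")
  stopifnot(binsize_ms > 0, window[1] < window[2])
  breaks <- seq(window[1], window[2], by = binsize_ms)
  if (breaks[length(breaks)] < window[2]) {
    breaks <- c(breaks, breaks[length(breaks)] + binsize_ms)
  }
  spikes <- unlist(raster[cells], use.names = FALSE)
  counts <- integer(length(breaks) - 1)
  if (length(spikes) > 0) {
    for (ev in event_times) {
      off <- spikes - ev
      off <- off[off >= breaks[1] & off < breaks[length(breaks)]]
      if (length(off) > 0) {
        counts <- counts + as.integer(
          table(cut(off, breaks = breaks, right = FALSE)))
      }
    }
  }
  structure(list(breaks = breaks, counts = counts,
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 n_events = length(event_times)),
            class = "perievent_histogram")
}

#' Post-event suppression fraction from paired runs
#'
#' Counts the selected cells' spikes inside the window after each event in
#' the inhibition-ON and inhibition-OFF rasters of a paired run, and
#' reports the fraction of spikes remaining with inhibition active
#' (`spikes_on / spikes_off`). The default window (5, 30) ms after the
#' event is where the ensemble-spike suppression of non-ensemble cells
#' concentrates.
#'
#' @param raster_on,raster_off per-cell spike lists from paired runs on
#'   identical inputs.
#' @param event_times reference events, ms.
#' @param window length-2 post-event window, ms; default `c(5, 30)`.
#' @param cells cells included.
#' @return a `suppression_summary`: `window`, `spikes_on`, `spikes_off`,
#'   `fraction_remaining`.
#' @export
suppression_fraction <- function(raster_on, raster_off, event_times,
                                 window = c(5, 30),
                                 cells = seq_along(raster_on)) {
  count_in <- function(raster) {
    spikes <- unlist(raster[cells], use.names = FALSE)
    if (length(spikes) == 0) return(0L)
    total <- 0L
    for (ev in event_times) {
      total <- total + sum(spikes - ev >= window[1] &
                             spikes - ev <= window[2])
    }
    total
  }
  s_on <- count_in(raster_on)
  s_off <- count_in(raster_off)
  if (s_off == 0) stop("no spikes in the OFF-run windows; fraction undefined")
  structure(list(window = window, spikes_on = s_on, spikes_off = s_off,
                 fraction_remaining = s_on / s_off),
            class = "suppression_summary")
}

#' Standard deviation of ensemble spike timing
#'
#' Pools, over all rhythm events, the offsets of the selected cells'
#' spikes relative to their nearest preceding event (within `window` ms
#' after the event) and returns the population standard deviation
#' (n denominator) of the pooled offsets.
#'
#' @param raster per-cell spike lists.
#' @param rhythm_event_times shared rhythm event times, ms.
#' @param window post-event window collecting each event's response, ms
#'   (default covers one ensemble response, well inside the rhythm period).
#' @param cells ensemble cell ids.
#' @return offset standard deviation, ms.
#' @export
#' @examples
#' ensemble_spike_sd(list(c(99, 100, 101)), 100, window = c(-5, 5)) # 0.816
ensemble_spike_sd <- function(raster, rhythm_event_times, window = c(0, 30),
                              cells = seq_along(raster)) {
  spikes <- unlist(raster[cells], use.names = FALSE)
  offs <- numeric(0)
  for (ev in rhythm_event_times) {
    d <- spikes - ev
    offs <- c(offs, d[d >= window[1] & d <= window[2]])
  }
  if (length(offs) < 2) stop("fewer than 2 spikes in all event windows")
  sqrt(mean((offs - mean(offs))^2))
}

#' Per-cell firing-rate statistics
#'
#' @param raster per-cell spike lists.
#' @param duration_ms recording length.
#' @param cells cells included.
#' @param breaks histogram breaks (Hz) or a number of bins.
#' @return list: `rates_hz` (per cell), `mean_hz`, `sd_hz` (sample sd
#'   across cells), `hist` (counts per bin), `breaks`.
#' @export
rate_stats <- function(raster, duration_ms, cells = seq_along(raster),
                       breaks = 20) {
  stopifnot(duration_ms > 0)
  rates <- lengths(raster[cells]) / (duration_ms / 1000)
  h <- graphics::hist(rates, breaks = breaks, plot = FALSE)
  list(rates_hz = rates, mean_hz = mean(rates),
       sd_hz = if (length(rates) > 1) stats::sd(rates) else 0,
       hist = h$counts, breaks = h$breaks)
}
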