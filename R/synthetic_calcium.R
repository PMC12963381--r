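#' Simulate fluorescence calcium traces with planted transients
#'
#' Each trace is a slowly varying baseline times (1 + sum of instantaneous-
#' rise, exponential-decay transients) plus Gaussian noise. Transient
#' amplitudes are expressed in dF/F0 units so a noiseless event of amplitude
#' `a` peaks at dF/F0 = a.
#'
#' @param duration_s recording length in seconds.
#' @param rate_hz sampling rate in Hz.
#' @param event_times_s list (one numeric vector of onset seconds per trace)
#'   or a single numeric vector for one trace.
#' @param event_amp transient amplitude in dF/F0 units.
#' @param decay_s exponential decay time constant (seconds), must be > 0.
#' @param drift relative amplitude of a slow sinusoidal baseline drift.
#' @param noise_sd Gaussian noise SD relative to the baseline level.
#' @param baseline_level raw fluorescence baseline (arbitrary units).
#' @param well_id,condition per-trace metadata (recycled).
#' @param seed integer seed.
#' @return a `calcium_trace_set`: list with `traces` (list of numeric
#'   vectors), `rate_hz`, `meta` (trace_id, well_id, condition) and `truth`
#'   (ground-truth event onset times per trace, seconds).
#' @export
simulate_calcium <- function(duration_s = 100, rate_hz = 5,
                             event_times_s = list(numeric(0)),
                             event_amp = 0.5, decay_s = 1,
                             drift = 0, noise_sd = 0,
                             baseline_level = 100,
                             well_id = "W1", condition = "ctrl",
                             seed = 1L) {
  stop_if_not(decay_s > 0, "decay_s must be > 0")
  stop_if_not(rate_hz > 0, "rate_hz must be > 0")
  if (!is.list(event_times_s)) event_times_s <- list(event_times_s)
  lapply(event_times_s, function(ev) {
    stop_if_not(all(ev >= 0 & ev <= duration_s),
                "event times must lie within [0, duration_s]")
  })
  n_tr <- length(event_times_s)
  tt <- seq(0, duration_s - 1 / rate_hz, by = 1 / rate_hz)
  with_seed(seed, {
    traces <- vector("list", n_tr)
    for (i in seq_len(n_tr)) {
      base <- baseline_level * (1 + drift * sin(2 * pi * tt / duration_s))
      sig <- rep(0, length(tt))
      for (ev in event_times_s[[i]]) {
        on <- tt >= ev
        sig[on] <- sig[on] + event_amp * exp(-(tt[on] - ev) / decay_s)
      }
      traces[[i]] <- base * (1 + sig) +
        rnorm(length(tt), 0, noise_sd * baseline_level)
    }
    meta <- data.frame(
      trace_id = sprintf("T%03d", seq_len(n_tr)),
      well_id = rep_len(well_id, n_tr),
      condition = rep_len(condition, n_tr),
      stringsAsFactors = FALSE
    )
    names(traces) <- meta$trace_id
    structure(list(traces = traces, rate_hz = rate_hz, meta = meta,
                   truth = setNames(event_times_s, meta$trace_id)),
              class = "calcium_trace_set")
  })
}

#' @export
print.calcium_trace_set <- function(x, ...) {
  cat(sprintf("calcium_trace_set: %d traces at %g Hz, %d samples each\n",
              length(x$traces), x$rate_hz,
              if (length(x$traces)) length(x$traces[[1]]) else 0))
  invisible(x)
}
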