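#' Baseline-normalized fluorescence (dF/F0) with a rolling-percentile
#' baseline
#'
#' The baseline `F0(t)` is the 10th percentile (linear interpolation
#' between order statistics) of the raw trace over a centered window of
#' `window_s` seconds, truncated at the trace edges;
#' `dF/F0 = (F - F0) / F0`. A non-positive baseline anywhere rejects the
#' trace.
#'
#' @param trace numeric fluorescence vector.
#' @param rate_hz sampling rate in Hz.
#' @param window_s rolling window length in seconds (default 10).
#' @param percentile baseline percentile (default 10).
#' @return numeric dF/F0 series of the same length.
#' @export
compute_dff <- function(trace, rate_hz, window_s = 10, percentile = 10) {
  w <- round(window_s * rate_hz)
  stop_if_not(w >= 2, "window must span at least 2 samples")
  n <- length(trace)
  stop_if_not(n >= w, "window longer than trace")
  half <- w / 2
  f0 <- vapply(seq_len(n), function(i) {
    lo <- max(1, ceiling(i - half))
    hi <- min(n, floor(i + half))
    quantile(trace[lo:hi], probs = percentile / 100, names = FALSE,
             type = 7)
  }, numeric(1))
  if (any(f0 <= 0)) {
    stop("non-positive baseline; trace rejected", call. = FALSE)
  }
  (trace - f0) / f0
}

#' Detect calcium transient onsets by threshold crossing
#'
#' An event is an upward crossing where the dF/F0 series moves from at or
#' below `threshold` to strictly above it ("exceeding" is strict).
#' Crossings within `min_separation_s` of the previous onset are merged
#' into one event (debounce). A series starting above threshold counts as
#' an event at its first sample.
#'
#' @param dff dF/F0 series.
#' @param rate_hz sampling rate in Hz.
#' @param threshold event threshold in dF/F0 units (default 0.2).
#' @param min_separation_s refractory separation in seconds (default 0.4).
#' @return numeric vector of onset times in seconds (strictly increasing).
#' @export
detect_events <- function(dff, rate_hz, threshold = 0.2,
                          min_separation_s = 0.4) {
  stop_if_not(threshold > 0, "threshold must be > 0")
  above <- dff > threshold
  if (!any(above)) return(numeric(0))
  cross <- which(above & !c(FALSE, above[-length(above)]))
  times <- (cross - 1) / rate_hz
  onsets <- times[1]
  for (t in times[-1]) {
    if (t - onsets[length(onsets)] >= min_separation_s) {
      onsets <- c(onsets, t)
    }
  }
  onsets
}

#' Summarize event rates per trace, well and condition
#'
#' Computes per-trace event rates (events per minute), averages them per
#' well, and summarizes conditions over well means (each well is one
#' biological replicate; traces are never pooled across wells).
#'
#' @param cts a `calcium_trace_set`.
#' @param threshold,window_s,percentile,min_separation_s detection
#'   parameters passed to [compute_dff()] and [detect_events()].
#' @return list with `events` (per trace: trace_id, well_id, condition,
#'   n_events, duration_s, events_per_min, onsets), `wells` (well_id,
#'   condition, events_per_min), `conditions` (condition, mean and SD over
#'   well means, n_wells).
#' @export
summarize_rates <- function(cts, threshold = 0.2, window_s = 10,
                            percentile = 10, min_separation_s = 0.4) {
  stopifnot(inherits(cts, "calcium_trace_set"))
  stop_if_not(all(cts$meta$trace_id %in% names(cts$traces)),
              "every trace needs metadata")
  ev <- lapply(cts$meta$trace_id, function(id) {
    f <- cts$traces[[id]]
    dff <- compute_dff(f, cts$rate_hz, window_s, percentile)
    onsets <- detect_events(dff, cts$rate_hz, threshold, min_separation_s)
    dur <- length(f) / cts$rate_hz
    data.frame(trace_id = id,
               well_id = cts$meta$well_id[cts$meta$trace_id == id],
               condition = cts$meta$condition[cts$meta$trace_id == id],
               n_events = length(onsets), duration_s = dur,
               events_per_min = length(onsets) / (dur / 60),
               stringsAsFactors = FALSE)
  })
  events <- do.call(rbind, ev)
  onsets <- lapply(cts$meta$trace_id, function(id) {
    detect_events(compute_dff(cts$traces[[id]], cts$rate_hz, window_s,
                              percentile),
                  cts$rate_hz, threshold, min_separation_s)
  })
  names(onsets) <- cts$meta$trace_id
  wells <- aggregate(events_per_min ~ well_id + condition, data = events,
                     FUN = mean)
  conditions <- do.call(rbind, lapply(split(wells, wells$condition),
    function(d) data.frame(condition = d$condition[1],
                           mean_events_per_min = mean(d$events_per_min),
                           sd_events_per_min = sd(d$events_per_min),
                           n_wells = nrow(d),
                           stringsAsFactors = FALSE)))
  rownames(conditions) <- NULL
  list(events = events, onsets = onsets, wells = wells,
       conditions = conditions)
}
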