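#' Sensor correlation check (SCC)
#'
#' A candidate sensor joins the target's window only if its correlation with
#' the target sensor reaches the target's threshold. The target sensor always
#' passes against itself.
#'
#' @param model a `correlation_model`.
#' @param s_cand candidate sensor index.
#' @param s_target target sensor index (last event of the window).
#' @return logical.
#' @export
scc <- function(model, s_cand, s_target) {
  S <- model$n_sensors
  if (s_cand < 1 || s_cand > S || s_target < 1 || s_target > S)
    stopf("scc: sensor index out of range 1..%d", S)
  s_cand == s_target || model$scm[s_cand, s_target] >= model$sct[s_target]
}

#' Time correlation check (TCC)
#'
#' A candidate event at time `t_cand` (sensor `s_cand`) may precede the
#' current window head (time `t_first`, sensor `s_first`) of a window whose
#' target event is at `t_target` (sensor `s_target`) only if (a) the gap to
#' the head does not exceed the maximum time interval of the ordered sensor
#' pair (candidate, head), and (b) the resulting window span does not exceed
#' the maximum time span of the target sensor's functional area. Equality
#' passes both gates. Unobserved sensor pairs use the model's global MTI
#' fallback.
#'
#' @param model a `correlation_model`.
#' @param t_cand,s_cand candidate event time (s) and sensor.
#' @param t_first,s_first current window head time and sensor.
#' @param t_target,s_target target event time and sensor.
#' @return logical.
#' @export
tcc <- function(model, t_cand, s_cand, t_first, s_first, t_target, s_target) {
  m <- model$mti[s_cand, s_first]
  if (is.na(m)) m <- model$mti_fallback
  (t_first - t_cand) <= m &&
    (t_target - t_cand) <= model$mts[model$area_map[s_target]]
}

new_window <- function(stream, first, target) {
  structure(list(first = as.integer(first), target = as.integer(target),
                 end_time = stream$time_abs[target]),
            class = "ar_window")
}

#' @export
print.ar_window <- function(x, ...) {
  cat(sprintf("<ar_window> events %d..%d (size %d), end time %.3f s\n",
              x$first, x$target, x$target - x$first + 1L, x$end_time))
  invisible(x)
}

# core scan shared by dynamic_segment and segment_stream: returns the first
# index of the window for target i
ds_first <- function(sv, tv, i, model, max_lookback) {
  if (i == 1L) return(1L)
  first <- i - 1L # E_{i-1} admitted unconditionally per the initialization
  s_i <- sv[i]; t_i <- tv[i]
  mts_i <- model$mts[model$area_map[s_i]]
  sct_i <- model$sct[s_i]
  scm <- model$scm; mti <- model$mti; fb <- model$mti_fallback
  j <- i - 2L
  while (j >= 1L && (i - j) <= max_lookback) {
    s_j <- sv[j]
    if (!(s_j == s_i || scm[s_j, s_i] >= sct_i)) break
    m <- mti[s_j, sv[first]]
    if (is.na(m)) m <- fb
    if ((tv[first] - tv[j]) > m || (t_i - tv[j]) > mts_i) break
    first <- j
    j <- j - 1L
  }
  first
}

#' Dynamic per-event window (spatio-temporal segmentation)
#'
#' Builds the context window of the event at position `i` online: the window
#' starts as the pair (previous event, target event) and grows backwards one
#' event at a time while each candidate passes both the sensor correlation
#' check ([scc()]) against the target and the time correlation check
#' ([tcc()]) against the current head and the target; the scan stops at the
#' first failure, the stream start, or `max_lookback` events. The very first
#' stream event yields the singleton window.
#'
#' @param stream an [event_stream()].
#' @param i target event position (the classification target is the window's
#'   last event).
#' @param model a `correlation_model` from [fit_correlation_model()].
#' @param max_lookback hard cap on window size (events); bounds the
#'   worst-case online latency when thresholds are degenerate.
#' @return an `ar_window` (list with `first`, `target`, `end_time`).
#' @export
dynamic_segment <- function(stream, i, model, max_lookback = 200L) {
  if (i < 1 || i > nrow(stream)) stopf("dynamic_segment: target index out of range")
  first <- ds_first(stream$sensor, stream$time_abs, as.integer(i), model,
                    as.integer(max_lookback))
  new_window(stream, first, i)
}

#' Fixed-size event window baseline
#'
#' The last `min(ws, i)` events ending at the target.
#'
#' @inheritParams dynamic_segment
#' @param ws window size in events (>= 1).
#' @return an `ar_window`.
#' @export
fixed_segment <- function(stream, i, ws) {
  if (ws < 1) stopf("fixed_segment: ws must be >= 1")
  new_window(stream, max(1L, as.integer(i) - as.integer(ws) + 1L), i)
}

#' Fixed time-interval window baseline
#'
#' All events with time in `(T_i - dt, T_i]`.
#'
#' @inheritParams dynamic_segment
#' @param dt interval length in seconds (> 0).
#' @return an `ar_window`.
#' @export
time_segment <- function(stream, i, dt) {
  if (dt <= 0) stopf("time_segment: dt must be > 0")
  tv <- stream$time_abs
  first <- findInterval(tv[i] - dt, tv, left.open = FALSE) + 1L
  # findInterval gives the count of tv <= cutoff; window is strictly after it
  new_window(stream, min(first, i), i)
}

#' Segment every target event of a stream
#'
#' Applies one of the three windowing methods to each requested target and
#' returns one record per target.
#'
#' @inheritParams dynamic_segment
#' @param method `"dynamic"` (requires `model`), `"fixed"` or `"time"`.
#' @param ws fixed window size (events) for `method = "fixed"`.
#' @param dt interval (seconds) for `method = "time"`.
#' @param targets integer vector of target positions (default: all events).
#' @return data.frame with columns `target`, `first`, `size`.
#' @export
segment_stream <- function(stream, method = c("dynamic", "fixed", "time"),
                           model = NULL, ws = 20, dt = 60,
                           targets = seq_len(nrow(stream)),
                           max_lookback = 200L) {
  method <- match.arg(method)
  sv <- stream$sensor; tv <- stream$time_abs
  first <- switch(method,
    dynamic = {
      if (is.null(model)) stopf("segment_stream: dynamic method needs a correlation model")
      vapply(targets, function(i) ds_first(sv, tv, i, model, max_lookback), integer(1))
    },
    fixed = pmax(1L, as.integer(targets) - as.integer(ws) + 1L),
    time = pmin(findInterval(tv[targets] - dt, tv) + 1L, targets))
  data.frame(target = as.integer(targets), first = first,
             size = as.integer(targets) - first + 1L)
}
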