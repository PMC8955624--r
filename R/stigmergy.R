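#' Aggregated pheromone intensity of one sensor activation
#'
#' Marker-based stigmergy: while a sensor is active it releases one unit of
#' pheromone per time step, and every deposited unit decays by the
#' volatilization rate `rho` per step afterwards. The intensity remaining at
#' the window end time `Te` of an activation on `[ts, te)` is the geometric
#' sum
#' \deqn{I = \sum_{t=ts}^{te-1} (1-\rho)^{Te-t-1}
#'         = \frac{(1-\rho)^{Te-te} - (1-\rho)^{Te-ts}}{\rho},}
#' which reduces to the plain activation duration `te - ts` when `rho = 0`.
#' Times are floored to the `time_step` grid first, so the exponents are
#' integers and the closed form equals the explicit sum exactly.
#'
#' All arguments are vectorized.
#'
#' @param ts,te activation start and end times (seconds), `ts <= te`.
#' @param Te window end time (seconds), `te <= Te`.
#' @param rho volatilization rate in `[0, 1)` per time step.
#' @param time_step seconds per decay tick (default 1).
#' @return dimensionless intensity (>= 0; 0 when `ts == te`).
#' @examples
#' pheromone_intensity(0, 12, 27, rho = 0.2) # 0.163833
#' pheromone_intensity(0, 2, 2, rho = 0.2)   # 1.8
#' @export
pheromone_intensity <- function(ts, te, Te, rho = 0.2, time_step = 1) {
  if (any(rho < 0) || any(rho >= 1)) stopf("pheromone_intensity: rho must be in [0, 1)")
  if (any(time_step <= 0)) stopf("pheromone_intensity: time_step must be > 0")
  if (any(ts > te)) stopf("pheromone_intensity: activation start after end (ts > te)")
  if (any(te > Te)) stopf("pheromone_intensity: activation ends after window end (te > Te)")
  n <- max(length(ts), length(te), length(Te), length(rho), length(time_step))
  ts <- rep_len(ts, n); te <- rep_len(te, n); Te <- rep_len(Te, n)
  rho <- rep_len(rho, n); time_step <- rep_len(time_step, n)
  a <- floor(Te / time_step) - floor(te / time_step) # steps since activation end
  b <- floor(Te / time_step) - floor(ts / time_step) # steps since activation start
  out <- numeric(n)
  pos <- rho > 0
  out[pos] <- ((1 - rho[pos])^a[pos] - (1 - rho[pos])^b[pos]) / rho[pos]
  out[!pos] <- ((b - a) * time_step)[!pos]
  out
}

# time of the first subsequent OFF event of the same sensor, for every event
# (NA where none exists); used to close activations
next_off_time <- function(stream) {
  n <- nrow(stream)
  out <- rep(NA_real_, n)
  for (s in unique(stream$sensor)) {
    idx <- which(stream$sensor == s)
    offs <- idx[stream$value[idx] == 0L]
    if (!length(offs)) next
    pos <- findInterval(idx, offs, left.open = TRUE) + 1L # first off strictly after
    has <- pos <= length(offs)
    out[idx[has]] <- stream$time_abs[offs[pos[has]]]
  }
  out
}

# index of the most recent ON event at or before each position (0 if none)
last_on_index <- function(stream) {
  on <- ifelse(stream$value == 1L, seq_len(nrow(stream)), 0L)
  cummax(on)
}

#' Extract sensor activations (triggers) of a window
#'
#' One trigger per ON/OPEN event inside the window, in time order. The
#' activation start `ts` is the ON event's time; the end `te` is the time of
#' the first subsequent OFF/CLOSE event of the same sensor at or before the
#' window end time `Te`, and `Te` itself when no such event exists (the
#' sensor is still active at the window end).
#'
#' @param stream the source [event_stream()].
#' @param window an `ar_window`, or the result row of [segment_stream()]
#'   given as `first`/`target` arguments.
#' @param first,target alternative to `window`: event-index range.
#' @return data.frame with columns `sensor`, `ts`, `te`.
#' @export
extract_triggers <- function(stream, window = NULL, first = window$first,
                             target = window$target) {
  Te <- stream$time_abs[target]
  idx <- first:target
  on <- idx[stream$value[idx] == 1L]
  if (!length(on))
    return(data.frame(sensor = integer(), ts = numeric(), te = numeric()))
  noff <- next_off_time(stream)[on]
  te <- pmin(ifelse(is.na(noff), Te, noff), Te)
  data.frame(sensor = stream$sensor[on], ts = stream$time_abs[on], te = te)
}

#' Build the directed weighted network (stigmergic track) of a window
#'
#' The trigger sequence u1, ..., um of the window traces the resident's
#' coarse trajectory. Edges follow the trigger order: the edge into the k-th
#' trigger starts at the previous trigger (for u1, at the last sensor
#' activated in the stream strictly before the window; at u1 itself when the
#' window opens the stream, giving a self-loop). The weight deposited on the
#' edge ending at trigger k is the aggregated pheromone intensity of that
#' activation at the window end time; repeated edges accumulate by summation.
#'
#' @inheritParams extract_triggers
#' @param rho,time_step stigmergy parameters, see [pheromone_intensity()].
#' @return S x S nonnegative matrix of class `dwn` with attribute
#'   `target_label` (the target event's label, possibly `NA`).
#' @export
build_dwn <- function(stream, window = NULL, first = window$first,
                      target = window$target, rho = 0.2, time_step = 1) {
  S <- length(sensor_catalog(stream))
  trg <- extract_triggers(stream, first = first, target = target)
  w <- matrix(0, S, S)
  if (nrow(trg)) {
    Te <- stream$time_abs[target]
    lastio <- last_on_index(stream)
    prev <- if (first > 1L && lastio[first - 1L] > 0L)
      stream$sensor[lastio[first - 1L]] else trg$sensor[1]
    from <- c(prev, trg$sensor[-nrow(trg)])
    to <- trg$sensor
    inten <- pheromone_intensity(trg$ts, trg$te, Te, rho = rho, time_step = time_step)
    lin <- (to - 1L) * S + from
    acc <- rowsum(inten, lin)
    w[as.integer(rownames(acc))] <- acc[, 1]
  }
  structure(w, class = c("dwn", "matrix"),
            target_label = stream$label[target])
}

#' @export
print.dwn <- function(x, ...) {
  nz <- which(x > 0, arr.ind = TRUE)
  cat(sprintf("<dwn> %dx%d, %d nonzero edges, total pheromone %.4f\n",
              nrow(x), ncol(x), nrow(nz), sum(x)))
  if (nrow(nz)) {
    o <- order(nz[, 1], nz[, 2])
    for (k in o) cat(sprintf("  %d -> %d : %.6f\n", nz[k, 1], nz[k, 2],
                             x[nz[k, 1], nz[k, 2]]))
  }
  invisible(x)
}

#' Activation-duration feature vector of a window (baseline)
#'
#' The classical windowed feature: per sensor, the summed activation duration
#' (seconds) of its triggers inside the window. Ignores trigger order and
#' recency, which is exactly what the stigmergic network adds.
#'
#' @inheritParams extract_triggers
#' @return numeric vector of length S with attribute `target_label`.
#' @export
build_fv <- function(stream, window = NULL, first = window$first,
                     target = window$target) {
  S <- length(sensor_catalog(stream))
  trg <- extract_triggers(stream, first = first, target = target)
  d <- numeric(S)
  if (nrow(trg)) {
    acc <- rowsum(trg$te - trg$ts, trg$sensor)
    d[as.integer(rownames(acc))] <- acc[, 1]
  }
  structure(d, target_label = stream$label[target])
}

#' Featurize every window of a segmented stream
#'
#' Bulk version of [build_dwn()] / [build_fv()]: one feature row per window
#' record, DWN matrices flattened column-major to length S^2.
#'
#' @param stream the source [event_stream()] (labels assigned).
#' @param windows data.frame from [segment_stream()] (`target`, `first`).
#' @param feature `"dwn"` or `"fv"`.
#' @param rho,time_step stigmergy parameters (DWN only).
#' @return list with `features` (n x S^2 or n x S matrix) and `labels`
#'   (integer vector, the target events' labels).
#' @export
featurize_stream <- function(stream, windows, feature = c("dwn", "fv"),
                             rho = 0.1, time_step = 1) {
  feature <- match.arg(feature)
  S <- length(sensor_catalog(stream))
  n <- nrow(windows)
  tv <- stream$time_abs
  sv <- stream$sensor
  noff <- next_off_time(stream)
  lastio <- last_on_index(stream)
  on_all <- which(stream$value == 1L)
  p <- if (feature == "dwn") S * S else S
  feats <- matrix(0, n, p)
  for (k in seq_len(n)) {
    f <- windows$first[k]; tgt <- windows$target[k]
    Te <- tv[tgt]
    lo <- findInterval(f - 1L, on_all) + 1L
    hi <- findInterval(tgt, on_all)
    if (hi < lo) next
    on <- on_all[lo:hi]
    ts <- tv[on]
    te <- pmin(ifelse(is.na(noff[on]), Te, noff[on]), Te)
    u <- sv[on]
    if (feature == "fv") {
      acc <- rowsum(te - ts, u)
      feats[k, as.integer(rownames(acc))] <- acc[, 1]
    } else {
      prev <- if (f > 1L && lastio[f - 1L] > 0L) sv[lastio[f - 1L]] else u[1]
      from <- c(prev, u[-length(u)])
      inten <- pheromone_intensity(ts, te, Te, rho = rho, time_step = time_step)
      lin <- (u - 1L) * S + from
      acc <- rowsum(inten, lin)
      feats[k, as.integer(rownames(acc))] <- acc[, 1]
    }
  }
  list(features = feats, labels = stream$label[windows$target])
}
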