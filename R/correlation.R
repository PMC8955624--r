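#' Sensor correlation matrix (windowed mutual information)
#'
#' The dependence between two sensors is measured as the probability that
#' both fire within the same sliding window of `ws` consecutive events
#' (stride 1): entry (i, j) is the number of windows containing at least one
#' event of sensor i and one of sensor j, divided by the total number of
#' windows. Presence, not multiplicity, is counted, so the matrix is
#' symmetric with entries in [0, 1]; the diagonal is each sensor's window
#' occurrence probability.
#'
#' @param stream an [event_stream()].
#' @param ws window length in events, at least 2.
#' @param ranges optional list of `c(first, last)` event-index ranges; windows
#'   are enumerated within each range only (used to fit on training blocks of
#'   a split stream without crossing block boundaries). Default: whole stream.
#' @return S x S numeric matrix, S the sensor catalog size.
#' @export
compute_scm <- function(stream, ws = 15, ranges = NULL) {
  S <- length(sensor_catalog(stream))
  if (ws < 2) stopf("compute_scm: ws must be >= 2")
  ranges <- ranges %||% list(c(1L, nrow(stream)))
  ranges <- Filter(function(r) r[2] - r[1] + 1L >= ws, ranges)
  if (!length(ranges))
    stopf("compute_scm: no range has at least ws = %d events", ws)
  co <- matrix(0, S, S)
  nwin <- 0L
  sv <- stream$sensor
  for (r in ranges) {
    s <- sv[r[1]:r[2]]
    n <- length(s)
    w <- n - ws + 1L
    nwin <- nwin + w
    # presence[k, j]: does window k contain sensor j? via per-sensor
    # cumulative counts, O(n * S)
    pres <- matrix(FALSE, w, S)
    for (j in unique(s)) {
      cs <- c(0L, cumsum(s == j))
      pres[, j] <- (cs[(ws + 1):(n + 1)] - cs[1:w]) > 0L
    }
    co <- co + crossprod(pres)
  }
  co / nwin
}

#' Per-sensor correlation thresholds
#'
#' For each sensor the threshold is the minimum correlation a candidate must
#' reach to be considered spatially related to it. Two modes: `key_sensor`
#' supplies, for every sensor, the geographically critical neighbour whose
#' correlation value becomes the threshold (the floorplan-informed rule);
#' `rank` takes the k-th largest off-diagonal value of the sensor's row, a
#' layout-free surrogate.
#'
#' @param scm matrix from [compute_scm()].
#' @param key_sensor integer vector of length S: `key_sensor[i]` is the key
#'   sensor of sensor i. Overrides `rank` when given.
#' @param rank k for the k-th-largest-row-value mode (default 1).
#' @return numeric threshold vector of length S.
#' @export
derive_sct <- function(scm, key_sensor = NULL, rank = 1) {
  S <- nrow(scm)
  if (!is.null(key_sensor)) {
    if (length(key_sensor) != S || anyNA(key_sensor))
      stopf("derive_sct: key_sensor must map every one of the %d sensors", S)
    return(scm[cbind(seq_len(S), as.integer(key_sensor))])
  }
  if (rank < 1 || rank > S - 1) stopf("derive_sct: rank must be in 1..S-1")
  vapply(seq_len(S), function(i) {
    v <- sort(scm[i, -i], decreasing = TRUE)
    v[rank]
  }, numeric(1))
}

#' Maximum time interval between consecutive events, per ordered sensor pair
#'
#' For every ordered pair (a, b) of sensors observed in consecutive events
#' (a immediately before b), the gaps between those events form a sample; the
#' threshold is its mean plus twice its standard deviation (the "2 sigma"
#' point). Pairs never observed are `NA` in the matrix and segmentation falls
#' back to the global threshold computed over all consecutive gaps.
#'
#' @inheritParams compute_scm
#' @param sd_type `"population"` (divide by n, the default; one observation
#'   has spread 0) or `"sample"`.
#' @return list with `mti` (S x S matrix, seconds, `NA` where unobserved) and
#'   `fallback` (scalar seconds).
#' @export
compute_mti <- function(stream, ranges = NULL, sd_type = "population") {
  S <- length(sensor_catalog(stream))
  sdev <- sd_fun(sd_type)
  ranges <- ranges %||% list(c(1L, nrow(stream)))
  a <- integer(0); b <- integer(0); dt <- numeric(0)
  for (r in ranges) {
    idx <- r[1]:r[2]
    if (length(idx) < 2L) next
    tv <- stream$time_abs[idx]; sv <- stream$sensor[idx]
    a <- c(a, sv[-length(sv)]); b <- c(b, sv[-1])
    dt <- c(dt, diff(tv))
  }
  if (!length(dt)) stopf("compute_mti: need at least 2 events")
  mti <- matrix(NA_real_, S, S)
  key <- (b - 1L) * S + a # column-major linear index of mti[a, b]
  for (grp in split(seq_along(dt), key)) {
    x <- dt[grp]
    mti[key[grp[1]]] <- mean(x) + 2 * sdev(x)
  }
  list(mti = mti, fallback = mean(dt) + 2 * sdev(dt))
}

#' Maximum time span of activity per clustered functional area
#'
#' Pools the durations (end minus begin, seconds) of all annotated activity
#' instances assigned to each functional area and takes mean plus twice the
#' standard deviation as that area's span threshold. Activities without an
#' entry in `activity_area` are assigned to the area where the majority of
#' their training events fire (with a warning); areas with no instances
#' receive the global mean + 2 sd over all instance durations.
#'
#' @inheritParams compute_mti
#' @param area_map integer vector of length S: functional area of each sensor.
#' @param activity_area named integer vector: activity name to area index
#'   (may be partial, see above).
#' @param n_areas number of areas K (default `max(area_map)`).
#' @return numeric vector of length `n_areas`, seconds.
#' @export
compute_mts <- function(stream, area_map, activity_area = NULL,
                        n_areas = max(area_map), ranges = NULL,
                        sd_type = "population") {
  sdev <- sd_fun(sd_type)
  ranges <- ranges %||% list(c(1L, nrow(stream)))
  inst <- activity_instances(stream)
  if (nrow(inst)) {
    inside <- vapply(seq_len(nrow(inst)), function(k) {
      any(vapply(ranges, function(r) inst$begin[k] >= r[1] && inst$end[k] <= r[2],
                 logical(1)))
    }, logical(1))
    inst <- inst[inside, , drop = FALSE]
  }
  if (!nrow(inst)) stopf("compute_mts: no labeled activity instances in the training data")

  activity_area <- activity_area %||% stats::setNames(integer(0), character(0))
  unmapped <- setdiff(unique(inst$activity), names(activity_area))
  for (a in unmapped) {
    # majority area of the activity's own events
    rows <- inst[inst$activity == a, , drop = FALSE]
    ev_areas <- unlist(lapply(seq_len(nrow(rows)), function(k)
      area_map[stream$sensor[rows$begin[k]:rows$end[k]]]))
    maj <- as.integer(names(which.max(table(ev_areas))))
    warnf("compute_mts: activity '%s' not mapped to an area; majority rule assigns area %d",
          a, maj)
    activity_area[a] <- maj
  }
  area <- activity_area[inst$activity]
  fallback <- mean(inst$duration) + 2 * sdev(inst$duration)
  mts <- rep(fallback, n_areas)
  for (k in unique(area)) {
    x <- inst$duration[area == k]
    mts[k] <- mean(x) + 2 * sdev(x)
  }
  mts
}

#' Fit the offline correlation model for dynamic segmentation
#'
#' The offline phase of the method: from labeled training data it computes
#' the sensor correlation matrix (SCM), the per-sensor correlation thresholds
#' (SCT), the per-ordered-pair maximum time intervals (MTI) with a global
#' fallback, and the per-area maximum time spans (MTS). These four products
#' plus the sensor-to-area map are everything the online segmentation needs.
#'
#' @inheritParams compute_mts
#' @param ws sliding-window length (events) for the SCM.
#' @param key_sensor,sct_rank threshold mode, see [derive_sct()].
#' @return object of class `correlation_model`.
#' @export
fit_correlation_model <- function(stream, area_map, activity_area = NULL,
                                  n_areas = max(area_map), ws = 15,
                                  key_sensor = NULL, sct_rank = 1,
                                  ranges = NULL, sd_type = "population") {
  S <- length(sensor_catalog(stream))
  if (length(area_map) != S) stopf("fit_correlation_model: area_map must cover all %d sensors", S)
  scm <- compute_scm(stream, ws = ws, ranges = ranges)
  sct <- derive_sct(scm, key_sensor = key_sensor, rank = sct_rank)
  ti <- compute_mti(stream, ranges = ranges, sd_type = sd_type)
  mts <- compute_mts(stream, area_map = area_map, activity_area = activity_area,
                     n_areas = n_areas, ranges = ranges, sd_type = sd_type)
  structure(list(scm = scm, sct = sct, mti = ti$mti, mti_fallback = ti$fallback,
                 mts = mts, area_map = as.integer(area_map),
                 scm_window = as.integer(ws), n_sensors = S,
                 sd_type = sd_type),
            class = "correlation_model")
}

#' @export
print.correlation_model <- function(x, ...) {
  cat(sprintf("<correlation_model> %d sensors, %d areas, SCM window %d\n",
              x$n_sensors, length(x$mts), x$scm_window))
  cat(sprintf("  SCT range [%.3f, %.3f]; MTI fallback %.1f s; MTS %s s\n",
              min(x$sct), max(x$sct), x$mti_fallback,
              paste(sprintf("%.0f", x$mts), collapse = "/")))
  invisible(x)
}

#' Serialize / restore a correlation model as JSON
#'
#' Matrices are written row-major with explicit dimensions so the round trip
#' is exact (`NA` entries of MTI map to JSON null).
#'
#' @param model a `correlation_model`.
#' @param path file path.
#' @return `read_correlation_model` returns the restored model;
#'   `write_correlation_model` returns `path` invisibly.
#' @export
write_correlation_model <- function(model, path) {
  payload <- list(
    n_sensors = model$n_sensors,
    scm = as.vector(t(model$scm)),
    sct = model$sct,
    mti = as.vector(t(model$mti)),
    mti_fallback = model$mti_fallback,
    mts = model$mts,
    area_map = model$area_map,
    scm_window = model$scm_window,
    sd_type = model$sd_type)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_correlation_model
#' @export
read_correlation_model <- function(path) {
  p <- jsonlite::fromJSON(path)
  S <- as.integer(p$n_sensors)
  structure(list(
    scm = matrix(as.numeric(p$scm), S, S, byrow = TRUE),
    sct = as.numeric(p$sct),
    mti = matrix(as.numeric(p$mti), S, S, byrow = TRUE),
    mti_fallback = as.numeric(p$mti_fallback),
    mts = as.numeric(p$mts),
    area_map = as.integer(p$area_map),
    scm_window = as.integer(p$scm_window),
    n_sensors = S,
    sd_type = p$sd_type), class = "correlation_model")
}
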