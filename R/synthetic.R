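#' Configuration of the "mini-home" simulated testbed
#'
#' A small smart home used throughout the test suite: three functional areas
#' (Kitchen, Bedroom, Living) owning three motion sensors each, and five
#' activities of daily living plus the implicit "Other Activity" emitted
#' between instances. The defaults are chosen as realistic for ambient
#' sensing -- activation dwells of a few seconds, activity durations of one
#' to five minutes with moderate spread, exponential inter-activity gaps --
#' while keeping integration runs fast.
#'
#' @param seed RNG seed for [simulate_stream()].
#' @param n_instances number of activity instances to draw.
#' @param epsilon cross-area firing probability per step (sensor noise /
#'   imprecise coverage), in `[0, 1)`.
#' @param gap_mean mean of the exponential inter-activity gap (seconds).
#' @param dwell_mean mean sensor activation dwell (seconds, log-normal).
#' @param start_date first calendar day of the stream.
#' @return a `sim_config` list: `sensors` (named catalog), `areas` (list of
#'   sensor-index vectors), `area_names`, `activities` (data.frame with
#'   `name`, `area`, `dur_mean`, `dur_sd`, `weight`), `schedule`
#'   (`gap_mean`, `wander_max`), `epsilon`, `dwell` parameters, `horizon`,
#'   `seed`.
#' @export
mini_home_config <- function(seed = 1, n_instances = 150, epsilon = 0.05,
                             gap_mean = 180, dwell_mean = 8,
                             start_date = "2021-06-01") {
  sensors <- stats::setNames(1:9, sprintf("M%03d", 1:9))
  activities <- data.frame(
    name = c("Cook", "Wash_Dishes", "Sleep", "Relax", "Work"),
    area = c(1L, 1L, 2L, 3L, 3L),
    dur_mean = c(120, 60, 300, 150, 90),
    dur_sd = c(25, 12, 60, 30, 18),
    weight = c(0.25, 0.10, 0.15, 0.30, 0.20))
  cfg <- list(
    sensors = sensors,
    areas = list(1:3, 4:6, 7:9),
    area_names = c("Kitchen", "Bedroom", "Living"),
    activities = activities,
    schedule = list(gap_mean = gap_mean, wander_max = 3L),
    epsilon = epsilon,
    dwell = list(mean = dwell_mean, sdlog = 0.4),
    horizon = as.integer(n_instances),
    start_date = start_date,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$epsilon < 0 || cfg$epsilon >= 1) stopf("sim_config: epsilon must be in [0, 1)")
  if (any(cfg$activities$dur_mean <= 0) || any(cfg$activities$dur_sd < 0))
    stopf("sim_config: activity durations must be positive")
  if (!all(cfg$activities$area %in% seq_along(cfg$areas)))
    stopf("sim_config: every activity's area must exist")
  if (!length(unlist(cfg$areas)) || !setequal(unlist(cfg$areas), cfg$sensors))
    stopf("sim_config: areas must partition the sensor catalog")
  if (cfg$horizon < 1) stopf("sim_config: horizon must be >= 1")
  invisible(cfg)
}

#' Sensor-to-area and activity-to-area maps of a simulation config
#'
#' @param config a `sim_config`.
#' @return `sim_area_map`: integer vector (sensor index to area);
#'   `sim_activity_area`: named integer vector (activity name to area).
#' @export
sim_area_map <- function(config) {
  S <- length(config$sensors)
  am <- integer(S)
  for (k in seq_along(config$areas)) am[config$areas[[k]]] <- k
  am
}

#' @rdname sim_area_map
#' @export
sim_activity_area <- function(config) {
  stats::setNames(config$activities$area, config$activities$name)
}

#' Simulate an annotated binary sensor-event stream
#'
#' Draws a sequence of activity instances from the schedule weights. Each
#' instance performs a random walk over its area's sensors: arriving at a
#' sensor emits ON, a log-normal dwell later the matching OFF, until the
#' instance's target duration (normal, truncated positive) is exhausted. With
#' probability `epsilon` a step fires an out-of-area sensor instead
#' (annotated with the ongoing activity, as a real mislocated firing would
#' be). The first and last event of every instance carry the begin/end
#' annotation. Between instances an exponential gap elapses during which up
#' to `wander_max` unannotated wander firings occur at random sensors. Events
#' are strictly time-ordered and the stream is a deterministic function of
#' `config$seed`.
#'
#' @param config a `sim_config`, see [mini_home_config()].
#' @return an [event_stream()] with annotations (labels not yet assigned);
#'   attribute `instances` holds the ground-truth instance table
#'   (`activity`, `t_begin`, `t_end`, `duration`).
#' @export
simulate_stream <- function(config) {
  validate_sim_config(config)
  acts <- config$activities
  S <- length(config$sensors)
  dwell_meanlog <- log(config$dwell$mean) - config$dwell$sdlog^2 / 2

  with_seed(config$seed, {
    t <- 6 * 3600 # day starts at 06:00
    ev <- list()
    inst <- list()
    emit <- function(tm, sensor, value, activity = NA_character_,
                     marker = NA_character_) {
      ev[[length(ev) + 1L]] <<- list(t = tm, s = sensor, v = value,
                                     a = activity, m = marker)
    }
    for (k in seq_len(config$horizon)) {
      ai <- sample(nrow(acts), 1, prob = acts$weight)
      area_sensors <- config$areas[[acts$area[ai]]]
      target_dur <- max(stats::rnorm(1, acts$dur_mean[ai], acts$dur_sd[ai]),
                        0.2 * acts$dur_mean[ai])
      t_begin <- t
      first_of_inst <- length(ev) + 1L
      repeat {
        s <- if (stats::runif(1) < config$epsilon)
          sample(setdiff(seq_len(S), area_sensors), 1)
        else sample(area_sensors, 1)
        dwell <- stats::rlnorm(1, dwell_meanlog, config$dwell$sdlog)
        # activity names travel on the begin/end marker lines only, as in the
        # CASAS annotation format; in-between events are labelled later
        emit(t, s, 1L)
        emit(t + dwell, s, 0L)
        t <- t + dwell + stats::runif(1, 0.5, 2)
        if (t - t_begin >= target_dur) break
      }
      ev[[first_of_inst]]$m <- "begin"
      ev[[first_of_inst]]$a <- acts$name[ai]
      ev[[length(ev)]]$m <- "end"
      ev[[length(ev)]]$a <- acts$name[ai]
      t_end <- ev[[length(ev)]]$t
      inst[[k]] <- data.frame(activity = acts$name[ai], t_begin = t_begin,
                              t_end = t_end, duration = t_end - t_begin)
      # inter-activity gap with optional unannotated wander firings
      gap <- stats::rexp(1, 1 / config$schedule$gap_mean)
      n_w <- sample(0:config$schedule$wander_max, 1)
      tw <- t + 5
      for (w in seq_len(n_w)) {
        tw <- tw + stats::runif(1, 20, 60)
        if (tw + 5 >= t + gap) break
        sw <- sample(S, 1)
        d <- stats::runif(1, 1, 3)
        emit(tw, sw, 1L)
        emit(tw + d, sw, 0L)
        tw <- tw + d
      }
      t <- t + max(gap, if (length(ev)) ev[[length(ev)]]$t - t + 1 else 0, 5)
    }
    tms <- vapply(ev, `[[`, numeric(1), "t")
    day0 <- as.Date(config$start_date)
    df <- data.frame(
      date = format(day0 + floor(tms / 86400), "%Y-%m-%d"),
      time_of_day = tms %% 86400,
      sensor = vapply(ev, `[[`, integer(1), "s"),
      value = vapply(ev, `[[`, integer(1), "v"),
      activity = vapply(ev, `[[`, character(1), "a"),
      marker = vapply(ev, `[[`, character(1), "m"),
      stringsAsFactors = FALSE)
    acat <- stats::setNames(seq_len(nrow(acts)), acts$name)
    out <- event_stream(df, sensor_catalog = config$sensors,
                        activity_catalog = acat)
    attr(out, "instances") <- do.call(rbind, inst)
    out
  })
}

#' Ground-truth segment of every event
#'
#' Recovers, from the begin/end annotations alone, the activity instance that
#' contains each event; contiguous runs of unannotated events form "Other"
#' pseudo-spans. Together the spans partition the stream.
#'
#' @param stream an annotated [event_stream()].
#' @return data.frame with one row per event: `event`, `span` (id),
#'   `activity` (name or `"Other"`), `first`, `last` (span bounds, event
#'   indices).
#' @export
ground_truth_windows <- function(stream) {
  n <- nrow(stream)
  inst <- activity_instances(stream)
  span_id <- integer(n)
  act <- rep("Other", n)
  for (k in seq_len(nrow(inst))) {
    idx <- inst$begin[k]:inst$end[k]
    span_id[idx] <- k
    act[idx] <- inst$activity[k]
  }
  # unannotated runs become pseudo-spans numbered after the real ones
  next_id <- nrow(inst)
  i <- 1L
  while (i <= n) {
    if (span_id[i] == 0L) {
      j <- i
      while (j < n && span_id[j + 1L] == 0L) j <- j + 1L
      next_id <- next_id + 1L
      span_id[i:j] <- next_id
      i <- j + 1L
    } else i <- i + 1L
  }
  first <- stats::ave(seq_len(n), span_id, FUN = min)
  last <- stats::ave(seq_len(n), span_id, FUN = max)
  data.frame(event = seq_len(n), span = span_id, activity = act,
             first = as.integer(first), last = as.integer(last))
}
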