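# shared fixture builders and independent oracles

# quick event_stream on a single day from parallel vectors
make_stream <- function(sensor, time, value = rep(1L, length(sensor)),
                        activity = rep(NA_character_, length(sensor)),
                        marker = rep(NA_character_, length(sensor)),
                        n_sensors = max(sensor),
                        activities = character(0)) {
  event_stream(
    data.frame(date = "2021-01-01", time_of_day = time,
               sensor = as.integer(sensor), value = as.integer(value),
               activity = activity, marker = marker,
               stringsAsFactors = FALSE),
    sensor_catalog = stats::setNames(seq_len(n_sensors),
                                     sprintf("M%03d", seq_len(n_sensors))),
    activity_catalog = stats::setNames(seq_along(activities), activities))
}

# brute-force SCM: enumerate every length-ws window and test joint presence
oracle_scm <- function(stream, ws) {
  s <- stream$sensor
  S <- length(attr(stream, "sensor_catalog"))
  W <- length(s) - ws + 1
  m <- matrix(0, S, S)
  for (k in seq_len(W)) {
    u <- unique(s[k:(k + ws - 1)])
    m[u, u] <- m[u, u] + 1
  }
  m / W
}

# brute-force explicit pheromone sum, term by term on the time grid
oracle_intensity <- function(ts, te, Te, rho, time_step = 1) {
  ts <- floor(ts / time_step); te <- floor(te / time_step); Te <- floor(Te / time_step)
  if (te == ts) return(0)
  tt <- ts:(te - 1)
  if (rho == 0) return(length(tt) * time_step)
  sum((1 - rho)^(Te - tt - 1))
}

# independent dynamic-segmentation oracle: grows an explicit event list and
# re-evaluates the three gate conditions from scratch at every extension
oracle_dynamic_window <- function(stream, i, model, max_lookback = 200L) {
  if (i == 1L) return(1L)
  win <- c(i - 1L, i)
  for (j in rev(seq_len(i - 2L))) {
    if ((i - j) > max_lookback) break
    s_j <- stream$sensor[j]; s_i <- stream$sensor[i]
    first <- win[1]
    pass_scc <- s_j == s_i || model$scm[s_j, s_i] >= model$sct[s_i]
    mti <- model$mti[s_j, stream$sensor[first]]
    if (is.na(mti)) mti <- model$mti_fallback
    t_first_cor <- 1 - (stream$time_abs[first] - stream$time_abs[j]) / mti
    t_i_cor <- 1 - (stream$time_abs[i] - stream$time_abs[j]) /
      model$mts[model$area_map[s_i]]
    if (pass_scc && t_first_cor >= 0 && t_i_cor >= 0) win <- c(j, win)
    else break
  }
  win[1]
}

# a hand-specifiable correlation model for segmentation unit tests
toy_model <- function(S = 3, scm = matrix(1, S, S), sct = rep(0, S),
                      mti = matrix(Inf, S, S), mti_fallback = Inf,
                      mts = Inf, area_map = rep(1L, S)) {
  structure(list(scm = scm, sct = sct, mti = mti, mti_fallback = mti_fallback,
                 mts = mts, area_map = area_map, scm_window = 2L,
                 n_sensors = S, sd_type = "population"),
            class = "correlation_model")
}

# random stream generator for property tests (uniform sensors, jittered clock)
random_stream <- function(n, S = 5, max_gap = 10) {
  make_stream(sensor = sample(S, n, replace = TRUE),
              time = cumsum(runif(n, 0.5, max_gap)),
              value = sample(0:1, n, replace = TRUE),
              n_sensors = S)
}

# the worked stigmergy example: trigger order (2) -> 2 -> 1 -> 3 -> 3 -> 2 -> 3
# with the printed clock times; window is events 2..12, target at 02:37:02,
# preceded by an out-of-window firing of sensor 2 (the "previous location")
fig3_stream <- function() {
  hms <- function(h, m, s) h * 3600 + m * 60 + s
  make_stream(
    sensor = c(2, 2, 2, 1, 1, 3, 3, 3, 3, 2, 2, 3, 2),
    time = c(hms(2, 36, 20), # prior ON of sensor 2, before the window
             hms(2, 36, 35), hms(2, 36, 47),   # trigger 2: ON .. OFF
             hms(2, 36, 48), hms(2, 36, 50),   # trigger 1
             hms(2, 36, 51), hms(2, 36, 53),   # trigger 3 (first)
             hms(2, 36, 54), hms(2, 36, 56),   # trigger 3 (second) -> 3->3
             hms(2, 36, 57), hms(2, 36, 59),   # trigger 2 (second)
             hms(2, 37, 0),                    # trigger 3 (last), no OFF
             hms(2, 37, 2)),                   # target event (sensor 2 OFF)
    value = c(1, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0),
    n_sensors = 3)
}

# labeled mini-home stream shared by the slower tests (fit once per session)
mini_stream <- local({
  cache <- new.env()
  function(seed = 11, n_instances = 150, epsilon = 0.05) {
    key <- paste(seed, n_instances, epsilon)
    if (is.null(cache[[key]])) {
      cfg <- mini_home_config(seed = seed, n_instances = n_instances,
                              epsilon = epsilon)
      cache[[key]] <- list(config = cfg,
                           stream = assign_labels(simulate_stream(cfg)))
    }
    cache[[key]]
  }
})
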