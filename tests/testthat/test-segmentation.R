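test_that("sensor correlation check compares SCM against the target's threshold", {
  m <- toy_model(S = 2, scm = matrix(c(1, 0.4, 0.4, 1), 2), sct = c(0.3, 0.3))
  expect_true(scc(m, 2, 1))
  m$sct <- c(0.5, 0.5)
  expect_false(scc(m, 2, 1))
  # the target sensor passes against itself even with a degenerate threshold
  m$sct <- c(1.5, 1.5)
  expect_true(scc(m, 1, 1))
  expect_error(scc(m, 3, 1), "out of range")
})

test_that("time correlation check gates on head gap (MTI) and window span (MTS), equality passing", {
  m <- toy_model(S = 2, mti = matrix(10, 2, 2), mts = 100)
  expect_true(tcc(m, t_cand = 95, s_cand = 1, t_first = 100, s_first = 2,
                  t_target = 115, s_target = 2))     # gap 5 <= 10, span 20 <= 100
  expect_false(tcc(m, 85, 1, 100, 2, 115, 2))        # gap 15 > 10
  expect_true(tcc(m, 90, 1, 100, 2, 115, 2))         # gap == 10: boundary passes
  expect_false(tcc(m, 95, 1, 100, 2, 300, 2))        # span 205 > 100
  # unobserved pair falls back to the global threshold instead of failing
  m2 <- toy_model(S = 2, mti = matrix(NA_real_, 2, 2), mti_fallback = 10, mts = 1e6)
  expect_true(tcc(m2, 95, 1, 100, 2, 115, 2))
  expect_false(tcc(m2, 80, 1, 100, 2, 115, 2))
})

test_that("dynamic windows initialize with the previous event and stop at the first failing candidate", {
  s <- make_stream(sensor = c(3, 1, 2, 1), time = c(0, 10, 20, 30), n_sensors = 3)
  # sensor 3 uncorrelated with target sensor 1: candidate at position 1 fails
  scm <- matrix(0.9, 3, 3); scm[3, 1] <- scm[1, 3] <- 0
  m <- toy_model(S = 3, scm = scm, sct = rep(0.5, 3))
  w <- dynamic_segment(s, 4, m)
  expect_equal(c(w$first, w$target), c(2L, 4L))
  expect_equal(w$end_time, 30)
  # E_{i-1} is admitted unconditionally even though it would fail the checks
  w2 <- dynamic_segment(make_stream(c(3, 1), c(0, 10), n_sensors = 3), 2, m)
  expect_equal(w2$first, 1L)
  # fully permissive thresholds: the window runs to the stream start / lookback cap
  free <- toy_model(S = 3)
  s10 <- make_stream(sensor = rep(1:2, 5), time = 1:10, n_sensors = 3)
  expect_equal(dynamic_segment(s10, 10, free)$first, 1L)
  expect_equal(dynamic_segment(s10, 10, free, max_lookback = 4)$first, 6L)
  # the very first event yields the singleton window
  expect_equal(dynamic_segment(s10, 1, free)$first, 1L)
})

test_that("dynamic segmentation matches the independent gate-by-gate oracle on random cases", {
  set.seed(101)
  sim <- mini_stream(seed = 11, n_instances = 30)
  am <- sim_area_map(sim$config)
  model <- fit_correlation_model(sim$stream, area_map = am,
                                 activity_area = sim_activity_area(sim$config),
                                 sct_rank = 2)
  n <- nrow(sim$stream)
  for (i in sample(n, 300)) {
    expect_equal(dynamic_segment(sim$stream, i, model)$first,
                 oracle_dynamic_window(sim$stream, i, model),
                 label = sprintf("target %d", i))
  }
})

test_that("dynamic windows are causal and respect the span bound beyond the initial pair", {
  sim <- mini_stream(seed = 11, n_instances = 30)
  s <- sim$stream
  model <- fit_correlation_model(s, area_map = sim_area_map(sim$config),
                                 activity_area = sim_activity_area(sim$config),
                                 sct_rank = 2)
  set.seed(5)
  for (i in sample(50:nrow(s), 40)) {
    w <- dynamic_segment(s, i, model)
    # online property: truncating the stream right after the target changes nothing
    w2 <- dynamic_segment(s[1:i, ], i, model)
    expect_equal(w2$first, w$first)
    if (w$target - w$first + 1L > 2L) {
      span <- s$time_abs[w$target] - s$time_abs[w$first]
      expect_lte(span, model$mts[model$area_map[s$sensor[w$target]]])
      # every event before the unconditionally admitted E_{i-1} passed SCC
      for (j in w$first:(w$target - 2L))
        expect_true(scc(model, s$sensor[j], s$sensor[w$target]))
    }
  }
})

test_that("fixed-size and time-interval baselines slice the expected events", {
  s <- make_stream(sensor = rep(1, 10), time = 1:10) # uniform 1 Hz
  expect_equal(fixed_segment(s, 10, 6)$first, 5L)
  expect_equal(fixed_segment(s, 3, 6)$first, 1L)
  expect_equal(fixed_segment(s, 7, 1)$first, 7L)
  # (T_i - dt, T_i] with T_i = 10, dt = 5 keeps times 6..10: five events
  w <- time_segment(s, 10, 5)
  expect_equal(w$target - w$first + 1L, 5L)
  # dt smaller than any gap: singleton
  expect_equal(time_segment(s, 5, 0.5)$first, 5L)
  # everything within range is included
  expect_equal(time_segment(s, 10, 60)$first, 1L)
  expect_error(fixed_segment(s, 3, 0), "ws")
  expect_error(time_segment(s, 3, 0), "dt")
})

test_that("segment_stream emits one consistent record per target for all methods", {
  sim <- mini_stream(seed = 11, n_instances = 30)
  s <- sim$stream
  model <- fit_correlation_model(s, area_map = sim_area_map(sim$config),
                                 activity_area = sim_activity_area(sim$config),
                                 sct_rank = 2)
  for (method in c("dynamic", "fixed", "time")) {
    w <- segment_stream(s, method, model = model, ws = 6, dt = 30)
    expect_equal(nrow(w), nrow(s))
    expect_true(all(w$first >= 1 & w$first <= w$target))
    expect_equal(w$size, w$target - w$first + 1L)
  }
  # bulk dynamic records agree with the single-target function
  wd <- segment_stream(s, "dynamic", model = model, targets = c(5L, 50L, 500L))
  expect_equal(wd$first, vapply(c(5L, 50L, 500L), function(i)
    dynamic_segment(s, i, model)$first, integer(1)))
  expect_error(segment_stream(s, "dynamic"), "correlation model")
})
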