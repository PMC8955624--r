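test_that("pheromone intensity reproduces the worked closed-form values", {
  # self-loop of the worked example: activation 27 s to 15 s before window end
  expect_equal(round(pheromone_intensity(0, 12, 27, rho = 0.2), 6), 0.163833)
  # final edge: activation ends at the window end, two steps long
  expect_equal(pheromone_intensity(0, 2, 2, rho = 0.2), 1.8)
})

test_that("closed form equals the explicit step-by-step sum and obeys the limits", {
  set.seed(7)
  for (k in 1:200) {
    Te <- sample(0:400, 1)
    te <- Te - sample(0:min(Te, 50), 1)
    ts <- te - sample(0:min(te, 60), 1)
    rho <- runif(1, 0, 0.95)
    expect_equal(pheromone_intensity(ts, te, Te, rho),
                 oracle_intensity(ts, te, Te, rho), tolerance = 1e-12)
  }
  # no volatility: intensity is the activation duration, exactly
  expect_identical(pheromone_intensity(3, 17, 40, rho = 0), 14)
  # vanishing volatility converges to the duration
  expect_equal(pheromone_intensity(3, 17, 40, rho = 1e-9), 14, tolerance = 1e-6)
  # empty activation deposits nothing
  expect_identical(pheromone_intensity(5, 5, 10, rho = 0.3), 0)
  # vectorized over tuples
  expect_equal(pheromone_intensity(c(0, 0), c(12, 2), c(27, 2), rho = c(0.2, 0.2)),
               c(oracle_intensity(0, 12, 27, 0.2), 1.8))
  expect_error(pheromone_intensity(5, 3, 10, 0.2), "ts > te")
  expect_error(pheromone_intensity(1, 12, 10, 0.2), "te > Te")
  expect_error(pheromone_intensity(1, 2, 3, 1), "rho")
})

test_that("old pheromone decays strictly as the window end recedes", {
  i0 <- pheromone_intensity(0, 10, 10, rho = 0.2)
  last <- i0
  for (Te in 11:30) {
    cur <- pheromone_intensity(0, 10, Te, rho = 0.2)
    expect_lt(cur, last)
    last <- cur
  }
  # without volatility the intensity is Te-invariant
  expect_equal(pheromone_intensity(0, 10, 30, rho = 0),
               pheromone_intensity(0, 10, 10, rho = 0))
})

test_that("trigger extraction pairs each ON with its own sensor's next OFF, capped at the window end", {
  # S2 ON..OFF, then S1 ON with no OFF before the target
  s <- make_stream(sensor = c(2, 2, 1, 3), value = c(1, 0, 1, 1),
                   time = c(0, 5, 8, 12), n_sensors = 3)
  trg <- extract_triggers(s, first = 1, target = 4)
  expect_equal(trg$sensor, c(2, 1, 3))
  expect_equal(trg$ts, c(0, 8, 12))
  expect_equal(trg$te, c(5, 12, 12)) # missing OFFs run to Te
  # two consecutive ONs of the same sensor are two separate triggers
  s2 <- make_stream(sensor = c(3, 3, 3), value = c(1, 1, 0), time = c(0, 2, 6))
  trg2 <- extract_triggers(s2, first = 1, target = 3)
  expect_equal(trg2$sensor, c(3, 3))
  expect_equal(trg2$te, c(6, 6)) # both close at the same OFF
  # all-OFF window has no triggers
  s3 <- make_stream(sensor = c(1, 2), value = c(0, 0), time = c(0, 1))
  expect_equal(nrow(extract_triggers(s3, first = 1, target = 2)), 0L)
})

test_that("the worked-example window reconstructs the expected directed weighted network", {
  s <- fig3_stream()
  d <- build_dwn(s, first = 2, target = 13, rho = 0.2)
  edges <- which(unclass(d) > 0, arr.ind = TRUE)
  got <- apply(edges, 1, paste, collapse = "->")
  expect_setequal(got, c("2->2", "2->1", "1->3", "3->3", "3->2", "2->3"))
  expect_equal(round(d[2, 2], 6), 0.163833) # self-loop onto the first trigger
  expect_equal(d[2, 3], 1.8, tolerance = 1e-12) # final edge
  expect_true(all(d >= 0))
})

test_that("self-loop fallback and edge accumulation behave per the stigmergy rules", {
  # a single trigger with no prior stream history loops onto itself
  s <- make_stream(sensor = c(5, 5), value = c(1, 0), time = c(0, 4), n_sensors = 6)
  d <- build_dwn(s, first = 1, target = 2, rho = 0)
  expect_equal(d[5, 5], 4)
  expect_equal(sum(d > 0), 1L)
  # repeated edges accumulate by summation: 1->2 twice
  s2 <- make_stream(sensor = c(1, 2, 2, 1, 1, 2, 2),
                    value = c(1, 1, 0, 1, 0, 1, 0),
                    time = c(0, 2, 5, 6, 8, 10, 13), n_sensors = 2)
  d2 <- build_dwn(s2, first = 1, target = 7, rho = 0)
  expect_equal(d2[1, 2], (5 - 2) + (13 - 10))
  # empty trigger list gives the zero matrix
  s3 <- make_stream(sensor = c(1, 2), value = c(0, 0), time = c(0, 1))
  expect_true(all(build_dwn(s3, first = 1, target = 2, rho = 0.2) == 0))
})

test_that("without volatility the network mass equals the duration feature vector", {
  # integer clock so the duration features live on the decay grid; per-sensor
  # ON/OFF alternation as a real binary sensor produces
  set.seed(3)
  n <- 400
  sensor <- sample(4, n, replace = TRUE)
  state <- integer(4)
  value <- integer(n)
  for (i in seq_len(n)) {
    value[i] <- 1L - state[sensor[i]]
    state[sensor[i]] <- value[i]
  }
  s <- make_stream(sensor = sensor, value = value,
                   time = cumsum(sample(1:9, n, replace = TRUE)),
                   n_sensors = 4)
  for (tgt in sample(20:n, 25)) {
    first <- max(1L, tgt - 12L)
    d <- build_dwn(s, first = first, target = tgt, rho = 0)
    fv <- build_fv(s, first = first, target = tgt)
    # column u of the matrix collects all deposits of sensor u's activations
    expect_equal(colSums(unclass(d)), as.numeric(fv), tolerance = 1e-9,
                 label = sprintf("target %d", tgt))
    expect_true(all(fv >= 0))
    # non-overlapping activations per sensor are bounded by the window span
    expect_lte(max(fv), s$time_abs[tgt] - s$time_abs[first] + 1e-9)
  }
})

test_that("bulk featurization agrees with the per-window builders", {
  sim <- mini_stream(seed = 11, n_instances = 20)
  s <- sim$stream
  win <- segment_stream(s, "fixed", ws = 10, targets = seq(15, nrow(s), by = 37))
  fx_dwn <- featurize_stream(s, win, "dwn", rho = 0.15)
  fx_fv <- featurize_stream(s, win, "fv")
  S <- length(attr(s, "sensor_catalog"))
  for (k in seq_len(nrow(win))) {
    d <- build_dwn(s, first = win$first[k], target = win$target[k], rho = 0.15)
    expect_equal(fx_dwn$features[k, ], as.vector(unclass(d)))
    fv <- build_fv(s, first = win$first[k], target = win$target[k])
    expect_equal(fx_fv$features[k, ], as.numeric(fv))
  }
  expect_equal(fx_dwn$labels, s$label[win$target])
})
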