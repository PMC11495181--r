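test_that("rate profiles realize the pattern taxonomy", {
  fx <- controlCyclesFixture()
  cyc <- fx$sc$cycles
  sched <- fx$schedule

  iaug <- rateProfile(neuronSpecs("x", pattern_class = "I-Aug",
                                  base_rate = 10, depth = 1,
                                  phasic = TRUE),
                      sched, cyc)
  c1 <- cyc[5, ]
  expect_equal(iaug(c1$i_onset), 0, tolerance = 1e-9)
  expect_equal(iaug(c1$e_onset - 1e-6), 20, tolerance = 1e-3)
  midE <- (c1$e_onset + c1$cycle_end) / 2
  expect_equal(iaug(midE), 0)                 # phasic: silent in expiration

  idec <- rateProfile(neuronSpecs("x", pattern_class = "I-Dec",
                                  base_rate = 10, depth = 1, phasic = TRUE),
                      sched, cyc)
  expect_equal(idec(c1$i_onset), 20, tolerance = 1e-3)

  nrm <- rateProfile(neuronSpecs("x", pattern_class = "NRM",
                                 base_rate = 7, depth = 0), sched, cyc)
  tt <- seq(10, 200, by = 7.3)
  expect_true(all(nrm(tt) == 7))

  expect_error(rateProfile(list(pattern_class = "bogus", base_rate = 1,
                                depth = 0), sched, cyc), "unknown pattern")
})

test_that("gasp-only neurons are silent in control and burst only at gasps", {
  gs <- scenarioFixture(7)
  tru <- gs$truth
  n19 <- sessionTrains(gs$session)$N19
  ctl <- controlWindow(gs$session)
  expect_equal(sum(spikeTimes(n19) >= ctl[1] & spikeTimes(n19) < ctl[2]), 0)
  expect_gt(length(spikeTimes(n19)), 50)
  gd <- attr(tru@schedule, "gasp_duration")
  inEnv <- vapply(spikeTimes(n19), function(t)
    any(t >= tru@gaspTimes & t < tru@gaspTimes + gd), logical(1))
  expect_true(all(inEnv))
})

test_that("thinning reproduces a constant nominal rate within 2%", {
  fx <- controlCyclesFixture()
  specs <- neuronSpecs("c", pattern_class = "NRM", base_rate = 10)
  counts <- vapply(1:100, function(s)
    length(spikeTimes(sampleCoupledPopulation(
      specs, NULL, list(), fx$schedule, fx$sc$cycles, seed = s)$c)),
    numeric(1))
  T <- max(fx$schedule$t1)
  expect_lt(abs(mean(counts) / T - 10) / 10, 0.02)
})

test_that("an uncoupled pair has Poisson-scale counts", {
  fx <- controlCyclesFixture(duration = 300)
  specs <- neuronSpecs(c("a", "b"), pattern_class = "NRM", base_rate = 10)
  tr <- sampleCoupledPopulation(specs, NULL, list(), fx$schedule,
                                fx$sc$cycles, seed = 5)
  for (id in c("a", "b"))
    expect_lt(abs(length(spikeTimes(tr[[id]])) - 3000), 4 * sqrt(3000))
})

test_that("coupling calibration matches the analytic excess count", {
  # excess target spikes in [latency, latency+width] after source spikes
  # = N_src * r_tgt * width * (strength - 1), checked by brute-force
  # counting over Monte Carlo repeats
  fx <- controlCyclesFixture(duration = 300)
  specs <- neuronSpecs(c("s", "t"), pattern_class = "NRM", base_rate = 10)
  conn <- connectionSpecs("s", "t", latency = 0.002, kernel_width = 0.003,
                          strength = 3)
  excess <- vapply(1:20, function(sd) {
    tr <- sampleCoupledPopulation(specs, conn, list(), fx$schedule,
                                  fx$sc$cycles, seed = 100 + sd)
    s <- spikeTimes(tr$s); t <- spikeTimes(tr$t)
    inWin <- sum(vapply(s, function(x)
      sum(t >= x + 0.002 & t < x + 0.005), numeric(1)))
    inWin - length(s) * 10 * 0.003            # observed minus baseline
  }, numeric(1))
  analytic <- 3000 * 10 * 0.003 * (3 - 1)
  mcSd <- stats::sd(excess) / sqrt(length(excess))
  # the first-order formula ignores kernel-overlap compounding, which
  # adds ~ r_src * width * (s - 1) relative excess (~6% here)
  expect_lt(abs(mean(excess) - analytic), 3 * mcSd + 0.06 * analytic)
})

test_that("sampling is deterministic and per-neuron streams are stable", {
  fx <- controlCyclesFixture()
  specs <- neuronSpecs(c("a", "b"), pattern_class = "NRM", base_rate = 8)
  t1 <- sampleCoupledPopulation(specs, NULL, list(), fx$schedule,
                                fx$sc$cycles, seed = 9)
  t2 <- sampleCoupledPopulation(specs, NULL, list(), fx$schedule,
                                fx$sc$cycles, seed = 9)
  expect_identical(lapply(t1, spikeTimes), lapply(t2, spikeTimes))
  t3 <- sampleCoupledPopulation(specs, NULL, list(), fx$schedule,
                                fx$sc$cycles, seed = 10)
  expect_false(identical(spikeTimes(t1$a), spikeTimes(t3$a)))
  # adding an unconnected neuron leaves existing spikes untouched
  specs3 <- neuronSpecs(c("a", "b", "zz"), pattern_class = "NRM",
                        base_rate = 8)
  t4 <- sampleCoupledPopulation(specs3, NULL, list(), fx$schedule,
                                fx$sc$cycles, seed = 9)
  expect_identical(spikeTimes(t1$a), spikeTimes(t4$a))
  expect_identical(spikeTimes(t1$b), spikeTimes(t4$b))
})

test_that("self-connections and cyclic graphs are handled", {
  fx <- controlCyclesFixture()
  specs <- neuronSpecs(c("a", "b"), pattern_class = "NRM", base_rate = 8)
  expect_error(sampleCoupledPopulation(
    specs, connectionSpecs("a", "a", strength = 2), list(),
    fx$schedule, fx$sc$cycles, seed = 1), "self-connection")
  # reciprocal excitation: event-walk fallback still yields the mutual
  # short-lag excess
  conn <- connectionSpecs(c("a", "b"), c("b", "a"), latency = 0.001,
                          kernel_width = 0.002, strength = c(2.5, 2.5))
  tr <- sampleCoupledPopulation(specs, conn, list(), fx$schedule,
                                fx$sc$cycles, seed = 4)
  co <- computeCorrelogram(tr$a, tr$b)
  n <- length(co@lags)
  mid <- (n + 1) / 2
  near <- co@counts[c(mid + 3:6, mid - (3:6))]   # lags +-1.5..3 ms
  far <- co@counts[c(1:20, (n - 19):n)]
  expect_gt(mean(near), 1.5 * mean(far))
})

test_that("phrenic and blood-pressure generation follow the schedule", {
  sched <- hypoxiaSchedule(control = 30, augmentation = 0, apneusis = 0,
                           apnea = 20, gasping = 25, recovery = 0)
  sc <- scheduleCycles(sched, seed = 6)
  sig <- genPhrenicAndBp(sched, sc$cycles, sc$gasp_times, fs = 500,
                         seed = 6)
  phr <- signalSamples(sig$phrenic)
  tt <- signalTimes(sig$phrenic)
  nCtl <- nrow(sc$cycles)
  # control: one burst per cycle, peaks within noise of each other
  peaks <- vapply(seq_len(nCtl), function(k)
    max(phr[tt >= sc$cycles$i_onset[k] & tt < sc$cycles$cycle_end[k]]),
    numeric(1))
  expect_lt(stats::sd(peaks) / mean(peaks), 0.15)
  # apnea: baseline only
  apn <- phr[tt >= 31 & tt < 49]
  expect_lt(max(apn), 0.3 * mean(peaks))
  # gasps coincide with blood-pressure steps
  expect_gte(length(sc$gasp_times), 3)
  expect_identical(sig$bp_step_times, sc$gasp_times)
  bp <- signalSamples(sig$bp)
  for (tg in sc$gasp_times) {
    pre <- median(bp[tt >= tg - 1.5 & tt < tg - 0.2])
    post <- median(bp[tt >= tg + 0.2 & tt < tg + 1.5])
    expect_gt(post - pre, 4)
  }
})

test_that("genSession composes a valid session with ground truth", {
  gs <- scenarioFixture(7)
  expect_identical(validateSession(gs$session), character(0))
  expect_equal(controlWindow(gs$session), c(0, 300))
  expect_equal(nrow(gs$truth@connections), 12)
  expect_length(sessionTrains(gs$session), 20)
  expect_error(genSession(list(schedule = hypoxiaSchedule(control = 0)),
                          seed = 1), "control epoch")
  # no connections -> empty truth connection table
  scn <- hypoxiaScenario(n_neurons = 3, n_connections = 0)
  gs0 <- genSession(scn, seed = 2)
  expect_equal(nrow(gs0$truth@connections), 0)
  # same config, different seed: same topology, different spikes
  gs2 <- genSession(hypoxiaScenario(n_neurons = 3, n_connections = 0),
                    seed = 3)
  expect_identical(gs0$truth@connections, gs2$truth@connections)
  expect_false(identical(spikeTimes(sessionTrains(gs0$session)[[1]]),
                         spikeTimes(sessionTrains(gs2$session)[[1]])))
})

test_that("scenario files round-trip through YAML", {
  d <- withr::local_tempdir()
  scn <- hypoxiaScenario(n_neurons = 4, n_connections = 2)
  p <- file.path(d, "scen.yaml")
  writeScenario(scn, p)
  back <- readScenario(p)
  expect_equal(back$neurons$pattern_class, scn$neurons$pattern_class)
  expect_equal(back$connections$strength, scn$connections$strength)
  expect_equal(back$schedule$class, scn$schedule$class)
})
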