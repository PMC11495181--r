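test_that("threshold crossing finds a square burst and tolerates flat signals", {
  fs <- 500
  x <- rep(0, 3 * fs)
  x[(1 * fs):(2 * fs)] <- 1                   # one square burst on [1, 2] s
  cyc <- detectCycles(continuousSignal("phrenic_integrated", x, fs),
                      control_window = c(0, 3))
  bursts <- attr(cyc, "bursts")
  expect_equal(nrow(bursts), 1)
  expect_equal(bursts$i_onset, 1, tolerance = 0.06)
  expect_equal(bursts$e_onset, 2, tolerance = 0.06)

  flat <- detectCycles(continuousSignal("phrenic_integrated",
                                        rep(0, 1000), fs), c(0, 2))
  expect_equal(nrow(flat), 0)
  expect_match(attr(flat, "warning"), "flat")
})

test_that("cycle boundaries on control breathing are within 50 ms of truth", {
  fx <- controlCyclesFixture(duration = 120, seed = 11)
  sig <- genPhrenicAndBp(fx$schedule, fx$sc$cycles, fs = 1000, seed = 11)
  cyc <- detectCycles(sig$phrenic, c(0, 120))
  tcyc <- fx$sc$cycles[2:(nrow(fx$sc$cycles) - 1), ]  # interior cycles
  iErr <- vapply(tcyc$i_onset, function(x) min(abs(cyc$i_onset - x)),
                 numeric(1))
  eErr <- vapply(tcyc$e_onset, function(x) min(abs(cyc$e_onset - x)),
                 numeric(1))
  expect_lt(max(iErr), 0.05)
  expect_lt(max(eErr), 0.05)
})

test_that("the scripted hypoxia sequence is recovered class by class", {
  gs <- scenarioFixture(7)
  tru <- gs$truth
  phr <- sessionSignals(gs$session)$phrenic_integrated
  cyc <- detectCycles(phr, controlWindow(gs$session))
  seg <- classifyEpochs(phr, cyc, controlWindow(gs$session))

  expect_identical(seg$epochs$class, tru@schedule$class)
  # boundaries within one local cycle of the scheduled transition
  localCycle <- c(2.5, 2.5, 2, 4, 5, 5)
  for (k in 2:nrow(seg$epochs))
    expect_lt(abs(seg$epochs$t0[k] - tru@schedule$t0[k]), localCycle[k])
  # epochs tile the window without overlap
  expect_true(all(diff(as.vector(rbind(seg$epochs$t0, seg$epochs$t1))) >= 0))
  expect_equal(seg$epochs$t1[-nrow(seg$epochs)], seg$epochs$t0[-1])

  # three scheduled sighs recovered within 200 ms
  sighs <- seg$events[seg$events$kind == "sigh", ]
  expect_equal(nrow(sighs), length(tru@sighTimes))
  expect_lt(max(abs(sort(sighs$time) - sort(tru@sighTimes))), 0.2)

  # every true gasp recovered within 100 ms of onset; no extras
  gasps <- seg$events[seg$events$kind == "gasp", ]
  expect_equal(nrow(gasps), length(tru@gaspTimes))
  expect_lt(max(abs(sort(gasps$time) - sort(tru@gaspTimes))), 0.1)
  # sighs (augmented bursts, peak late in inspiration) are never gasps
  expect_false(any(abs(outer(sighs$time, gasps$time, "-")) < 1))
})

test_that("control-only records yield no gasp events", {
  for (s in 1:3) {
    fx <- controlCyclesFixture(duration = 150, seed = 20 + s)
    sig <- genPhrenicAndBp(fx$schedule, fx$sc$cycles, fs = 500,
                           seed = 20 + s)
    cyc <- detectCycles(sig$phrenic, c(0, 150))
    seg <- classifyEpochs(sig$phrenic, cyc, c(0, 150))
    expect_equal(sum(seg$events$kind == "gasp"), 0)
    expect_identical(unique(seg$epochs$class), "control")
  }
})

test_that("control windows with too few cycles are a precondition error", {
  fx <- controlCyclesFixture(duration = 120, seed = 11)
  sig <- genPhrenicAndBp(fx$schedule, fx$sc$cycles, fs = 500, seed = 11)
  cyc <- detectCycles(sig$phrenic, c(0, 120))
  expect_error(classifyEpochs(sig$phrenic, cyc, c(0, 12)),
               "fewer than 10 cycles")
})

test_that("epoch classes are robust to small added noise", {
  gs <- scenarioFixture(7)
  phr <- sessionSignals(gs$session)$phrenic_integrated
  base <- classifyEpochs(phr, detectCycles(phr, c(0, 300)), c(0, 300))
  noisy <- withr::with_seed(1, continuousSignal(
    "phrenic_integrated",
    signalSamples(phr) + rnorm(length(signalSamples(phr)), 0, 0.05 * 1.0),
    samplingRate(phr), 0))
  segN <- classifyEpochs(noisy, detectCycles(noisy, c(0, 300)), c(0, 300))
  expect_identical(segN$epochs$class, base$epochs$class)
})

test_that("blood-pressure steps coincide with gasps and synchrony is typed", {
  gs <- scenarioFixture(7)
  tru <- gs$truth
  ses <- gs$session
  phr <- sessionSignals(ses)$phrenic_integrated
  cyc <- detectCycles(phr, controlWindow(ses))
  seg <- classifyEpochs(phr, cyc, controlWindow(ses))
  gasps <- seg$events[seg$events$kind == "gasp", ]
  ctl <- cyc[cyc$i_onset >= 0 & cyc$cycle_end <= 300, ]
  cls <- classifyAllNeurons(ses, ctl, analysisConfig(cth_n_shuffles = 200))
  bp <- detectBpStepsAndSync(sessionSignals(ses)$blood_pressure, gasps,
                             sessionTrains(ses), cls$classes)
  expect_equal(bp$coincidence_count, length(tru@gaspTimes))
  sync <- bp$sync_table
  participants <- tru@neurons$neuron_id[tru@neurons$gasp_participating]
  nonparticipants <- setdiff(tru@neurons$neuron_id, participants)
  # no neuron that is silent around gasps is called synchronous
  expect_length(intersect(sync$neuron_id, nonparticipants), 0)
  # most injected participants are recovered
  expect_gte(length(intersect(sync$neuron_id, participants)),
             0.7 * length(participants))
  # the control-silent (gasp-only) cell is synchronous and typed NRM
  expect_true("N19" %in% sync$neuron_id)
  expect_equal(sync$control_class[sync$neuron_id == "N19"],
               "not respiratory-modulated")
})
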