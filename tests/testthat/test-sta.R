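test_that("a constant signal averages to zero after rectification", {
  sig <- continuousSignal("other", rep(4.2, 5000), fs = 500)
  tr <- spikeTrain("t", seq(1, 9, by = 0.5), c(0, 10))
  sta <- spikeTriggeredAverage(sig, tr, window = 0.05)
  expect_true(all(sta@meanTrace == 0))
  expect_equal(sta@nTriggers + sta@nExcluded, length(spikeTimes(tr)))
})

test_that("a spike-locked pulse appears at its exact lag and amplitude", {
  fs <- 1000
  tr <- poissonTrain("t", 8, 120, seed = 3)
  base <- continuousSignal("other", rep(0, 120 * fs), fs)
  sig <- injectSpikeLocked(base, tr, latency = 0.003, width = 0.002,
                           amplitude = 10)
  sta <- spikeTriggeredAverage(sig, tr, window = 0.05, rectify = FALSE)
  at3 <- sta@meanTrace[abs(sta@lags - 0.004) < 1e-9]
  expect_gt(at3, 9)                            # ~10 up to pulse overlap
  expect_lt(max(sta@meanTrace[sta@lags < 0]), 2)
})

test_that("triggers without full window coverage are excluded and counted", {
  sig <- continuousSignal("other", rnorm(1000), fs = 100)  # covers [0, 10)
  tr <- spikeTrain("t", c(0.02, 5, 9.98), c(0, 10))
  sta <- spikeTriggeredAverage(sig, tr, window = 0.5)
  expect_equal(sta@nTriggers, 1L)
  expect_equal(sta@nExcluded, 2L)
  expect_error(spikeTriggeredAverage(sig, spikeTrain("t", 0.01, c(0, 10)),
                                     window = 0.5),
               "no trigger")
})

test_that("the average is linear in the signal when rectification is off", {
  withr::local_seed(4)
  fs <- 200
  a <- rnorm(fs * 30); b <- rnorm(fs * 30)
  tr <- poissonTrain("t", 5, 30, seed = 5)
  staA <- spikeTriggeredAverage(continuousSignal("other", a, fs), tr,
                                0.1, rectify = FALSE)
  staB <- spikeTriggeredAverage(continuousSignal("other", b, fs), tr,
                                0.1, rectify = FALSE)
  staAB <- spikeTriggeredAverage(continuousSignal("other", a + b, fs), tr,
                                 0.1, rectify = FALSE)
  expect_equal(staAB@meanTrace, staA@meanTrace + staB@meanTrace,
               tolerance = 1e-12)
})

test_that("premotor and inhibitory relationships are flagged from STAs", {
  fs <- 1000
  tr <- poissonTrain("v", 10, 200, seed = 6)
  base <- withr::with_seed(7, continuousSignal(
    "phrenic_integrated", rnorm(200 * fs, 5, 0.4), fs))
  cfg <- analysisConfig(rng_seed = 8)

  prem <- injectSpikeLocked(base, tr, latency = 0.004, width = 0.005,
                            amplitude = 2)
  sta <- detectStaFeatures(spikeTriggeredAverage(prem, tr, 0.1), prem, tr,
                           cfg, n_surrogates = 100)
  expect_true(any(corrFeatures(sta)$premotor))

  inh <- injectSpikeLocked(base, tr, latency = 0.004, width = 0.005,
                           amplitude = -2)
  # suppression of a signal riding near its median would be folded by
  # rectification in this synthetic fixture, so average the raw trace
  sta2 <- detectStaFeatures(spikeTriggeredAverage(inh, tr, 0.1,
                                                  rectify = FALSE),
                            inh, tr, cfg, n_surrogates = 100,
                            rectify = FALSE)
  expect_true(any(corrFeatures(sta2)$inhibitory))

  # null control: triggers independent of the signal are rarely flagged
  flags <- vapply(1:20, function(r) {
    tr0 <- poissonTrain("n", 10, 200, seed = 100 + r)
    s <- detectStaFeatures(spikeTriggeredAverage(base, tr0, 0.1), base,
                           tr0, cfg, n_surrogates = 100, seed = 200 + r)
    any(corrFeatures(s)$significant)
  }, logical(1))
  expect_lte(sum(flags), 3)
})
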