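test_that("phase mapping concentrates onset-locked spikes in bin 0", {
  cyc <- data.frame(i_onset = c(0, 2, 4), e_onset = c(1, 3, 5),
                    cycle_end = c(2, 4, 6))
  tr <- spikeTrain("x", c(0, 2, 4) + 1e-9, c(0, 6))
  cth <- computeCth(tr, cyc, bins_per_phase = 10)
  expect_equal(which(cth@rate > 0), 1L)
  expect_equal(max(cth@scaledRate), 1)
  expect_equal(cth@nCycles, 3L)
})

test_that("bin rates equal hand-computed values on a 3-cycle fixture", {
  # cycles with I = 1 s, E = 3 s; one spike exactly mid-expiration each
  # cycle maps to phase 0.75; that bin's rate = count / summed bin time
  cyc <- data.frame(i_onset = c(0, 4, 8), e_onset = c(1, 5, 9),
                    cycle_end = c(4, 8, 12))
  tr <- spikeTrain("x", c(2.5, 6.5, 10.5), c(0, 12))
  B <- 10L
  cth <- computeCth(tr, cyc, B)
  binIdx <- floor(0.75 * 2 * B) + 1L          # phase 0.75
  expect_equal(which(cth@rate > 0), binIdx)
  expect_equal(cth@rate[binIdx], 3 / (3 * 3 / B))  # 3 spikes / 0.9 s
  expect_error(computeCth(tr, cyc[0, ], B), "no cycles")
})

test_that("a homogeneous train gives flat per-bin rates", {
  fx <- controlCyclesFixture()
  tr <- poissonTrain("p", 20, 250, seed = 8)
  cth <- computeCth(tr, fx$sc$cycles, 25)
  spans <- gaspnet:::binTimeSpans(fx$sc$cycles, 25L)
  sdRate <- sqrt(20 / spans)                  # Poisson sd of a bin rate
  expect_true(all(abs(cth@rate - 20) < 4 * sdRate))
})

test_that("modulation tests reject strong modulation and honour edge cases", {
  fx <- controlCyclesFixture()
  cfg <- analysisConfig(cth_n_shuffles = 200)
  tr <- sampleCoupledPopulation(
    neuronSpecs("m", pattern_class = "I-Aug", base_rate = 10, depth = 1,
                phasic = TRUE),
    NULL, list(), fx$schedule, fx$sc$cycles, seed = 2)$m
  tm <- testModulation(tr, fx$sc$cycles, cfg)
  expect_true(tm$modulated)
  expect_lt(tm$p_testA, 1e-6)
  expect_equal(tm$p_testB, 1 / 201)           # minimum attainable

  expect_error(testModulation(tr, fx$sc$cycles[1, ], cfg), "at least 2")
})

test_that("pattern classification follows the peak-half rules", {
  mkcth <- function(rate) {
    new("CycleTriggeredHistogram", neuronId = "x", binsPerPhase = 25L,
        phase = (seq_len(50) - 0.5) / 50, rate = rate,
        scaledRate = if (any(rate > 0)) rate / max(rate) else rate,
        nCycles = 30L)
  }
  r <- rep(1, 50); r[5] <- 30                 # peak at phase 0.09
  cth <- classifyPattern(mkcth(r), modulated = TRUE)
  expect_equal(cth@modulation, "I"); expect_equal(cth@subtype, "Dec")

  r <- rep(1, 50); r[20] <- 30                # peak at phase 0.39
  cth <- classifyPattern(mkcth(r), modulated = TRUE)
  expect_equal(cth@modulation, "I"); expect_equal(cth@subtype, "Aug")

  r <- rep(1, 50); r[30] <- 30                # first half of expiration
  cth <- classifyPattern(mkcth(r), modulated = TRUE)
  expect_equal(cth@modulation, "E"); expect_equal(cth@subtype, "Dec")

  # uniform, tests non-rejecting: NRM and tonic (no silent bin)
  cth <- classifyPattern(mkcth(rep(8, 50)), modulated = FALSE)
  expect_equal(cth@modulation, "NRM")
  expect_equal(cth@tonicity, "tonic")

  # all-zero CTH: NRM with zero-rate flag
  cth <- classifyPattern(mkcth(rep(0, 50)), modulated = FALSE)
  expect_true(as.character(cth@modulation) == "NRM")
  expect_true(isTRUE(attr(cth@modulation, "zero_rate")))

  # scaled rate is invariant to multiplying all rates by a constant
  a <- classifyPattern(mkcth(r), TRUE)
  b <- classifyPattern(mkcth(r * 7.3), TRUE)
  expect_equal(a@scaledRate, b@scaledRate)
  expect_equal(a@subtype, b@subtype)
})

test_that("generated classes are recovered from control CTHs", {
  # compact version of the classification-recovery benchmark (the full
  # 200-neuron run lives in the acceptance suite)
  fx <- controlCyclesFixture()
  cfg <- analysisConfig(cth_n_shuffles = 200)
  cases <- expand.grid(cls = c("I-Aug", "I-Dec", "E-Aug", "E-Dec"),
                       phasic = c(TRUE, FALSE),
                       stringsAsFactors = FALSE)
  ok <- 0L
  for (i in seq_len(nrow(cases))) {
    tr <- sampleCoupledPopulation(
      neuronSpecs("x", pattern_class = cases$cls[i], base_rate = 10,
                  depth = 0.8, phasic = cases$phasic[i]),
      NULL, list(), fx$schedule, fx$sc$cycles, seed = 300 + i)$x
    cth <- computeCth(tr, fx$sc$cycles, 25)
    tm <- testModulation(tr, fx$sc$cycles, cfg)
    cth <- classifyPattern(cth, tm$modulated, tm$p_testA, tm$p_testB)
    want <- strsplit(cases$cls[i], "-")[[1]]
    if (cth@modulation == want[1] && cth@subtype == want[2] &&
        cth@tonicity == ifelse(cases$phasic[i], "phasic", "tonic"))
      ok <- ok + 1L
  }
  expect_equal(ok, nrow(cases))
})
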