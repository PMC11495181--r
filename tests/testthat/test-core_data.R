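test_that("SpikeTrain invariants are enforced with informative messages", {
  expect_s4_class(spikeTrain("n1", c(0.1, 0.2), c(0, 1)), "SpikeTrain")
  expect_error(spikeTrain("n1", c(0.2, 0.1), c(0, 1)),
               "times not increasing for n1")
  # half-open interval: a spike exactly at t1 is invalid
  expect_error(spikeTrain("n1", c(0.5, 1.0), c(0, 1)), "outside interval")
  expect_error(spikeTrain("n1", 0.5, c(1, 0)), "t0 < t1")
  expect_error(continuousSignal("other", c(1, NA), fs = 100),
               "non-finite")
  expect_error(continuousSignal("other", 1:5, fs = -1), "positive")
})

test_that("readSession parses spike tables and rejects violations by name", {
  d <- withr::local_tempdir()
  sp <- file.path(d, "spikes.csv")
  writeLines(c("neuron_id,time_s", "n1,0.1", "n1,0.2", "n2,0.15"), sp)
  ses <- readSession(sp)
  expect_length(sessionTrains(ses), 2L)
  expect_equal(spikeTimes(sessionTrains(ses)$n1), c(0.1, 0.2))
  expect_length(spikeTimes(sessionTrains(ses)$n2), 1L)

  writeLines(c("neuron_id,time_s", "n1,0.2", "n1,0.1"), sp)
  expect_error(readSession(sp), "times not increasing for n1")

  writeLines("neuron_id,time_s", sp)
  expect_length(sessionTrains(readSession(sp)), 0L)

  sig <- file.path(d, "phrenic_integrated.signal.csv")
  writeLines(c("value", "1", "2"), sig)  # header line missing fs
  expect_error(readSession(sp, sig), "missing fs")
})

test_that("write/read round-trips random sessions exactly and deterministically", {
  d <- withr::local_tempdir()
  withr::local_seed(42)
  for (i in 1:30) {
    n <- sample(1:4, 1)
    trains <- lapply(seq_len(n), function(k)
      spikeTrain(paste0("n", k),
                 sort(runif(sample(0:20, 1), 0, 10)) + k * 1e-4,
                 c(0, 10.01), sample(c("VRC", "raphe", "pons"), 1)))
    sig <- continuousSignal("phrenic_integrated", rnorm(50), fs = 1000,
                            start = 0)
    ses <- newSession(trains, list(sig), controlWindow = c(0, 10),
                      metadata = list(animal = paste0("a", i)))
    out <- file.path(d, paste0("s", i))
    writeSession(ses, out)
    back <- readSession(file.path(out, "spikes.csv"),
                        file.path(out, "phrenic_integrated.signal.csv"),
                        file.path(out, "session.json"),
                        file.path(out, "neurons.csv"))
    expect_identical(lapply(sessionTrains(ses), spikeTimes),
                     lapply(sessionTrains(back), spikeTimes))
    expect_identical(vapply(sessionTrains(ses), region, character(1)),
                     vapply(sessionTrains(back), region, character(1)))
    expect_identical(signalSamples(sessionSignals(back)[[1]]),
                     signalSamples(sig))
    expect_equal(samplingRate(sessionSignals(back)[[1]]), 1000)
    expect_equal(controlWindow(back), c(0, 10))
  }
  # byte-identical rewrite of identical content
  ses <- newSession(list(spikeTrain("a", c(0.5, exp(1)), c(0, 3))))
  writeSession(ses, file.path(d, "w1"))
  writeSession(ses, file.path(d, "w2"))
  expect_identical(readLines(file.path(d, "w1", "spikes.csv")),
                   readLines(file.path(d, "w2", "spikes.csv")))
})

test_that("validateSession reports (never raises) and is pure", {
  tr <- spikeTrain("a", c(0.2, 0.4), c(0, 1))
  ses <- newSession(list(tr), controlWindow = c(0, 1))
  expect_identical(validateSession(ses), character(0))

  bad <- ses
  bad@trains$a@times <- c(0.2, 2)            # spike beyond interval end
  rep1 <- validateSession(bad)
  expect_match(rep1, "outside interval", all = FALSE)
  expect_identical(rep1, validateSession(bad))

  dup <- ses
  dup@trains <- list(a = tr, a2 = spikeTrain("a", 0.3, c(0, 1)))
  expect_match(validateSession(dup), "neuron_id not unique", all = FALSE)

  wide <- ses
  wide@controlWindow <- c(0, 5)              # beyond the train interval
  expect_match(validateSession(wide), "control window", all = FALSE)
})

test_that("analysisConfig validates its fields", {
  cfg <- analysisConfig()
  expect_equal(cfg$di_threshold, 3.0)
  expect_equal(cfg$fdr_q, 0.05)
  expect_equal(cfg$alpha_cth, 0.05)
  expect_error(analysisConfig(alpha_cth = 1.5))
  expect_error(analysisConfig(k_on = 0.1, k_off = 0.2))
  expect_error(analysisConfig(corr_bin_width = 0))
})
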