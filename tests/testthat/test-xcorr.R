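test_that("a pure shift puts all counts in one bin", {
  t <- sort(runif(200, 1, 99))
  ref <- spikeTrain("r", t, c(0, 100))
  tgt <- spikeTrain("t", t + 0.005, c(0, 100))
  co <- computeCorrelogram(ref, tgt, bin_width = 0.001, window = 0.02)
  hot <- which(co@counts > 0 & abs(co@lags - 0.005) < 1e-9)
  expect_length(hot, 1L)
  expect_equal(co@counts[hot], 200L)
  expect_equal(co@rate[hot], 200 / (200 * 0.001))
})

test_that("two single-spike trains give one count at the exact lag", {
  a <- spikeTrain("a", 1.0, c(0, 2))
  b <- spikeTrain("b", 1.002, c(0, 2))
  co <- computeCorrelogram(a, b)
  expect_equal(sum(co@counts), 1L)
  expect_equal(co@lags[co@counts == 1L], 0.002)
  expect_error(computeCorrelogram(spikeTrain("e", numeric(0), c(0, 1)), b),
               "empty reference train: e")
})

test_that("counts match the brute-force oracle exactly on small trains", {
  withr::local_seed(5)
  for (i in 1:25) {
    na <- sample(2:100, 1); nb <- sample(2:100, 1)
    a <- spikeTrain("a", sort(runif(na, 0, 20)), c(0, 20))
    b <- spikeTrain("b", sort(runif(nb, 0, 20)), c(0, 20))
    co <- computeCorrelogram(a, b, bin_width = 0.01, window = 0.2)
    expect_identical(co@counts,
                     bruteCorrCounts(spikeTimes(a), spikeTimes(b),
                                     0.01, 20L))
  }
})

test_that("correlograms are symmetric under swapping reference and target", {
  a <- poissonTrain("a", 15, 120, seed = 6)
  b <- poissonTrain("b", 12, 120, seed = 7)
  ab <- computeCorrelogram(a, b)
  ba <- computeCorrelogram(b, a)
  expect_identical(ab@counts, rev(ba@counts))
})

test_that("an independent Poisson pair is flat at the analytic level", {
  a <- poissonTrain("a", 10, 600, seed = 8)
  b <- poissonTrain("b", 10, 600, seed = 9)
  co <- computeCorrelogram(a, b, 0.001, 0.02)
  expected <- length(spikeTimes(a)) * 10 * 0.001
  expect_true(all(abs(co@counts - expected) < 4 * sqrt(expected)))
})

test_that("gamma shape estimation honours the stated behaviours", {
  tr <- poissonTrain("p", 20, 300, seed = 10)
  fit <- fitGammaSurrogates(tr)
  expect_equal(fit$shape, 1, tolerance = 0.1)     # exponential ISIs

  reg <- spikeTrain("r", seq(0.1, 99.9, by = 0.1), c(0, 100))
  expect_equal(fitGammaSurrogates(reg)$shape, 100) # clipped

  isi <- withr::with_seed(11, rgamma(5000, shape = 4, scale = 0.025))
  tr4 <- spikeTrain("g", cumsum(isi), c(0, sum(isi) + 1))
  expect_gt(fitGammaSurrogates(tr4)$shape, 3.6)
  expect_lt(fitGammaSurrogates(tr4)$shape, 4.4)

  expect_error(fitGammaSurrogates(spikeTrain("s", 1, c(0, 2))),
               "at least 2 spikes")
  expect_warning(fitGammaSurrogates(spikeTrain("w", c(1, 2, 3), c(0, 5))),
                 "fewer than 50")
})

test_that("surrogates preserve the mean rate within 5%", {
  tr <- poissonTrain("p", 10, 300, seed = 12)
  fit <- suppressWarnings(fitGammaSurrogates(tr, n_surrogates = 100,
                                             seed = 13))
  rates <- vapply(fit$surrogates, function(s)
    length(s) / (300 - spikeTimes(tr)[1]), numeric(1))
  expect_lt(abs(mean(rates) - 10) / 10, 0.05)
  # reproducibility
  fit2 <- suppressWarnings(fitGammaSurrogates(tr, 100, seed = 13))
  expect_identical(fit$surrogates, fit2$surrogates)
})

test_that("an injected excitatory connection yields a significant offset peak", {
  fx <- controlCyclesFixture(duration = 600, seed = 42)
  specs <- neuronSpecs(c("a", "b"), pattern_class = "NRM", base_rate = 10)
  conn <- connectionSpecs("a", "b", latency = 0.001, kernel_width = 0.002,
                          strength = 3)
  tr <- sampleCoupledPopulation(specs, conn, list(), fx$schedule,
                                fx$sc$cycles, seed = 42)
  cfg <- analysisConfig(n_surrogates = 200, rng_seed = 42)
  co <- detectFeatures(computeCorrelogram(tr$a, tr$b), tr$a, tr$b, cfg)
  fe <- corrFeatures(co)
  pk <- fe[fe$kind == "peak" & fe$position == "offset", ]
  expect_gte(nrow(pk), 1)
  expect_gt(pk$extremum_lag[1], 0)
  expect_lte(pk$extremum_lag[1], 0.004)
  expect_gte(pk$di[1], 3)
  expect_true(pk$significant[1])
})

test_that("a shared latent drive yields a central feature spanning lag zero", {
  fx <- controlCyclesFixture(duration = 600, seed = 21)
  specs <- neuronSpecs(c("a", "b"), pattern_class = "NRM", base_rate = 10)
  tr <- sampleCoupledPopulation(specs, NULL,
                                list(commonDriveSpec(c("a", "b"))),
                                fx$schedule, fx$sc$cycles, seed = 21)
  cfg <- analysisConfig(n_surrogates = 200, rng_seed = 21)
  co <- detectFeatures(computeCorrelogram(tr$a, tr$b), tr$a, tr$b, cfg)
  fe <- corrFeatures(co)
  ce <- fe[fe$position == "central" & fe$kind == "peak", ]
  expect_gte(nrow(ce), 1)
  expect_lte(ce$lag_lo[1], 0)
  expect_gte(ce$lag_hi[1], 0)
})

test_that("detectability index grows with injected strength", {
  fx <- controlCyclesFixture(duration = 300, seed = 30)
  cfg <- analysisConfig(n_surrogates = 100, rng_seed = 30)
  medDi <- vapply(c(1.5, 2, 3), function(s) {
    di <- vapply(1:12, function(r) {
      tr <- sampleCoupledPopulation(
        neuronSpecs(c("a", "b"), pattern_class = "NRM", base_rate = 10),
        connectionSpecs("a", "b", latency = 0.001, kernel_width = 0.002,
                        strength = s),
        list(), fx$schedule, fx$sc$cycles, seed = 1000 * s + r)
      co <- detectFeatures(computeCorrelogram(tr$a, tr$b), tr$a, tr$b,
                           cfg, seed = 500 + r)
      fe <- corrFeatures(co)
      pk <- fe[fe$kind == "peak" & fe$position == "offset" &
                 fe$extremum_lag <= 0.004, ]
      if (nrow(pk)) max(pk$di) else 0
    }, numeric(1))
    median(di)
  }, numeric(1))
  expect_true(all(diff(medDi) >= 0))
})

test_that("screenPairs needs two usable trains and reports skips", {
  one <- newSession(list(poissonTrain("a", 10, 60, seed = 1)))
  out <- screenPairs(one, analysisConfig(n_surrogates = 100))
  expect_equal(nrow(out$edges), 0)
  expect_equal(out$n_assessed, 0)

  two <- newSession(list(poissonTrain("a", 10, 60, seed = 1),
                         spikeTrain("b", 1, c(0, 60))))
  out2 <- screenPairs(two, analysisConfig(n_surrogates = 100))
  expect_equal(out2$n_assessed, 0)
  expect_match(out2$skipped$reason, "unusable", all = FALSE)
})
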