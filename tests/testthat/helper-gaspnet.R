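# Shared fixtures, built in code.

# Homogeneous Poisson train on [0, T).
poissonTrain <- function(id, rate, T, seed = NULL, region = "other") {
  gen <- function() {
    t <- cumsum(stats::rexp(ceiling(rate * T * 1.4) + 20, rate))
    spikeTrain(id, t[t < T], c(0, T), region)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Control-only schedule and cycles, cached per (duration, seed).
.ctl_cache <- new.env(parent = emptyenv())
controlCyclesFixture <- function(duration = 250, seed = 3) {
  key <- paste0("d", duration, "s", seed)
  if (is.null(.ctl_cache[[key]])) {
    sched <- hypoxiaSchedule(control = duration, augmentation = 0,
                             apneusis = 0, apnea = 0, gasping = 0,
                             recovery = 0)
    .ctl_cache[[key]] <- list(schedule = sched,
                              sc = scheduleCycles(sched, seed = seed))
  }
  .ctl_cache[[key]]
}

# One default-scenario session per seed, cached (generation ~10 s).
.scen_cache <- new.env(parent = emptyenv())
scenarioFixture <- function(seed = 7) {
  key <- paste0("s", seed)
  if (is.null(.scen_cache[[key]]))
    .scen_cache[[key]] <- genSession(hypoxiaScenario(), seed = seed)
  .scen_cache[[key]]
}

# Brute-force correlogram oracle: exhaustive pair enumeration.
bruteCorrCounts <- function(ref, tgt, bin, nhalf) {
  lags <- as.vector(outer(tgt, ref, "-"))
  idx <- floor(lags / bin + 0.5)
  idx <- idx[idx >= -nhalf & idx <= nhalf]
  tabulate(idx + nhalf + 1L, nbins = 2L * nhalf + 1L)
}

# Unordered pair key.
pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
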