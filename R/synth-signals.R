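#' Generate integrated phrenic and arterial blood-pressure signals
#'
#' The phrenic envelope is a per-cycle inspiratory burst (a sharp onset
#' followed by an augmenting ramp, decaying rapidly at expiratory onset),
#' scaled by each epoch's amplitude gain; sigh cycles carry an extra
#' late-inspiratory bump; apnea epochs emit baseline only; gasps are
#' short decrementing bursts (instant rise, exponential decay). Blood
#' pressure is a baseline plus slow drift and noise, with an additive
#' step of `bp_step_height` mmHg at each true gasp time that relaxes
#' slowly (time constant `bp_step_tau`), emulating the steplike pressure
#' increments coincident with gasp bursts.
#'
#' @param schedule [hypoxiaSchedule()] data.frame.
#' @param cycles,gasp_times from [scheduleCycles()].
#' @param fs sampling rate (Hz), at least 100.
#' @param seed integer seed.
#' @param amp control burst amplitude (arbitrary integrated-phrenic
#'   units).
#' @param noise_sd additive noise sd as a fraction of `amp`.
#' @param bp_baseline,bp_step_height,bp_step_tau blood-pressure baseline,
#'   per-gasp step height (mmHg) and relaxation time constant (s).
#' @param sigh_gain extra late-inspiratory amplitude factor on sigh
#'   cycles.
#' @return list with `phrenic` and `bp` ([ContinuousSignal-class]),
#'   plus `bp_step_times` (equal to the gasp times).
#' @export
genPhrenicAndBp <- function(schedule, cycles, gasp_times = numeric(0),
                            fs = 1000, seed = 1L, amp = 1,
                            noise_sd = 0.02, bp_baseline = 100,
                            bp_step_height = 8, bp_step_tau = 30,
                            sigh_gain = 1.8) {
  stopifnot(fs >= 100)
  t0 <- min(schedule$t0)
  t1 <- max(schedule$t1)
  t <- seq(t0, t1 - 1 / fs, by = 1 / fs)
  env <- rep(0, length(t))

  gain <- stats::setNames(schedule$amp_gain, schedule$class)
  for (k in seq_len(nrow(cycles))) {
    cy <- cycles[k, ]
    a <- amp * gain[[cy$epoch]]
    iIdx <- which(t >= cy$i_onset & t < cy$e_onset)
    u <- (t[iIdx] - cy$i_onset) / (cy$e_onset - cy$i_onset)
    burst <- a * (0.3 + 0.7 * u^1.5)          # abrupt onset, augmenting ramp
    if (isTRUE(cy$sigh))
      burst <- burst * (1 + (sigh_gain - 1) * exp(-((u - 0.92) / 0.06)^2))
    env[iIdx] <- burst
    peak <- if (length(burst)) burst[length(burst)] else a
    eIdx <- which(t >= cy$e_onset & t < min(cy$e_onset + 0.15, cy$cycle_end))
    env[eIdx] <- peak * exp(-(t[eIdx] - cy$e_onset) / 0.01)
  }
  gd <- attr(schedule, "gasp_duration") %||% 0.4
  for (tg in gasp_times) {
    gIdx <- which(t >= tg & t < tg + gd)
    env[gIdx] <- pmax(env[gIdx], 1.3 * amp * exp(-(t[gIdx] - tg) / 0.1))
  }

  withSeed(streamSeed(seed, "signals"), {
    phr <- pmax(env + 0.02 * amp +
                  stats::rnorm(length(t), 0, noise_sd * amp), 0)
    steps <- rep(0, length(t))
    for (tg in gasp_times) {
      after <- t >= tg
      steps[after] <- steps[after] +
        bp_step_height * exp(-(t[after] - tg) / bp_step_tau)
    }
    bp <- bp_baseline + 1.5 * sin(2 * pi * t / 150) + steps +
      stats::rnorm(length(t), 0, 1)
    list(phrenic = continuousSignal("phrenic_integrated", phr, fs, t0),
         bp = continuousSignal("blood_pressure", bp, fs, t0),
         bp_step_times = gasp_times)
  })
}

#' Add a spike-locked component to a continuous signal
#'
#' Adds a pulse of the given amplitude and width at a fixed latency after
#' every trigger spike. Used to realize premotor-like (positive pulse) or
#' functionally inhibitory (negative pulse) relationships between a
#' neuron and a nerve signal for spike-triggered-average validation.
#'
#' @param signal a [ContinuousSignal-class].
#' @param train the trigger [SpikeTrain-class].
#' @param latency pulse onset lag after each spike (s).
#' @param width pulse duration (s).
#' @param amplitude pulse height (signal units; may be negative).
#' @return the modified [ContinuousSignal-class].
#' @export
injectSpikeLocked <- function(signal, train, latency = 0.004,
                              width = 0.005, amplitude = 1) {
  x <- signal@samples
  n <- length(x)
  w <- max(1L, round(width * signal@fs))
  for (s in train@times) {
    i0 <- round((s + latency - signal@start) * signal@fs) + 1L
    if (i0 < 1L || i0 > n) next
    idx <- i0:min(n, i0 + w - 1L)
    x[idx] <- x[idx] + amplitude
  }
  continuousSignal(signal@name, x, signal@fs, signal@start)
}
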