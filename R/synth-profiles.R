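#' Neuron specification table for the synthetic generator
#'
#' One row per neuron. `pattern_class` follows the field's taxonomy:
#' augmenting/decrementing inspiratory and expiratory cells (`I-Aug`,
#' `I-Dec`, `E-Aug`, `E-Dec`), post-inspiratory (`post-I`, realized as a
#' decrementing profile at expiratory onset), tonic inspiratory/expiratory
#' (`tonic-I`, `tonic-E`: modulated but never silent), non-respiratory-
#' modulated (`NRM`) and `gasp-only` (silent during control, bursting only
#' at gasps, as for cells recruited de novo during autoresuscitation).
#'
#' @param neuron_id character ids.
#' @param region regions (`VRC`, `raphe`, `pons`, `other`).
#' @param pattern_class one of the classes above.
#' @param base_rate mean firing rate in the preferred phase (spikes/s).
#' @param depth modulation depth in `[0, 1]`.
#' @param phasic logical; silent outside the preferred phase.
#' @param gasp_participating logical; bursts during gasps.
#' @param gasp_rate peak rate of the decrementing gasp burst (spikes/s).
#' @return data.frame of neuron specs.
#' @export
neuronSpecs <- function(neuron_id, region = "other",
                        pattern_class = "NRM", base_rate = 10,
                        depth = 0, phasic = FALSE,
                        gasp_participating = FALSE, gasp_rate = 200) {
  df <- data.frame(neuron_id = as.character(neuron_id),
                   region = region, pattern_class = pattern_class,
                   base_rate = base_rate, depth = depth, phasic = phasic,
                   gasp_participating = gasp_participating,
                   gasp_rate = gasp_rate, stringsAsFactors = FALSE)
  bad <- !df$pattern_class %in% PATTERN_CLASSES
  if (any(bad))
    stop("unknown pattern class: ",
         paste(unique(df$pattern_class[bad]), collapse = ", "))
  stopifnot(all(df$base_rate >= 0), all(df$depth >= 0 & df$depth <= 1))
  df
}

# Map a pattern class to (preferred phase, half-wave shape, phasic
# override). tonic-I / tonic-E are never phasic; post-I decrements from
# expiratory onset.
classShape <- function(cls) {
  switch(cls,
    "I-Aug" = list(phase = "I", shape = "aug"),
    "I-Dec" = list(phase = "I", shape = "dec"),
    "E-Aug" = list(phase = "E", shape = "aug"),
    "E-Dec" = list(phase = "E", shape = "dec"),
    "post-I" = list(phase = "E", shape = "dec"),
    "tonic-I" = list(phase = "I", shape = "dec", tonic = TRUE),
    "tonic-E" = list(phase = "E", shape = "dec", tonic = TRUE),
    "NRM" = list(phase = "none", shape = "flat"),
    "gasp-only" = list(phase = "gasp", shape = "flat"),
    stop("unknown pattern class: ", cls))
}

# Vectorized intensity (spikes/s) of one neuron spec at times `t`.
# Phase profiles are raised-cosine half-waves: augmenting sin^2(pi u / 2)
# rises from 0 at phase onset to its peak at phase end; decrementing is
# the mirror image. Within the preferred phase
#   lambda(u) = base (1 - depth) + 2 base depth g(u)
# (time-average base over the phase); outside it the rate is the tonic
# floor base (1 - depth), or zero for phasic cells. During apnea and
# gasping epochs all phase-locked terms are suppressed to the tonic
# floor; gasp-participating cells add a decrementing burst envelope
# (instant rise, exponential decay, time constant 100 ms) at each true
# gasp time.
evalRateProfile <- function(spec, t, cycles, schedule, gasp_times,
                            gasp_duration = 0.4) {
  cs <- classShape(spec$pattern_class)
  phasic <- isTRUE(spec$phasic) && is.null(cs$tonic)
  base <- spec$base_rate
  depth <- spec$depth
  floorRate <- base * (1 - depth)

  lam <- rep(if (cs$phase == "none") base
             else if (cs$phase == "gasp") 0
             else if (phasic) 0 else floorRate, length(t))

  if (cs$phase %in% c("I", "E") && nrow(cycles)) {
    ci <- findInterval(t, cycles$i_onset)
    ok <- ci >= 1L
    okIdx <- which(ok & t < cycles$cycle_end[pmax(ci, 1L)])
    if (length(okIdx)) {
      cc <- ci[okIdx]
      tt <- t[okIdx]
      inI <- tt < cycles$e_onset[cc]
      u <- ifelse(inI,
                  (tt - cycles$i_onset[cc]) /
                    (cycles$e_onset[cc] - cycles$i_onset[cc]),
                  (tt - cycles$e_onset[cc]) /
                    (cycles$cycle_end[cc] - cycles$e_onset[cc]))
      pref <- if (cs$phase == "I") inI else !inI
      g <- if (cs$shape == "aug") sin(pi * u / 2)^2 else cos(pi * u / 2)^2
      lam[okIdx] <- ifelse(pref, floorRate + 2 * base * depth * g,
                           if (phasic) 0 else floorRate)
    }
  }

  # apnea / gasping epochs: suppress phase-locked activity
  if (nrow(schedule)) {
    ei <- findInterval(t, schedule$t0)
    supp <- ei >= 1L & schedule$class[pmax(ei, 1L)] %in% c("apnea", "gasping")
    if (cs$phase %in% c("I", "E"))
      lam[supp] <- if (phasic) 0 else floorRate
  }

  if (isTRUE(spec$gasp_participating) && length(gasp_times)) {
    gi <- findInterval(t, gasp_times)
    hit <- gi >= 1L
    dt <- t - gasp_times[pmax(gi, 1L)]
    inG <- hit & dt >= 0 & dt < gasp_duration
    lam[inG] <- lam[inG] + spec$gasp_rate * exp(-dt[inG] / 0.1)
  }
  pmax(lam, 0)
}

#' Firing-rate profile of a synthetic neuron as a function of time
#'
#' Returns the nonnegative piecewise-smooth intensity function realized
#' for a neuron spec under a motor-pattern schedule: respiratory-phase-
#' locked raised-cosine half-waves (augmenting profiles peak in the second
#' half of their phase, decrementing in the first), a tonic floor or
#' silence outside the preferred phase, suppression of phase-locked terms
#' during apnea and gasping, and decrementing burst envelopes at gasp
#' times for gasp-participating cells.
#'
#' @param spec one row of [neuronSpecs()] (or a list with the same
#'   fields).
#' @param schedule a [hypoxiaSchedule()] data.frame.
#' @param cycles the true cycles data.frame from [scheduleCycles()].
#' @param gasp_times true gasp onset times (s).
#' @param gasp_duration gasp envelope duration (s).
#' @return `function(t)` evaluating the intensity (spikes/s) at `t`.
#' @export
rateProfile <- function(spec, schedule, cycles, gasp_times = numeric(0),
                        gasp_duration = 0.4) {
  spec <- as.list(spec)
  classShape(spec$pattern_class)  # validate early: unknown class errors
  function(t) evalRateProfile(spec, t, cycles, schedule, gasp_times,
                              gasp_duration)
}

# Upper bound on a spec's intensity anywhere in the session (thinning
# envelope). Incoming excitatory couplings are bounded by strength^2
# (two overlapping source spikes per kernel window).
specMaxRate <- function(spec, incoming_strengths = numeric(0)) {
  cs <- classShape(spec$pattern_class)
  m <- if (cs$phase == "none") spec$base_rate
       else if (cs$phase == "gasp") 0
       else spec$base_rate * (1 + spec$depth)
  if (isTRUE(spec$gasp_participating)) m <- m + spec$gasp_rate
  s <- incoming_strengths[incoming_strengths > 1]
  if (length(s)) m <- m * prod(s^2)
  m
}
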