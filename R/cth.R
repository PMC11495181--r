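# Map spike times to normalized respiratory phase: inspiration to
# [0, 0.5), expiration to [0.5, 1). Returns phase and cycle index (NA for
# spikes outside any cycle).
spikePhases <- function(times, cycles) {
  ci <- findInterval(times, cycles$i_onset)
  ok <- ci >= 1L & times < cycles$cycle_end[pmax(ci, 1L)]
  cc <- ifelse(ok, ci, NA_integer_)
  inI <- ok & times < cycles$e_onset[pmax(ci, 1L)]
  phase <- rep(NA_real_, length(times))
  idx <- which(ok)
  if (length(idx)) {
    ci2 <- cc[idx]
    io <- cycles$i_onset[ci2]; eo <- cycles$e_onset[ci2]
    ce <- cycles$cycle_end[ci2]
    phase[idx] <- ifelse(inI[idx],
                         0.5 * (times[idx] - io) / (eo - io),
                         0.5 + 0.5 * (times[idx] - eo) / (ce - eo))
  }
  list(phase = phase, cycle = cc)
}

# Real time (s) each phase bin spans, summed over cycles. The phase map
# allots [0, 0.5) to inspiration regardless of the real I:E duration
# ratio, so each of the B inspiratory bins spans I_dur/B per cycle.
binTimeSpans <- function(cycles, bins_per_phase) {
  idur <- cycles$e_onset - cycles$i_onset
  edur <- cycles$cycle_end - cycles$e_onset
  c(rep(sum(idur) / bins_per_phase, bins_per_phase),
    rep(sum(edur) / bins_per_phase, bins_per_phase))
}

#' Phase-normalized respiratory cycle-triggered histogram
#'
#' Each spike in a cycle maps to normalized phase (inspiration linearly
#' onto `[0, 0.5)`, expiration onto `[0.5, 1)`); the rate in a bin is the
#' spike count across cycles divided by the summed real time the bin
#' spans. The scaled rate divides by the maximum bin rate, as CTHs are
#' conventionally displayed.
#'
#' @param train a [SpikeTrain-class].
#' @param cycles cycles data.frame (`i_onset`, `e_onset`, `cycle_end`);
#'   at least one cycle.
#' @param bins_per_phase bins per phase (at least 2; 25 by default via
#'   [analysisConfig()]).
#' @return a [CycleTriggeredHistogram-class] (classification fields unset
#'   until [testModulation()]/[classifyPattern()]).
#' @export
computeCth <- function(train, cycles, bins_per_phase = 25L) {
  if (is.null(cycles) || nrow(cycles) < 1L)
    stop("no cycles supplied for CTH of ", train@neuronId)
  stopifnot(bins_per_phase >= 2L)
  B <- as.integer(bins_per_phase)
  ph <- spikePhases(train@times, cycles)$phase
  ph <- ph[!is.na(ph)]
  counts <- tabulate(pmin(floor(ph * 2 * B) + 1L, 2L * B), nbins = 2L * B)
  spans <- binTimeSpans(cycles, B)
  rate <- counts / spans
  new("CycleTriggeredHistogram", neuronId = train@neuronId,
      binsPerPhase = B, phase = (seq_len(2 * B) - 0.5) / (2 * B),
      rate = rate,
      scaledRate = if (any(rate > 0)) rate / max(rate) else rate,
      nCycles = nrow(cycles))
}

#' Two-test respiratory-modulation decision
#'
#' Two complementary statistical tests of the null hypothesis that a
#' neuron's firing is unmodulated by respiratory phase. Test A is
#' parametric: a Pearson chi-square test of rate homogeneity across
#' phase bins on spike counts pooled over cycles (the replicates), with
#' the null expectation proportional to the real time each bin spans.
#' Test B is a Monte Carlo randomization: each cycle's spikes receive an
#' independent uniform circular shift in time within the cycle, the
#' statistic is the variance of the pooled phase histogram, and
#' `p = (1 + #{surrogate >= observed}) / (n_shuffles + 1)`. A neuron is
#' respiratory modulated if either test rejects at `alpha`.
#'
#' @param train a [SpikeTrain-class].
#' @param cycles cycles data.frame (at least 2; 20 or more recommended).
#' @param config an [analysisConfig()] list (`alpha_cth`,
#'   `cth_bins_per_phase`, `cth_n_shuffles`).
#' @param seed integer seed for the randomization test.
#' @return list with `p_testA`, `p_testB`, `modulated`.
#' @export
testModulation <- function(train, cycles, config = NULL, seed = NULL) {
  cfg <- asConfig(config)
  if (nrow(cycles) < 2L)
    stop("need at least 2 cycles to test modulation of ", train@neuronId)
  if (nrow(cycles) < 20L)
    warning("fewer than 20 cycles for modulation test of ", train@neuronId)
  if (is.null(seed))
    seed <- streamSeed(cfg$rng_seed, paste0(train@neuronId, "cth"))
  B <- cfg$cth_bins_per_phase
  nb <- 2L * B
  sp <- spikePhases(train@times, cycles)
  keep <- !is.na(sp$phase)
  ph <- sp$phase[keep]
  cyc <- sp$cycle[keep]
  nC <- nrow(cycles)

  # Test A (parametric): Pearson chi-square test of rate homogeneity
  # across phase bins, pooling spike counts over cycles (the
  # replicates); the null expectation in a bin is proportional to the
  # real time the bin spans, so unequal inspiratory and expiratory
  # durations do not masquerade as modulation
  bin <- pmin(floor(ph * nb) + 1L, nb)
  idur <- cycles$e_onset - cycles$i_onset
  edur <- cycles$cycle_end - cycles$e_onset
  O <- tabulate(bin, nbins = nb)
  spans <- c(rep(sum(idur) / B, B), rep(sum(edur) / B, B))
  pA <- if (sum(O) == 0) 1 else {
    E <- sum(O) * spans / sum(spans)
    stats::pchisq(sum((O - E)^2 / E), nb - 1, lower.tail = FALSE)
  }

  # Test B: each cycle's spikes rotated by an independent uniform
  # circular shift in time within the cycle (exactly distribution-
  # preserving for phase-unlocked firing even when inspiratory and
  # expiratory durations differ), phases recomputed, statistic =
  # variance of the pooled phase histogram
  obsStat <- stats::var(tabulate(bin, nbins = nb))
  io <- cycles$i_onset[cyc]
  dur <- (cycles$cycle_end - cycles$i_onset)[cyc]
  idu <- idur[cyc]
  edu <- edur[cyc]
  tau <- train@times[keep] - io
  pB <- withSeed(seed, {
    ge <- 0L
    for (s in seq_len(cfg$cth_n_shuffles)) {
      shift <- stats::runif(nC)
      tau2 <- (tau + shift[cyc] * dur) %% dur
      ph2 <- ifelse(tau2 < idu, 0.5 * tau2 / idu,
                    0.5 + 0.5 * (tau2 - idu) / edu)
      stat <- stats::var(tabulate(pmin(floor(ph2 * nb) + 1L, nb),
                                  nbins = nb))
      if (stat >= obsStat) ge <- ge + 1L
    }
    (1 + ge) / (cfg$cth_n_shuffles + 1)
  })
  if (length(bin) == 0L) pB <- 1
  list(p_testA = pA, p_testB = pB,
       modulated = (pA < cfg$alpha_cth) || (pB < cfg$alpha_cth))
}

#' Classify the respiratory firing pattern from a CTH
#'
#' Non-modulated neurons are `NRM`. Modulated neurons are inspiratory
#' (`I`) or expiratory (`E`) according to the phase half containing the
#' maximum bin rate (ties broken toward the earlier bin); the subtype is
#' `Dec` if the within-phase peak lies in the first half of that phase
#' and `Aug` if in the second (decrementing/augmenting discharge). A
#' neuron is `phasic` if any smoothed bin rate falls below
#' `max(eps_phasic_frac * peak, eps_phasic_floor)` (firing probability
#' essentially zero somewhere in the cycle), otherwise `tonic`.
#'
#' @param cth a [CycleTriggeredHistogram-class].
#' @param modulated logical from [testModulation()] (with its p-values
#'   optionally passed through `p_testA`/`p_testB`).
#' @param p_testA,p_testB p-values recorded into the returned object.
#' @param config an [analysisConfig()] list.
#' @return the CTH with `modulation`, `subtype`, `tonicity`, `modulated`
#'   and p-value slots filled.
#' @export
classifyPattern <- function(cth, modulated, p_testA = NA_real_,
                            p_testB = NA_real_, config = NULL) {
  cfg <- asConfig(config)
  cth@modulated <- modulated
  cth@pTestA <- p_testA
  cth@pTestB <- p_testB
  B <- cth@binsPerPhase
  r <- cth@rate
  if (all(r == 0)) {
    cth@modulation <- "NRM"; cth@subtype <- "other"
    cth@tonicity <- "phasic"
    attr(cth@modulation, "zero_rate") <- TRUE
    return(cth)
  }
  # cyclic 5-bin smoothing: respiratory phase wraps, and genuinely
  # silent stretches span many bins, so smoothing suppresses single-bin
  # sampling dips without masking real silence
  w <- 5L
  rp <- c(r[(length(r) - w + 1):length(r)], r, r[1:w])
  sm <- movingAverage(rp, w)[(w + 1):(w + length(r))]
  eps <- max(cfg$eps_phasic_frac * max(r), cfg$eps_phasic_floor)
  cth@tonicity <- if (any(sm < eps)) "phasic" else "tonic"
  if (!isTRUE(modulated)) {
    cth@modulation <- "NRM"; cth@subtype <- "other"
    return(cth)
  }
  peakBin <- which.max(r)                     # ties: earlier bin wins
  inI <- peakBin <= B
  cth@modulation <- if (inI) "I" else "E"
  within <- if (inI) peakBin else peakBin - B
  cth@subtype <- if (within <= B / 2) "Dec" else "Aug"
  cth
}

#' Compute, test and classify CTHs for every neuron in a session
#'
#' Applies [computeCth()], [testModulation()] and [classifyPattern()] to
#' each train, using only the control window (the cycles supplied should
#' come from the control period, as classification is defined on control
#' breathing).
#'
#' @param session a [Session-class].
#' @param cycles control-window cycles data.frame.
#' @param config an [analysisConfig()] list.
#' @return list with `cths` (named list of
#'   [CycleTriggeredHistogram-class]) and `classes` (data.frame
#'   `neuron_id`, `modulation`, `subtype`, `tonicity`, `p_testA`,
#'   `p_testB`).
#' @export
classifyAllNeurons <- function(session, cycles, config = NULL) {
  cfg <- asConfig(config)
  cths <- list()
  rows <- list()
  for (tr in session@trains) {
    cth <- computeCth(tr, cycles, cfg$cth_bins_per_phase)
    if (length(tr@times) >= 2L && any(cth@rate > 0)) {
      tm <- suppressWarnings(testModulation(tr, cycles, cfg))
    } else {
      tm <- list(p_testA = 1, p_testB = 1, modulated = FALSE)
    }
    cth <- classifyPattern(cth, tm$modulated, tm$p_testA, tm$p_testB, cfg)
    cths[[tr@neuronId]] <- cth
    rows[[tr@neuronId]] <- data.frame(
      neuron_id = tr@neuronId, modulation = cth@modulation,
      subtype = cth@subtype, tonicity = cth@tonicity,
      p_testA = tm$p_testA, p_testB = tm$p_testB,
      stringsAsFactors = FALSE)
  }
  classes <- do.call(rbind, rows)
  rownames(classes) <- NULL
  list(cths = cths, classes = classes)
}
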