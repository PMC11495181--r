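#' @import methods
NULL

REGION_LEVELS <- c("VRC", "raphe", "pons", "other")
SIGNAL_NAMES <- c("phrenic_integrated", "blood_pressure", "etco2",
                  "tracheal_pressure", "other")
PATTERN_CLASSES <- c("I-Aug", "I-Dec", "E-Aug", "E-Dec", "post-I",
                     "tonic-I", "tonic-E", "NRM", "gasp-only")
EPOCH_CLASSES <- c("control", "augmentation", "depression_apneusis",
                   "apnea", "gasping", "recovery")

#' SpikeTrain: one neuron's sorted spike times
#'
#' Holds the spike times (seconds) of a single isolated neuron together with
#' its anatomical region and the recording interval. The interval is
#' half-open `[t0, t1)`: a spike exactly at `t1` is invalid.
#'
#' @slot neuronId single string, unique within a session.
#' @slot region one of `"VRC"`, `"raphe"`, `"pons"`, `"other"`.
#' @slot times strictly increasing numeric vector of spike times (s).
#' @slot interval numeric length 2, recording interval `[t0, t1)` with
#'   `t0 < t1`.
#' @export
setClass("SpikeTrain",
  representation(neuronId = "character", region = "character",
                 times = "numeric", interval = "numeric"),
  prototype(neuronId = NA_character_, region = "other",
            times = numeric(0), interval = c(0, 1)))

setValidity("SpikeTrain", function(object) {
  msg <- character(0)
  if (length(object@neuronId) != 1L || is.na(object@neuronId) ||
      !nzchar(object@neuronId))
    msg <- c(msg, "neuronId must be a single non-empty string")
  if (length(object@region) != 1L || !(object@region %in% REGION_LEVELS))
    msg <- c(msg, sprintf("region must be one of %s",
                          paste(REGION_LEVELS, collapse = ", ")))
  if (length(object@interval) != 2L || any(!is.finite(object@interval)) ||
      object@interval[1] >= object@interval[2])
    msg <- c(msg, "interval must be [t0, t1] with t0 < t1")
  tt <- object@times
  if (length(tt)) {
    if (any(!is.finite(tt)))
      msg <- c(msg, sprintf("non-finite spike time for %s", object@neuronId))
    if (length(tt) > 1L && any(diff(tt) <= 0))
      msg <- c(msg, sprintf("times not increasing for %s", object@neuronId))
    if (length(object@interval) == 2L &&
        (tt[1] < object@interval[1] || tt[length(tt)] >= object@interval[2]))
      msg <- c(msg, sprintf("spike outside interval for %s", object@neuronId))
  }
  if (length(msg)) msg else TRUE
})

#' ContinuousSignal: a uniformly sampled physiological trace
#'
#' @slot name signal kind; one of `"phrenic_integrated"`, `"blood_pressure"`,
#'   `"etco2"`, `"tracheal_pressure"`, `"other"`.
#' @slot fs sampling rate (Hz), positive.
#' @slot start time of the first sample (s).
#' @slot samples finite numeric vector.
#' @export
setClass("ContinuousSignal",
  representation(name = "character", fs = "numeric", start = "numeric",
                 samples = "numeric"),
  prototype(name = "other", fs = 1000, start = 0, samples = numeric(0)))

setValidity("ContinuousSignal", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || !(object@name %in% SIGNAL_NAMES))
    msg <- c(msg, sprintf("signal name must be one of %s",
                          paste(SIGNAL_NAMES, collapse = ", ")))
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@start) != 1L || !is.finite(object@start))
    msg <- c(msg, "start must be a single finite number")
  if (length(object@samples) && any(!is.finite(object@samples)))
    msg <- c(msg, sprintf("non-finite samples in signal %s", object@name))
  if (length(msg)) msg else TRUE
})

#' Session: simultaneously recorded spike trains and signals
#'
#' A recording session bundles the spike trains of all simultaneously
#' monitored neurons, the sampled physiological signals, the normoxic
#' control window used for baseline statistics, and free-form metadata.
#'
#' @slot trains list of [SpikeTrain-class], names equal to neuron ids.
#' @slot signals list of [ContinuousSignal-class], names equal to signal
#'   names.
#' @slot controlWindow numeric length 2, `[t0, t1]` of the control period;
#'   must lie within every train's recording interval.
#' @slot metadata named list.
#' @export
setClass("Session",
  representation(trains = "list", signals = "list",
                 controlWindow = "numeric", metadata = "list"),
  prototype(trains = list(), signals = list(),
            controlWindow = c(0, 1), metadata = list()))

setValidity("Session", function(object) {
  rep <- validateSessionInternal(object)
  if (length(rep)) rep else TRUE
})

#' CycleTriggeredHistogram: phase-normalized firing-rate histogram
#'
#' Firing rate of one neuron as a function of normalized respiratory phase
#' (inspiration mapped to `[0, 0.5)`, expiration to `[0.5, 1)`), averaged
#' over cycles, together with the respiratory-modulation classification.
#'
#' @slot neuronId neuron identifier.
#' @slot binsPerPhase number of bins allotted to each phase.
#' @slot phase bin-centre phases in `[0, 1)`.
#' @slot rate per-bin firing rate (spikes/s).
#' @slot scaledRate `rate / max(rate)` (all zero for a silent neuron).
#' @slot nCycles number of cycles averaged.
#' @slot pTestA,pTestB p-values of the parametric (chi-square) and
#'   randomization modulation tests (`NA` until [testModulation()] is run).
#' @slot modulated logical; either test rejected at the configured level.
#' @slot modulation `"I"`, `"E"` or `"NRM"`.
#' @slot subtype `"Aug"`, `"Dec"` or `"other"`.
#' @slot tonicity `"phasic"` or `"tonic"`.
#' @export
setClass("CycleTriggeredHistogram",
  representation(neuronId = "character", binsPerPhase = "integer",
                 phase = "numeric", rate = "numeric", scaledRate = "numeric",
                 nCycles = "integer", pTestA = "numeric", pTestB = "numeric",
                 modulated = "logical", modulation = "character",
                 subtype = "character", tonicity = "character"),
  prototype(pTestA = NA_real_, pTestB = NA_real_, modulated = NA,
            modulation = NA_character_, subtype = NA_character_,
            tonicity = NA_character_))

setValidity("CycleTriggeredHistogram", function(object) {
  msg <- character(0)
  if (any(object@rate < 0)) msg <- c(msg, "rate must be nonnegative")
  if (length(object@rate) != length(object@phase))
    msg <- c(msg, "rate and phase lengths differ")
  if (any(object@rate > 0) &&
      abs(max(object@scaledRate) - 1) > 1e-12)
    msg <- c(msg, "scaledRate must attain 1 when any spike is present")
  if (length(msg)) msg else TRUE
})

#' Correlogram: binned pairwise cross-correlation with surrogate bands
#'
#' Counts of target spikes at signed lags relative to every reference
#' spike. Positive lag means the target spike follows the reference spike.
#'
#' @slot refId,targetId reference and target neuron ids.
#' @slot binWidth bin width (s).
#' @slot lags bin-centre lags, symmetric about 0.
#' @slot counts integer counts per bin.
#' @slot rate `counts / (nRef * binWidth)` (spikes/s).
#' @slot nRef number of reference spikes.
#' @slot surrogateMean,surrogateLo,surrogateHi per-bin surrogate mean and
#'   2.5/97.5 percentile band (length 0 until [detectFeatures()]).
#' @slot features data.frame of detected features (see [detectFeatures()]).
#' @export
setClass("Correlogram",
  representation(refId = "character", targetId = "character",
                 binWidth = "numeric", lags = "numeric", counts = "integer",
                 rate = "numeric", nRef = "integer",
                 surrogateMean = "numeric", surrogateLo = "numeric",
                 surrogateHi = "numeric", features = "data.frame"),
  prototype(surrogateMean = numeric(0), surrogateLo = numeric(0),
            surrogateHi = numeric(0), features = data.frame()))

setValidity("Correlogram", function(object) {
  msg <- character(0)
  if (any(object@counts < 0)) msg <- c(msg, "counts must be nonnegative")
  if (length(object@lags) &&
      max(abs(object@lags + rev(object@lags))) > 1e-9)
    msg <- c(msg, "lags must be symmetric about 0")
  if (length(msg)) msg else TRUE
})

#' SpikeTriggeredAverage: average of a signal around trigger spikes
#'
#' @slot triggerId trigger neuron id.
#' @slot signalName name of the averaged signal.
#' @slot lags sample-spaced lags, symmetric about 0 (s).
#' @slot meanTrace average (rectified) signal value at each lag.
#' @slot nTriggers triggers used; @slot nExcluded triggers dropped for
#'   incomplete window coverage.
#' @slot surrogateMean,surrogateLo,surrogateHi surrogate bands.
#' @slot features data.frame of detected features.
#' @export
setClass("SpikeTriggeredAverage",
  representation(triggerId = "character", signalName = "character",
                 lags = "numeric", meanTrace = "numeric",
                 nTriggers = "integer", nExcluded = "integer",
                 surrogateMean = "numeric", surrogateLo = "numeric",
                 surrogateHi = "numeric", features = "data.frame"),
  prototype(surrogateMean = numeric(0), surrogateLo = numeric(0),
            surrogateHi = numeric(0), features = data.frame()))

setValidity("SpikeTriggeredAverage", function(object) {
  msg <- character(0)
  if (object@nTriggers <= 0L) msg <- c(msg, "nTriggers must be positive")
  if (length(object@lags) &&
      max(abs(object@lags + rev(object@lags))) > 1e-9)
    msg <- c(msg, "lags must be symmetric about 0")
  if (length(msg)) msg else TRUE
})

#' FeatureMap: directed correlation feature map
#'
#' Inferred functional graph over the recorded population. Offset
#' correlogram features yield directed excitatory/inhibitory edges; central
#' features yield undirected shared-influence edges.
#'
#' @slot nodes data.frame with columns `neuron_id`, `region`, `modulation`,
#'   `subtype`, `tonicity`.
#' @slot edges data.frame with columns `source`, `target`, `sign`
#'   (`excitation`, `inhibition`, `shared_drive`, `shared_opposite`),
#'   `directed`, `extremum_lag_s`, `di`, `p_mc`, `q_value`.
#' @export
setClass("FeatureMap",
  representation(nodes = "data.frame", edges = "data.frame"))

setValidity("FeatureMap", function(object) {
  msg <- character(0)
  if (nrow(object@edges)) {
    ids <- object@nodes$neuron_id
    if (!all(object@edges$source %in% ids) ||
        !all(object@edges$target %in% ids))
      msg <- c(msg, "every edge endpoint must be a node")
    bad <- object@edges$directed !=
      (object@edges$sign %in% c("excitation", "inhibition"))
    if (any(bad))
      msg <- c(msg, "directed edges must be excitation/inhibition, undirected shared_*")
  }
  if (length(msg)) msg else TRUE
})

#' GroundTruth: the synthetic generator's known structure
#'
#' Everything the generator injected, for recovery testing: neuron
#' specifications, coupling structure, the motor-pattern schedule, true
#' cycle boundaries, gasp times, sigh times and blood-pressure step times.
#'
#' @slot neurons data.frame of neuron specifications.
#' @slot connections data.frame of pairwise couplings.
#' @slot commonDrives list of common-drive specifications.
#' @slot schedule data.frame of epochs (`class`, `t0`, `t1`, gains).
#' @slot cycles data.frame of true cycles (`i_onset`, `e_onset`,
#'   `cycle_end`).
#' @slot gaspTimes,sighTimes,bpStepTimes numeric event times (s).
#' @export
setClass("GroundTruth",
  representation(neurons = "data.frame", connections = "data.frame",
                 commonDrives = "list", schedule = "data.frame",
                 cycles = "data.frame", gaspTimes = "numeric",
                 sighTimes = "numeric", bpStepTimes = "numeric"),
  prototype(commonDrives = list(), gaspTimes = numeric(0),
            sighTimes = numeric(0), bpStepTimes = numeric(0)))

#' RunReport: machine-readable pipeline run summary
#'
#' @slot config the configuration used (as a list).
#' @slot counts named list of per-stage record counts.
#' @slot seeds named list of seeds used.
#' @slot warnings character vector of stage warnings.
#' @export
setClass("RunReport",
  representation(config = "list", counts = "list", seeds = "list",
                 warnings = "character"),
  prototype(warnings = character(0)))
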