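#' Construct a SpikeTrain
#'
#' @param neuronId single string.
#' @param times numeric vector of spike times in seconds, strictly
#'   increasing, all within `[t0, t1)`.
#' @param interval recording interval `c(t0, t1)`.
#' @param region one of `"VRC"`, `"raphe"`, `"pons"`, `"other"`.
#' @return a validated [SpikeTrain-class].
#' @examples
#' spikeTrain("n1", c(0.1, 0.5, 0.9), interval = c(0, 1), region = "VRC")
#' @export
spikeTrain <- function(neuronId, times, interval, region = "other") {
  new("SpikeTrain", neuronId = as.character(neuronId),
      region = as.character(region),
      times = as.numeric(times), interval = as.numeric(interval))
}

#' Construct a ContinuousSignal
#'
#' @param name signal kind (see [ContinuousSignal-class]).
#' @param samples finite numeric vector.
#' @param fs sampling rate in Hz.
#' @param start time of the first sample (s).
#' @return a validated [ContinuousSignal-class].
#' @export
continuousSignal <- function(name, samples, fs, start = 0) {
  new("ContinuousSignal", name = as.character(name),
      samples = as.numeric(samples), fs = as.numeric(fs),
      start = as.numeric(start))
}

#' Construct a Session
#'
#' @param trains list of [SpikeTrain-class] objects.
#' @param signals list of [ContinuousSignal-class] objects.
#' @param controlWindow `c(t0, t1)` of the normoxic control period.
#' @param metadata named list.
#' @return a validated [Session-class].
#' @export
newSession <- function(trains = list(), signals = list(),
                       controlWindow = NULL, metadata = list()) {
  if (is.null(controlWindow)) {
    controlWindow <- if (length(trains))
      trains[[1]]@interval else c(0, 1)
  }
  names(trains) <- vapply(trains, function(x) x@neuronId, character(1))
  if (length(signals))
    names(signals) <- vapply(signals, function(x) x@name, character(1))
  new("Session", trains = trains, signals = signals,
      controlWindow = as.numeric(controlWindow), metadata = metadata)
}

## -- accessors ---------------------------------------------------------------

#' @rdname SpikeTrain-class
setMethod("neuronId", "SpikeTrain", function(object) object@neuronId)
#' @rdname SpikeTrain-class
setMethod("region", "SpikeTrain", function(object) object@region)
#' @rdname SpikeTrain-class
setMethod("spikeTimes", "SpikeTrain", function(object) object@times)
#' @rdname SpikeTrain-class
setMethod("recordingInterval", "SpikeTrain", function(object) object@interval)

#' @rdname ContinuousSignal-class
setMethod("signalName", "ContinuousSignal", function(object) object@name)
#' @rdname ContinuousSignal-class
setMethod("samplingRate", "ContinuousSignal", function(object) object@fs)
#' @rdname ContinuousSignal-class
setMethod("signalSamples", "ContinuousSignal", function(object) object@samples)
#' @rdname ContinuousSignal-class
setMethod("signalTimes", "ContinuousSignal", function(object)
  object@start + (seq_along(object@samples) - 1) / object@fs)

#' @rdname Session-class
setMethod("sessionTrains", "Session", function(object) object@trains)
#' @rdname Session-class
setMethod("sessionSignals", "Session", function(object) object@signals)
#' @rdname Session-class
setMethod("controlWindow", "Session", function(object) object@controlWindow)
#' @rdname Session-class
setMethod("sessionMetadata", "Session", function(object) object@metadata)

#' @rdname corrFeatures
setMethod("corrFeatures", "Correlogram", function(object) object@features)
#' @rdname corrFeatures
setMethod("corrFeatures", "SpikeTriggeredAverage",
          function(object) object@features)

#' @rdname mapNodes
setMethod("mapNodes", "FeatureMap", function(object) object@nodes)
#' @rdname mapNodes
setMethod("mapEdges", "FeatureMap", function(object) object@edges)

## -- show --------------------------------------------------------------------

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain %s [%s]: %d spikes on [%.3f, %.3f) s\n",
              object@neuronId, object@region, length(object@times),
              object@interval[1], object@interval[2]))
})

setMethod("show", "ContinuousSignal", function(object) {
  cat(sprintf("ContinuousSignal %s: %d samples @ %g Hz from t=%g s\n",
              object@name, length(object@samples), object@fs, object@start))
})

setMethod("show", "Session", function(object) {
  cat(sprintf("Session: %d spike trains, %d signals\n",
              length(object@trains), length(object@signals)))
  if (length(object@trains)) {
    reg <- table(vapply(object@trains, region, character(1)))
    cat("  regions:", paste(names(reg), reg, sep = "=", collapse = ", "),
        "\n")
  }
  cat(sprintf("  control window: [%.1f, %.1f] s\n",
              object@controlWindow[1], object@controlWindow[2]))
})

setMethod("show", "CycleTriggeredHistogram", function(object) {
  cat(sprintf(
    "CTH %s: %d bins/phase, %d cycles, class %s%s/%s (pA=%.3g, pB=%.3g)\n",
    object@neuronId, object@binsPerPhase, object@nCycles,
    ifelse(is.na(object@modulation), "?", object@modulation),
    ifelse(is.na(object@subtype) || object@subtype == "other", "",
           paste0("-", object@subtype)),
    ifelse(is.na(object@tonicity), "?", object@tonicity),
    object@pTestA, object@pTestB))
})

setMethod("show", "Correlogram", function(object) {
  cat(sprintf("Correlogram %s -> %s: %d bins of %.2g ms, n_ref=%d\n",
              object@refId, object@targetId, length(object@lags),
              object@binWidth * 1e3, object@nRef))
  if (nrow(object@features))
    cat(sprintf("  %d feature(s): %s\n", nrow(object@features),
                paste(sprintf("%s %s @ %+.1f ms (DI %.1f)",
                              object@features$position, object@features$kind,
                              object@features$extremum_lag * 1e3,
                              object@features$di), collapse = "; ")))
})

setMethod("show", "SpikeTriggeredAverage", function(object) {
  cat(sprintf("STA of %s triggered by %s: %d lags, %d triggers (%d excluded)\n",
              object@signalName, object@triggerId, length(object@lags),
              object@nTriggers, object@nExcluded))
})

setMethod("show", "FeatureMap", function(object) {
  cat(sprintf("FeatureMap: %d nodes, %d edges\n",
              nrow(object@nodes), nrow(object@edges)))
  if (nrow(object@edges))
    print(table(object@edges$sign))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d neurons, %d connections, %d common drives, %d epochs\n",
    nrow(object@neurons), nrow(object@connections),
    length(object@commonDrives), nrow(object@schedule)))
})

setMethod("show", "RunReport", function(object) {
  cat("RunReport\n")
  for (nm in names(object@counts))
    cat(sprintf("  %s: %s\n", nm, object@counts[[nm]]))
  if (length(object@warnings))
    cat("  warnings:", length(object@warnings), "\n")
})
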