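#' @rdname SpikeTrain-class
#' @param object a gaspnet S4 object.
#' @export
setGeneric("neuronId", function(object) standardGeneric("neuronId"))

#' @rdname SpikeTrain-class
#' @export
setGeneric("region", function(object) standardGeneric("region"))

#' @rdname SpikeTrain-class
#' @export
setGeneric("spikeTimes", function(object) standardGeneric("spikeTimes"))

#' @rdname SpikeTrain-class
#' @export
setGeneric("recordingInterval",
           function(object) standardGeneric("recordingInterval"))

#' @rdname ContinuousSignal-class
#' @param object a gaspnet S4 object.
#' @export
setGeneric("signalName", function(object) standardGeneric("signalName"))

#' @rdname ContinuousSignal-class
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname ContinuousSignal-class
#' @export
setGeneric("signalSamples", function(object) standardGeneric("signalSamples"))

#' @rdname ContinuousSignal-class
#' @export
setGeneric("signalTimes", function(object) standardGeneric("signalTimes"))

#' @rdname Session-class
#' @param object a gaspnet S4 object.
#' @export
setGeneric("sessionTrains", function(object) standardGeneric("sessionTrains"))

#' @rdname Session-class
#' @export
setGeneric("sessionSignals",
           function(object) standardGeneric("sessionSignals"))

#' @rdname Session-class
#' @export
setGeneric("controlWindow", function(object) standardGeneric("controlWindow"))

#' @rdname Session-class
#' @export
setGeneric("sessionMetadata",
           function(object) standardGeneric("sessionMetadata"))

#' Features detected on a correlogram or spike-triggered average
#' @param object a [Correlogram-class] or [SpikeTriggeredAverage-class].
#' @return data.frame of features (possibly empty).
#' @export
setGeneric("corrFeatures", function(object) standardGeneric("corrFeatures"))

#' Nodes and edges of a feature map
#' @param object a [FeatureMap-class].
#' @export
setGeneric("mapNodes", function(object) standardGeneric("mapNodes"))

#' @rdname mapNodes
#' @export
setGeneric("mapEdges", function(object) standardGeneric("mapEdges"))
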