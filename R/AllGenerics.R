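#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @export
setGeneric("windowLength", function(x) standardGeneric("windowLength"))

#' @export
setGeneric("slideWidth", function(x) standardGeneric("slideWidth"))

#' @export
setGeneric("numWindows", function(x) standardGeneric("numWindows"))

#' @export
setGeneric("windowStarts", function(x) standardGeneric("windowStarts"))

#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @export
setGeneric("scanGrid", function(x) standardGeneric("scanGrid"))

#' @export
setGeneric("optimalWindow", function(x) standardGeneric("optimalWindow"))

#' @export
setGeneric("optimalGroups", function(x) standardGeneric("optimalGroups"))

#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @export
setGeneric("baselineTable", function(x) standardGeneric("baselineTable"))

#' @export
setGeneric("eventStats", function(x, ...) standardGeneric("eventStats"))

#' @export
setGeneric("intervalLabels", function(x, windows, ...) standardGeneric("intervalLabels"))
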