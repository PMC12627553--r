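#' @describeIn LabeledClip-class amplitude series accessor.
#' @param object,x an object.
#' @export
setGeneric("waveform", function(object) standardGeneric("waveform"))

#' @describeIn LabeledClip-class binary bowhead-presence label accessor.
#' @export
setGeneric("clipLabel", function(object) standardGeneric("clipLabel"))

#' @describeIn LabeledClip-class ground-truth event table accessor.
#' @export
setGeneric("clipEvents", function(object) standardGeneric("clipEvents"))

#' @describeIn SpectrogramTile-class log-magnitude matrix accessor.
#' @export
setGeneric("tileValues", function(object) standardGeneric("tileValues"))

#' @describeIn TileSet-class label vector accessor.
#' @export
setGeneric("tileLabels", function(object) standardGeneric("tileLabels"))

#' @describeIn PerformanceSummary-class sensitivity TP/(TP+FN); NA when
#'   undefined.
#' @export
setGeneric("sensitivity", function(object) standardGeneric("sensitivity"))

#' @describeIn PerformanceSummary-class false-positive rate FP/(FP+TN); NA
#'   when undefined.
#' @export
setGeneric("fpRate", function(object) standardGeneric("fpRate"))

#' @describeIn IceField-class concentration matrix accessor.
#' @export
setGeneric("concentration", function(object) standardGeneric("concentration"))

#' @describeIn Network-class architecture specification accessor.
#' @export
setGeneric("archSpec", function(object) standardGeneric("archSpec"))

#' @describeIn Network-class weight list accessor.
#' @export
setGeneric("netWeights", function(object) standardGeneric("netWeights"))

#' @describeIn DetectorFit-class best network accessor.
#' @export
setGeneric("bestNetwork", function(object) standardGeneric("bestNetwork"))

#' @describeIn DetectorFit-class training history accessor.
#' @export
setGeneric("trainHistory", function(object) standardGeneric("trainHistory"))

#' @describeIn DetectorFit-class normalization statistics accessor.
#' @export
setGeneric("normStats", function(object) standardGeneric("normStats"))
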