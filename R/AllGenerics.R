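#' @describeIn BandGrid band center wavelengths in nanometres.
#' @param object,x an object.
#' @export
setGeneric("bandCenters", function(object) standardGeneric("bandCenters"))

#' @describeIn BandGrid number of bands.
#' @export
setGeneric("nBands", function(object) standardGeneric("nBands"))

#' Physical pixel size accessor
#' @param object an object carrying a pixel size.
#' @return pixel edge length in micrometres.
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @describeIn SyntheticScene names of the scalar channels in a scene.
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' Extract a named channel image from a scene
#' @param object a \linkS4class{SyntheticScene}.
#' @param name channel name.
#' @return the channel image.
#' @export
setGeneric("getChannel", function(object, name) standardGeneric("getChannel"))

#' Planted truth accessor
#' @param object a scene or cohort object.
#' @return the planted truth table / object.
#' @export
setGeneric("plaqueTruth", function(object) standardGeneric("plaqueTruth"))

#' @describeIn PlaqueLabelMap the raw integer label matrix.
#' @export
setGeneric("labelMatrix", function(object) standardGeneric("labelMatrix"))

#' @describeIn PlaqueLabelMap number of labeled plaques.
#' @export
setGeneric("nPlaques", function(object) standardGeneric("nPlaques"))

#' Per-object areas in square micrometres
#' @param object a \linkS4class{PlaqueLabelMap}.
#' @return named numeric vector of component areas (um^2).
#' @export
setGeneric("plaqueAreas", function(object) standardGeneric("plaqueAreas"))

#' Held-out R-squared accessor
#' @param object a \linkS4class{ModelResult}.
#' @export
setGeneric("r2Test", function(object) standardGeneric("r2Test"))

#' Permutation importance accessor
#' @param object a \linkS4class{ModelResult}.
#' @export
setGeneric("importances", function(object) standardGeneric("importances"))

#' Effect-leverage residual pairs accessor
#' @param object a \linkS4class{LeverageFit}.
#' @export
setGeneric("leverages", function(object) standardGeneric("leverages"))

#' Coefficient table accessor
#' @param object a \linkS4class{LeverageFit}.
#' @export
setGeneric("estimates", function(object) standardGeneric("estimates"))
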