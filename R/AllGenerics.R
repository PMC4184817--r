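#' @rdname FluorescenceStack-class
#' @param object,x a container object
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname FluorescenceStack-class
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname FluorescenceStack-class
#' @export
setGeneric("stimOnset", function(x) standardGeneric("stimOnset"))

#' @rdname FluorescenceStack-class
#' @export
setGeneric("stimOffset", function(x) standardGeneric("stimOffset"))

#' @rdname FluorescenceStack-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname FluorescenceStack-class
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))

#' @rdname DffStack-class
#' @param x a [DffStack-class]
#' @export
setGeneric("dff", function(x) standardGeneric("dff"))

#' @rdname DffStack-class
#' @export
setGeneric("baselineF0", function(x) standardGeneric("baselineF0"))

#' @rdname DffStack-class
#' @export
setGeneric("baselineWindow", function(x) standardGeneric("baselineWindow"))

#' @rdname DffStack-class
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' Compute the dF/F stack of a recording
#'
#' @param stack a [FluorescenceStack-class].
#' @param ... passed to methods.
#' @return A [DffStack-class].
#' @export
setGeneric("computeDff", function(stack, ...) standardGeneric("computeDff"))

#' @rdname PhaseSegmentation-class
#' @param x a [PhaseSegmentation-class]
#' @export
setGeneric("lightPhase", function(x) standardGeneric("lightPhase"))

#' @rdname PhaseSegmentation-class
#' @export
setGeneric("darkPhase", function(x) standardGeneric("darkPhase"))

#' @rdname PhaseSegmentation-class
#' @export
setGeneric("peakFrame", function(x) standardGeneric("peakFrame"))

#' @rdname AfiResponse-class
#' @param x an [AfiResponse-class]
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @rdname AfiResponse-class
#' @export
setGeneric("areaPixels", function(x) standardGeneric("areaPixels"))

#' @rdname AfiResponse-class
#' @export
setGeneric("areaMm2", function(x) standardGeneric("areaMm2"))
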