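#' @rdname FluorescenceStack-class
#' @aliases frames frameTimes stimOnset stimOffset pixelSize orientation
setMethod("frames", "FluorescenceStack", function(x) x@frames)

#' @rdname FluorescenceStack-class
setMethod("frameTimes", "FluorescenceStack", function(x) x@frameTimes)

#' @rdname FluorescenceStack-class
setMethod("stimOnset", "FluorescenceStack", function(x) x@stimOnset)

#' @rdname FluorescenceStack-class
setMethod("stimOffset", "FluorescenceStack", function(x) x@stimOffset)

#' @rdname FluorescenceStack-class
setMethod("pixelSize", "FluorescenceStack", function(x) x@pixelSize)

#' @rdname FluorescenceStack-class
setMethod("orientation", "FluorescenceStack", function(x) x@orientation)

#' @rdname DffStack-class
setMethod("dff", "DffStack", function(x) x@dff)

#' @rdname DffStack-class
setMethod("baselineF0", "DffStack", function(x) x@f0)

#' @rdname DffStack-class
setMethod("baselineWindow", "DffStack", function(x) x@baselineWindow)

#' @rdname DffStack-class
setMethod("validMask", "DffStack", function(x) x@valid)

#' @rdname DffStack-class
setMethod("frameTimes", "DffStack", function(x) x@frameTimes)

#' @rdname DffStack-class
setMethod("stimOnset", "DffStack", function(x) x@stimOnset)

#' @rdname DffStack-class
setMethod("stimOffset", "DffStack", function(x) x@stimOffset)

#' @rdname DffStack-class
setMethod("pixelSize", "DffStack", function(x) x@pixelSize)

#' @rdname DffStack-class
setMethod("orientation", "DffStack", function(x) x@orientation)

#' @rdname PhaseSegmentation-class
setMethod("lightPhase", "PhaseSegmentation", function(x) {
  if (is.na(x@lightStart)) return(integer(0))
  x@lightStart:x@lightEnd
})

#' @rdname PhaseSegmentation-class
setMethod("darkPhase", "PhaseSegmentation", function(x) {
  if (is.na(x@darkStart)) return(integer(0))
  x@darkStart:x@darkEnd
})

#' @rdname PhaseSegmentation-class
setMethod("peakFrame", "PhaseSegmentation", function(x) x@peakFrame)

#' @rdname AfiResponse-class
setMethod("intensity", "AfiResponse", function(x) x@intensity)

#' @rdname AfiResponse-class
setMethod("areaPixels", "AfiResponse", function(x) x@areaPixels)

#' @rdname AfiResponse-class
setMethod("areaMm2", "AfiResponse", function(x) x@areaMm2)

setMethod("show", "FluorescenceStack", function(object) {
  d <- dim(object@frames)
  cat("FluorescenceStack:", d[1], "frames of", d[2], "x", d[3], "pixels\n")
  cat("  time range:", round(min(object@frameTimes), 3), "-",
      round(max(object@frameTimes), 3), "s; stimulus",
      object@stimOnset, "-", object@stimOffset, "s\n")
  cat("  pixel size:", object@pixelSize, "um; orientation:",
      object@orientation, "\n")
})

setMethod("show", "DffStack", function(object) {
  d <- dim(object@dff)
  cat("DffStack:", d[1], "frames of", d[2], "x", d[3], "pixels\n")
  cat("  baseline: frames", min(object@baselineWindow), "-",
      max(object@baselineWindow), ";", sum(!object@valid),
      "masked pixel(s)\n")
  flat <- object@dff
  dim(flat) <- c(d[1], d[2] * d[3])
  rng <- range(flat[, as.vector(object@valid), drop = FALSE], na.rm = TRUE)
  cat(sprintf("  dF/F range: %+.3f%% to %+.3f%%\n", 100 * rng[1], 100 * rng[2]))
})

setMethod("show", "PhaseSegmentation", function(object) {
  if (object@noResponse) {
    cat("PhaseSegmentation: no response detected (band",
        signif(object@band, 3), ")\n")
  } else {
    cat("PhaseSegmentation: light phase frames", object@lightStart, "-",
        object@lightEnd, "(peak", object@peakFrame, ")")
    if (!is.na(object@darkStart))
      cat("; dark phase frames", object@darkStart, "-", object@darkEnd)
    else cat("; no dark phase")
    cat("\n")
  }
})

setMethod("show", "AfiResponse", function(object) {
  cat(sprintf("AfiResponse: intensity %.3f%% dF/F%s\n", object@intensity,
              if (object@noResponse) " (no-response flag set)" else ""))
  cat(sprintf("  area of excitation: %d px (%.4f mm^2) above %.2f%%; ipsi %d / contra %d\n",
              object@areaPixels, object@areaMm2, object@threshold,
              object@ipsiPixels, object@contraPixels))
})
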