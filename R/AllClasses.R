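#' @import methods
NULL

#' FluorescenceStack: a raw widefield AFI movie
#'
#' Container for a raw autofluorescent flavoprotein imaging (AFI) recording:
#' a time x rows x cols array of camera counts in the 16-bit range, the frame
#' time base, and the stimulus epoch.  The camera faces the dorsal surface of
#' the exposed spinal cord; by convention the top half of the image is the
#' left (ipsilateral, i.e. stimulated) side of the cord.
#'
#' Counts are stored as numeric.  They are integer photon counts when read
#' from a 16-bit TIFF or rendered with shot noise; noiseless synthetic movies
#' keep continuous values so that ground truth survives exactly.
#'
#' @slot frames numeric 3-D array, time x rows x cols, values in [0, 65535].
#' @slot frameTimes numeric, seconds from recording start, strictly
#'   increasing, one per frame.
#' @slot stimOnset,stimOffset numeric seconds; the stimulation epoch.
#' @slot pixelSize numeric, micrometers per pixel edge.
#' @slot orientation character; `"top-left"` means image rows
#'   `1..nrow/2` are the left/ipsilateral cord side.
#'
#' @seealso [computeDff()], [renderMovie()], [readFluorescenceStack()]
#' @export
setClass("FluorescenceStack",
  representation(
    frames      = "array",
    frameTimes  = "numeric",
    stimOnset   = "numeric",
    stimOffset  = "numeric",
    pixelSize   = "numeric",
    orientation = "character"
  )
)

setValidity("FluorescenceStack", function(object) {
  msg <- character()
  f <- object@frames
  if (length(dim(f)) != 3L)
    msg <- c(msg, "frames must be a 3-D array (time x rows x cols)")
  if (anyNA(f) || any(f < 0) || any(f > 65535))
    msg <- c(msg, "counts must lie in the 16-bit range [0, 65535]")
  if (length(object@frameTimes) != dim(f)[1L])
    msg <- c(msg, "frameTimes must have one entry per frame")
  if (is.unsorted(object@frameTimes, strictly = TRUE))
    msg <- c(msg, "frameTimes must be strictly increasing")
  if (length(object@stimOnset) != 1L || length(object@stimOffset) != 1L ||
      object@stimOnset >= object@stimOffset)
    msg <- c(msg, "stimOnset must precede stimOffset")
  if (sum(object@frameTimes < object@stimOnset) < 2L)
    msg <- c(msg, "need at least 2 frames strictly before stimOnset (baseline)")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a positive scalar (micrometers)")
  if (!object@orientation %in% c("top-left", "bottom-left"))
    msg <- c(msg, "orientation must be 'top-left' or 'bottom-left'")
  if (length(msg)) msg else TRUE
})

#' Construct a FluorescenceStack
#'
#' @param frames numeric 3-D array (time x rows x cols) of counts.
#' @param frameTimes numeric seconds, one per frame, strictly increasing.
#' @param stimOnset,stimOffset stimulus epoch in seconds.
#' @param pixelSize micrometers per pixel edge (default 10).
#' @param orientation which image half is the left/ipsilateral cord side.
#' @return A [FluorescenceStack-class] object.
#' @examples
#' st <- FluorescenceStack(array(1000, c(4, 2, 2)), frameTimes = 0:3,
#'                         stimOnset = 1.5, stimOffset = 2.5)
#' @export
FluorescenceStack <- function(frames, frameTimes, stimOnset, stimOffset,
                              pixelSize = 10, orientation = "top-left") {
  new("FluorescenceStack", frames = frames, frameTimes = as.numeric(frameTimes),
      stimOnset = stimOnset, stimOffset = stimOffset,
      pixelSize = pixelSize, orientation = orientation)
}

#' DffStack: fractional fluorescence change of a recording
#'
#' Per-pixel fractional change relative to the mean pre-stimulus fluorescence
#' F0, i.e. dF/F = (F - F0) / F0.  Stored unitless; rendered as percent only
#' at reporting boundaries.  Pixels whose baseline mean is zero (dead pixels,
#' dural vein) are masked: their dF/F is NA and they are excluded from every
#' downstream metric.
#'
#' @slot dff numeric 3-D array, same dimensions as the input frames.
#' @slot f0 numeric matrix of per-pixel baseline means (counts).
#' @slot valid logical matrix; FALSE where F0 = 0 (masked pixels).
#' @slot baselineWindow integer vector of frame indices used as baseline
#'   (1-based, closed).
#' @slot frameTimes,stimOnset,stimOffset,pixelSize,orientation carried over
#'   from the source [FluorescenceStack-class].
#'
#' @seealso [computeDff()], [roiTrace()], [areaOfExcitation()]
#' @export
setClass("DffStack",
  representation(
    dff            = "array",
    f0             = "matrix",
    valid          = "matrix",
    baselineWindow = "integer",
    frameTimes     = "numeric",
    stimOnset      = "numeric",
    stimOffset     = "numeric",
    pixelSize      = "numeric",
    orientation    = "character"
  )
)

setValidity("DffStack", function(object) {
  msg <- character()
  d <- dim(object@dff)
  if (length(d) != 3L)
    msg <- c(msg, "dff must be a 3-D array")
  if (!identical(dim(object@f0), d[2:3]) || !identical(dim(object@valid), d[2:3]))
    msg <- c(msg, "f0 and valid must be rows x cols matrices")
  if (length(object@frameTimes) != d[1L])
    msg <- c(msg, "frameTimes must have one entry per frame")
  if (length(object@baselineWindow) < 1L ||
      any(object@baselineWindow < 1L) || any(object@baselineWindow > d[1L]))
    msg <- c(msg, "baselineWindow indices out of range")
  if (length(msg)) msg else TRUE
})

#' Construct a DffStack directly
#'
#' Normally a `DffStack` is produced by [computeDff()]; this constructor
#' exists for simulation and testing, where a dF/F field is specified
#' directly.
#'
#' @param dff numeric 3-D array (time x rows x cols) of fractional change.
#' @param frameTimes,stimOnset,stimOffset,pixelSize,orientation as in
#'   [FluorescenceStack()].
#' @param f0 per-pixel baseline means; defaults to 1 everywhere.
#' @param valid logical validity mask; defaults to all TRUE.
#' @param baselineWindow integer frame indices of the baseline; defaults to
#'   the frames strictly before `stimOnset`.
#' @return A [DffStack-class] object.
#' @export
DffStack <- function(dff, frameTimes, stimOnset, stimOffset,
                     pixelSize = 10, orientation = "top-left",
                     f0 = NULL, valid = NULL, baselineWindow = NULL) {
  d <- dim(dff)
  if (is.null(f0)) f0 <- matrix(1, d[2L], d[3L])
  if (is.null(valid)) valid <- matrix(TRUE, d[2L], d[3L])
  if (is.null(baselineWindow)) baselineWindow <- which(frameTimes < stimOnset)
  new("DffStack", dff = dff, f0 = f0, valid = valid,
      baselineWindow = as.integer(baselineWindow),
      frameTimes = as.numeric(frameTimes), stimOnset = stimOnset,
      stimOffset = stimOffset, pixelSize = pixelSize,
      orientation = orientation)
}

#' PhaseSegmentation: light/dark phases of the biphasic AFI transient
#'
#' The flavoprotein fluorescence response to afferent stimulation is
#' biphasic: a steep increase immediately after stimulation onset (the light
#' phase, oxidation of mitochondrial flavoproteins) followed by a decrease
#' below baseline (the dark phase, reduction).  This class records the frame
#' ranges of both lobes for one dF/F trace.  Ranges are 1-based closed
#' integer intervals; an absent phase is `NA`.
#'
#' @slot lightStart,lightEnd first/last frame of the light phase (NA when no
#'   response was detected).
#' @slot darkStart,darkEnd first/last frame of the dark phase (NA when the
#'   trace never drops below the noise band).
#' @slot peakFrame frame of maximal dF/F within the light phase.
#' @slot troughFrame frame of minimal dF/F within the dark phase.
#' @slot band numeric; the detection band in dF/F units (k baseline SDs).
#' @slot noResponse logical; TRUE when the trace never exceeds the band.
#' @seealso [segmentPhases()]
#' @export
setClass("PhaseSegmentation",
  representation(
    lightStart  = "integer", lightEnd   = "integer",
    darkStart   = "integer", darkEnd    = "integer",
    peakFrame   = "integer", troughFrame = "integer",
    band        = "numeric", noResponse = "logical"
  )
)

setValidity("PhaseSegmentation", function(object) {
  msg <- character()
  if (!object@noResponse) {
    if (is.na(object@lightStart) || is.na(object@lightEnd) ||
        object@lightStart > object@lightEnd)
      msg <- c(msg, "light phase must be a non-empty range when a response exists")
    if (!is.na(object@peakFrame) &&
        (object@peakFrame < object@lightStart || object@peakFrame > object@lightEnd))
      msg <- c(msg, "peakFrame must lie inside the light phase")
    if (!is.na(object@darkStart) && object@darkStart <= object@lightEnd)
      msg <- c(msg, "dark phase must start after the light phase ends")
  }
  if (object@band < 0) msg <- c(msg, "band must be non-negative")
  if (length(msg)) msg else TRUE
})

#' RoiSpec: a square region of interest on the cord surface
#'
#' Square pixel selections (default 20 x 20) placed over the dorsal horn,
#' one per side, are the unit of trace extraction.  The side label must be
#' consistent with the stack's orientation: with `"top-left"` orientation an
#' ipsilateral ROI lies in the top image half.
#'
#' @slot center integer (row, col) of the ROI center.
#' @slot size integer edge length in pixels.
#' @slot side `"ipsilateral"` or `"contralateral"`.
#' @slot level free-text spinal level label, e.g. `"L4-6"`.
#' @seealso [roiTrace()], [afiIntensity()]
#' @export
setClass("RoiSpec",
  representation(center = "integer", size = "integer",
                 side = "character", level = "character")
)

setValidity("RoiSpec", function(object) {
  msg <- character()
  if (length(object@center) != 2L || any(object@center < 1L))
    msg <- c(msg, "center must be positive (row, col)")
  if (length(object@size) != 1L || object@size < 1L)
    msg <- c(msg, "size must be a positive integer")
  if (!object@side %in% c("ipsilateral", "contralateral"))
    msg <- c(msg, "side must be 'ipsilateral' or 'contralateral'")
  if (length(msg)) msg else TRUE
})

#' Construct an RoiSpec
#'
#' @param center numeric (row, col) center of the square ROI.
#' @param size edge length in pixels (default 20, the conventional square
#'   selection for spinal AFI).
#' @param side `"ipsilateral"` (stimulated) or `"contralateral"`.
#' @param level spinal level annotation (free text).
#' @return An [RoiSpec-class] object.
#' @examples
#' RoiSpec(c(16, 32), size = 10, side = "ipsilateral", level = "L4-6")
#' @export
RoiSpec <- function(center, size = 20, side = "ipsilateral", level = "") {
  new("RoiSpec", center = as.integer(center), size = as.integer(size),
      side = side, level = level)
}

#' AfiResponse: scalar outcomes of one AFI recording
#'
#' The two per-recording outcomes of the pipeline: AFI intensity (maximal
#' light-phase dF/F of the ROI-mean trace, in percent) and area of excitation
#' (number of pixels whose peak dF/F exceeds a fixed predefined level), plus
#' the phase segmentation they were derived from.
#'
#' @slot intensity percent dF/F; maximal light-phase ROI-mean response.
#' @slot areaPixels supra-threshold pixel count over the whole field.
#' @slot areaMm2 the same converted to mm^2 via the pixel size.
#' @slot ipsiPixels,contraPixels per-side split of `areaPixels` at the
#'   image midline.
#' @slot threshold percent dF/F level defining the area of excitation.
#' @slot segmentation the [PhaseSegmentation-class] of the ROI trace.
#' @slot noResponse TRUE when the ROI trace never exceeded the noise band;
#'   `intensity` is then the global post-onset maximum.
#' @slot nValidRoi number of unmasked pixels in the ROI.
#' @seealso [measureAfiResponse()]
#' @export
setClass("AfiResponse",
  representation(
    intensity    = "numeric", areaPixels  = "integer",
    areaMm2      = "numeric", ipsiPixels  = "integer",
    contraPixels = "integer", threshold   = "numeric",
    segmentation = "PhaseSegmentation",
    noResponse   = "logical", nValidRoi   = "integer"
  )
)

setValidity("AfiResponse", function(object) {
  msg <- character()
  if (object@areaPixels < 0L) msg <- c(msg, "areaPixels must be >= 0")
  if (!is.finite(object@intensity)) msg <- c(msg, "intensity must be finite")
  if (object@threshold <= 0) msg <- c(msg, "threshold must be > 0")
  if (length(msg)) msg else TRUE
})
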