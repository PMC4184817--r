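# ROI pixel index helpers ----------------------------------------------------

.roiRows <- function(roi, nr) {
  s <- roi@size
  r0 <- roi@center[1L] - (s - 1L) %/% 2L
  rows <- r0:(r0 + s - 1L)
  if (any(rows < 1L) || any(rows > nr)) stop("ROI exceeds image bounds (rows)")
  rows
}

.roiCols <- function(roi, nc) {
  s <- roi@size
  c0 <- roi@center[2L] - (s - 1L) %/% 2L
  cols <- c0:(c0 + s - 1L)
  if (any(cols < 1L) || any(cols > nc)) stop("ROI exceeds image bounds (cols)")
  cols
}

.checkRoiSide <- function(x, roi) {
  nr <- dim(x@dff)[2L]
  mid <- nr %/% 2L
  rows <- .roiRows(roi, nr)
  topHalf <- all(rows <= mid)
  botHalf <- all(rows > mid)
  ipsiTop <- x@orientation == "top-left"
  ok <- (roi@side == "ipsilateral" && ((ipsiTop && topHalf) || (!ipsiTop && botHalf))) ||
        (roi@side == "contralateral" && ((ipsiTop && botHalf) || (!ipsiTop && topHalf)))
  if (!ok)
    warning("ROI side label '", roi@side,
            "' is inconsistent with stack orientation '", x@orientation, "'")
  invisible(ok)
}

#' Extract the mean dF/F trace of a region of interest
#'
#' Per-frame mean of dF/F over the valid (unmasked) pixels of a square ROI.
#' Masked pixels are excluded from the mean; the count of valid pixels is
#' attached as attribute `nValid`.
#'
#' @param x a [DffStack-class].
#' @param roi an [RoiSpec-class].
#' @param checkSide warn if the ROI's side label contradicts the stack
#'   orientation (default TRUE).
#' @return numeric vector, one dF/F value per frame, with attribute
#'   `nValid`.
#' @export
roiTrace <- function(x, roi, checkSide = TRUE) {
  stopifnot(is(x, "DffStack"), is(roi, "RoiSpec"))
  d <- dim(x@dff)
  rows <- .roiRows(roi, d[2L])
  cols <- .roiCols(roi, d[3L])
  if (checkSide) .checkRoiSide(x, roi)
  v <- x@valid[rows, cols, drop = FALSE]
  n <- sum(v)
  if (n == 0L) stop("ROI has no valid pixels")
  sub <- x@dff[, rows, cols, drop = FALSE]
  dim(sub) <- c(d[1L], length(rows) * length(cols))
  tr <- rowSums(sub[, as.vector(v), drop = FALSE]) / n
  attr(tr, "nValid") <- n
  tr
}

#' AFI intensity of a region of interest
#'
#' The maximal dF/F of the ROI-mean trace during the light phase, reported
#' in percent.  When no light phase is detected (trace never exceeds the
#' noise band) the global post-onset maximum is returned instead and the
#' result carries attribute `noResponse = TRUE`.
#'
#' @inheritParams roiTrace
#' @param k noise-band multiplier passed to [segmentPhases()].
#' @return numeric scalar (percent dF/F) with attributes `noResponse`
#'   (logical) and `segmentation` (the [PhaseSegmentation-class]).
#' @examples
#' mv <- renderMovie(sceneParams(noiseScale = 0), seed = 1)
#' d <- computeDff(mv$stack)
#' afiIntensity(d, RoiSpec(mv$truth$blobCenters$ipsi, size = 10))
#' @export
afiIntensity <- function(x, roi, k = 2, checkSide = TRUE) {
  tr <- roiTrace(x, roi, checkSide = checkSide)
  seg <- segmentPhases(tr, x@frameTimes, x@stimOnset, k = k)
  if (seg@noResponse) {
    post <- which(x@frameTimes >= x@stimOnset)
    val <- 100 * max(tr[post])
  } else {
    val <- 100 * max(tr[seg@lightStart:seg@lightEnd])
  }
  attr(val, "noResponse") <- seg@noResponse
  attr(val, "segmentation") <- seg
  val
}

#' Area of excitation
#'
#' Number of valid pixels whose dF/F exceeds a fixed predefined level within
#' a frame window.  By default the per-pixel maximum over the window decides
#' membership ("max" mode, matching a definition of intensity as a maximum);
#' `mode = "peak-frame"` instead thresholds the single frame of peak mean
#' response.  A pixel whose value equals the threshold exactly does not
#' count ("above" is strict).  The count is split into ipsilateral and
#' contralateral halves at the image midline, and converted to mm^2 via the
#' pixel size.
#'
#' @param x a [DffStack-class].
#' @param threshold percent dF/F level (> 0); the same fixed level should be
#'   used across recordings of an experiment.  Default 0.25.
#' @param window integer frame indices; default the light phase of the
#'   whole-field mean trace (all post-onset frames when no response is
#'   detected).
#' @param midlineRow last row of the top half; default `nrow %/% 2`.
#' @param mode `"max"` (default) or `"peak-frame"`; see Details.
#' @param k noise-band multiplier used when deriving the default window.
#' @return list with `areaPixels`, `areaMm2`, `ipsiPixels`, `contraPixels`,
#'   `thresholdPct`, `window`, `mode`.
#' @export
areaOfExcitation <- function(x, threshold = 0.25, window = NULL,
                             midlineRow = NULL, mode = c("max", "peak-frame"),
                             k = 2) {
  stopifnot(is(x, "DffStack"))
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a positive scalar (percent dF/F)")
  d <- dim(x@dff)
  if (is.null(window)) {
    fieldTrace <- .fieldMeanTrace(x)
    seg <- segmentPhases(fieldTrace, x@frameTimes, x@stimOnset, k = k)
    window <- if (seg@noResponse) which(x@frameTimes >= x@stimOnset)
              else seg@lightStart:seg@lightEnd
  }
  window <- as.integer(window)
  if (length(window) == 0L) stop("window is empty")
  if (any(window < 1L) || any(window > d[1L]))
    stop("window indices out of range")

  thrFrac <- threshold / 100
  if (mode == "max") {
    px <- apply(x@dff[window, , , drop = FALSE], c(2, 3), max)
  } else {
    fieldTrace <- .fieldMeanTrace(x)
    pkf <- window[which.max(fieldTrace[window])]
    px <- x@dff[pkf, , ]
  }
  hit <- x@valid & !is.na(px) & px > thrFrac

  if (is.null(midlineRow)) midlineRow <- d[2L] %/% 2L
  topCount <- sum(hit[seq_len(midlineRow), , drop = FALSE])
  botCount <- sum(hit) - topCount
  if (x@orientation == "top-left") {
    ipsi <- topCount; contra <- botCount
  } else {
    ipsi <- botCount; contra <- topCount
  }
  list(areaPixels = as.integer(sum(hit)),
       areaMm2 = sum(hit) * (x@pixelSize / 1000)^2,
       ipsiPixels = as.integer(ipsi), contraPixels = as.integer(contra),
       thresholdPct = threshold, window = window, mode = mode)
}

.fieldMeanTrace <- function(x) {
  d <- dim(x@dff)
  flat <- x@dff
  dim(flat) <- c(d[1L], d[2L] * d[3L])
  v <- as.vector(x@valid)
  if (!any(v)) stop("stack has no valid pixels")
  rowSums(flat[, v, drop = FALSE]) / sum(v)
}

#' Full per-recording AFI response
#'
#' Combines [afiIntensity()] and [areaOfExcitation()] for one ROI into an
#' [AfiResponse-class]: the area window is the light phase of the ROI trace
#' (all post-onset frames under the no-response flag).
#'
#' @inheritParams afiIntensity
#' @param threshold percent dF/F level for the area of excitation.
#' @param midlineRow forwarded to [areaOfExcitation()].
#' @return An [AfiResponse-class].
#' @export
measureAfiResponse <- function(x, roi, threshold = 0.25, k = 2,
                               midlineRow = NULL, checkSide = TRUE) {
  tr <- roiTrace(x, roi, checkSide = checkSide)
  seg <- segmentPhases(tr, x@frameTimes, x@stimOnset, k = k)
  post <- which(x@frameTimes >= x@stimOnset)
  if (seg@noResponse) {
    inten <- 100 * max(tr[post])
    win <- post
  } else {
    inten <- 100 * max(tr[seg@lightStart:seg@lightEnd])
    win <- seg@lightStart:seg@lightEnd
  }
  ar <- areaOfExcitation(x, threshold = threshold, window = win,
                         midlineRow = midlineRow)
  new("AfiResponse", intensity = inten,
      areaPixels = ar$areaPixels, areaMm2 = ar$areaMm2,
      ipsiPixels = ar$ipsiPixels, contraPixels = ar$contraPixels,
      threshold = threshold, segmentation = seg,
      noResponse = seg@noResponse, nValidRoi = attr(tr, "nValid"))
}
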