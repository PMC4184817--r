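#' Convert a raw fluorescence stack to dF/F
#'
#' For every pixel, the baseline fluorescence F0 is the mean count over the
#' baseline window (by default, every frame strictly before stimulus onset),
#' and dF/F at frame t is `(F(t) - F0) / F0`.  Pixels with F0 = 0 (dead
#' pixels, the dural vein) are masked: their dF/F is NA and they are excluded
#' from all downstream metrics rather than interpolated.
#'
#' The result is unitless; multiply by 100 for percent.  By construction the
#' mean dF/F over the baseline window is zero for every valid pixel.
#'
#' @param stack a [FluorescenceStack-class].
#' @param baselineWindow integer vector of frame indices to use as baseline;
#'   default all frames with `frameTimes < stimOnset`.  Must be non-empty
#'   and lie entirely before stimulus onset.
#' @param smoothSigma optional Gaussian spatial smoothing SD in pixels
#'   applied to the dF/F frames (default 0 = off).
#' @return A [DffStack-class].
#' @examples
#' st <- FluorescenceStack(array(1000, c(4, 2, 2)), 0:3, 1.5, 2.5)
#' d <- computeDff(st)
#' range(dff(d))  # constant movie: identically zero
#' @export
setMethod("computeDff", "FluorescenceStack",
function(stack, baselineWindow = NULL, smoothSigma = 0) {
  ft <- stack@frameTimes
  if (is.null(baselineWindow))
    baselineWindow <- which(ft < stack@stimOnset)
  baselineWindow <- as.integer(baselineWindow)
  if (length(baselineWindow) == 0L)
    stop("no pre-stimulus frames: baseline window is empty")
  if (any(baselineWindow < 1L) || any(baselineWindow > dim(stack@frames)[1L]))
    stop("baseline window indices out of range")
  if (any(ft[baselineWindow] >= stack@stimOnset))
    stop("baseline window overlaps the stimulus epoch")

  f <- stack@frames
  d <- dim(f)
  f0 <- colMeans(f[baselineWindow, , , drop = FALSE], dims = 1)
  dim(f0) <- d[2:3]
  valid <- f0 > 0

  # (F - F0) / F0 broadcast over time; invalid pixels -> NA
  f0safe <- ifelse(valid, f0, NA_real_)
  out <- sweep(f, c(2, 3), f0safe, "-")
  out <- sweep(out, c(2, 3), f0safe, "/")

  if (smoothSigma > 0) {
    for (t in seq_len(d[1L]))
      out[t, , ] <- .gaussBlur2d(out[t, , ], smoothSigma, valid)
  }

  new("DffStack", dff = out, f0 = f0, valid = valid,
      baselineWindow = baselineWindow, frameTimes = ft,
      stimOnset = stack@stimOnset, stimOffset = stack@stimOffset,
      pixelSize = stack@pixelSize, orientation = stack@orientation)
})

# Separable Gaussian blur honoring the validity mask (masked pixels neither
# contribute nor receive).
.gaussBlur2d <- function(m, sigma, valid) {
  r <- ceiling(3 * sigma)
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  w <- matrix(0, nrow(m), ncol(m))
  acc <- matrix(0, nrow(m), ncol(m))
  m0 <- ifelse(valid, m, 0)
  v0 <- ifelse(valid, 1, 0)
  conv1 <- function(x, along) {
    out <- array(0, dim(x))
    for (i in seq_along(k)) {
      sh <- i - r - 1L
      if (along == 1L) {
        src <- max(1, 1 - sh):min(nrow(x), nrow(x) - sh)
        out[src + sh, ] <- out[src + sh, ] + k[i] * x[src, ]
      } else {
        src <- max(1, 1 - sh):min(ncol(x), ncol(x) - sh)
        out[, src + sh] <- out[, src + sh] + k[i] * x[, src]
      }
    }
    out
  }
  acc <- conv1(conv1(m0, 1L), 2L)
  w <- conv1(conv1(v0, 1L), 2L)
  res <- ifelse(valid & w > 0, acc / w, NA_real_)
  res
}

#' Segment a dF/F trace into light and dark phases
#'
#' The flavoprotein transient is biphasic: fluorescence rises steeply right
#' after stimulation onset (light phase) and subsequently falls below
#' baseline (dark phase).  Detection uses a noise band of `k` baseline
#' standard deviations: the light phase is the longest contiguous post-onset
#' run of samples strictly above the band; the dark phase is the first
#' contiguous run after the light phase strictly below minus the band.
#'
#' When the trace never exceeds the band the segmentation carries a
#' no-response flag rather than raising an error; downstream intensity
#' metrics then fall back to the global post-onset maximum.
#'
#' @param trace numeric dF/F time series (unitless).
#' @param frameTimes numeric seconds, one per sample.
#' @param stimOnset stimulus onset in seconds.
#' @param baselineWindow integer indices of baseline samples; default all
#'   samples strictly before `stimOnset`.
#' @param k band multiplier in baseline SDs (default 2).
#' @return A [PhaseSegmentation-class].
#' @examples
#' t <- seq(0, 30, 0.1)
#' tr <- biphasicKernel(pmax(t - 5, 0), a = 0.005)
#' seg <- segmentPhases(tr, t, stimOnset = 5)
#' seg
#' @export
segmentPhases <- function(trace, frameTimes, stimOnset,
                          baselineWindow = NULL, k = 2) {
  stopifnot(length(trace) == length(frameTimes))
  if (is.null(baselineWindow))
    baselineWindow <- which(frameTimes < stimOnset)
  if (length(baselineWindow) == 0L)
    stop("no pre-stimulus samples in trace")
  bsd <- stats::sd(trace[baselineWindow])
  band <- if (is.na(bsd)) 0 else k * bsd

  post <- which(frameTimes >= stimOnset)
  if (length(post) == 0L) stop("trace has no post-onset samples")

  runs <- function(idx, cond) {
    # contiguous runs (in index space of `idx`) where cond holds
    r <- rle(cond)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    lapply(keep, function(j) idx[starts[j]:ends[j]])
  }

  above <- runs(post, trace[post] > band)
  if (length(above) == 0L) {
    return(new("PhaseSegmentation",
               lightStart = NA_integer_, lightEnd = NA_integer_,
               darkStart = NA_integer_, darkEnd = NA_integer_,
               peakFrame = NA_integer_, troughFrame = NA_integer_,
               band = band, noResponse = TRUE))
  }
  light <- above[[which.max(lengths(above))]]
  pk <- light[which.max(trace[light])]

  afterIdx <- post[post > max(light)]
  dark <- if (length(afterIdx))
    runs(afterIdx, trace[afterIdx] < -band) else list()
  if (length(dark)) {
    dk <- dark[[1L]]
    tr <- dk[which.min(trace[dk])]
    new("PhaseSegmentation",
        lightStart = min(light), lightEnd = max(light),
        darkStart = min(dk), darkEnd = max(dk),
        peakFrame = pk, troughFrame = tr,
        band = band, noResponse = FALSE)
  } else {
    new("PhaseSegmentation",
        lightStart = min(light), lightEnd = max(light),
        darkStart = NA_integer_, darkEnd = NA_integer_,
        peakFrame = pk, troughFrame = NA_integer_,
        band = band, noResponse = FALSE)
  }
}
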