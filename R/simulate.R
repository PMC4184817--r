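#' Scene parameters for synthetic AFI movies
#'
#' Describes the synthetic imaging scene: geometry, time base, baseline
#' count level, noise/artifact layers and the temporal kernel.  Defaults are
#' test-scale (64 x 64 pixels at 10 frames/s) rather than the full 512 x 512
#' CCD format; all values are illustrative emulation choices, echoed into
#' the ground-truth sidecar of every rendered movie.
#'
#' The spatial response profile per side is a flat-top blob: 1 within
#' `coreRadius` of the blob center, Gaussian decay with SD `sigma` outside.
#' The flat core makes the realized peak dF/F at a centered ROI equal the
#' preset amplitude exactly, which is what ground-truth identifiability
#' checks rely on.
#'
#' @param dim image size `c(rows, cols)`.
#' @param pixelSize micrometers per pixel edge.
#' @param frameRate frames per second.
#' @param duration recording length, seconds.
#' @param stimOnset,stimOffset stimulus epoch, seconds.
#' @param baselineLevel mean baseline count level B (16-bit headroom).
#' @param noiseScale shot-noise scale: counts get additive Gaussian noise
#'   with SD `noiseScale * sqrt(expected counts)` (Poisson approximation);
#'   0 disables noise.
#' @param bleachRate photobleaching fraction per second (default 0).
#' @param ipsiAmp,contraAmp peak fractional dF/F per side.
#' @param blobCenters list with `ipsi` and `contra` `(row, col)` centers;
#'   default quarter-height points on the vertical midcolumn.
#' @param coreRadius flat-top radius of the activation blob, pixels.
#' @param sigma Gaussian shoulder SD, pixels.
#' @param veinRows image rows forced to `veinLevel` counts, emulating the
#'   dural vein running along the cord midline; default a 2-row central
#'   band.  `veinLevel = 0` (default) makes them masked dead pixels.
#' @param veinLevel constant count value of vein rows.
#' @param tau1,tau2,tau3,u temporal kernel constants, see
#'   [biphasicKernel()].
#' @param ampLimit amplitudes must satisfy `|a| < ampLimit` (default
#'   0.0075, the conventional +/-0.75 percent display range).
#' @return validated list of class `"SceneParams"`.
#' @export
sceneParams <- function(dim = c(64, 64), pixelSize = 10, frameRate = 10,
                        duration = 40, stimOnset = 5, stimOffset = 15,
                        baselineLevel = 20000, noiseScale = 0.4,
                        bleachRate = 0, ipsiAmp = 0.005, contraAmp = 0.002,
                        blobCenters = NULL, coreRadius = 8, sigma = 3,
                        veinRows = NULL, veinLevel = 0,
                        tau1 = 1, tau2 = 6, tau3 = 10, u = 0.6,
                        ampLimit = 0.0075) {
  stopifnot(length(dim) == 2L, all(dim >= 8), frameRate > 0, duration > 0,
            stimOnset < stimOffset, stimOnset > 0,
            baselineLevel > 0, baselineLevel <= 65535,
            noiseScale >= 0, bleachRate >= 0, coreRadius >= 0, sigma > 0,
            tau1 > 0, tau2 > 0, tau3 > 0, u >= 0, u < 1)
  if (abs(ipsiAmp) >= ampLimit || abs(contraAmp) >= ampLimit)
    stop("blob amplitude outside the +/-", 100 * ampLimit, "% display range")
  if (is.null(blobCenters))
    blobCenters <- list(ipsi   = c(round(dim[1] / 4), round(dim[2] / 2)),
                        contra = c(round(3 * dim[1] / 4), round(dim[2] / 2)))
  if (is.null(veinRows)) {
    mid <- dim[1] %/% 2L
    veinRows <- c(mid, mid + 1L)
  }
  structure(list(dim = as.integer(dim), pixelSize = pixelSize,
                 frameRate = frameRate, duration = duration,
                 stimOnset = stimOnset, stimOffset = stimOffset,
                 baselineLevel = baselineLevel, noiseScale = noiseScale,
                 bleachRate = bleachRate, ipsiAmp = ipsiAmp,
                 contraAmp = contraAmp, blobCenters = blobCenters,
                 coreRadius = coreRadius, sigma = sigma,
                 veinRows = as.integer(veinRows), veinLevel = veinLevel,
                 tau1 = tau1, tau2 = tau2, tau3 = tau3, u = u,
                 ampLimit = ampLimit),
            class = "SceneParams")
}

#' Effect presets for the synthetic experiments
#'
#' Named bundles of effect sizes for the emulated study arms.  Movie-level
#' amplitudes are fractional dF/F; cohort-level means are percent dF/F.
#' The palpation-naive ipsilateral amplitude is fixed at 0 (innocuous
#' palpation evokes no response in naive animals); the treatment presets
#' encode a strong post-treatment suppression with linear recovery at
#' 0.92 %/min after stimulation and a nominal 0.19 %/min drift, statistically
#' indistinguishable from zero at the preset noise level, after sham.
#'
#' Available presets: `"noxious-naive"`, `"noxious-neuropathic"`,
#' `"palpation-naive"`, `"palpation-neuropathic"`, `"scs"`, `"sham"`,
#' `"null"`.
#'
#' @param name preset name.
#' @return list of class `"EffectPreset"` with elements `name`, `movie`
#'   (ipsi/contra amplitudes), `cohort` (per-side intensity and area means
#'   and SDs, percent and pixels) and, for the treatment presets,
#'   `timecourse` (`s0`, `slope`, `betweenSd`, `withinSd`, `areaT0`,
#'   `areaT0Sd`).
#' @export
effectPreset <- function(name = c("noxious-naive", "noxious-neuropathic",
                                  "palpation-naive", "palpation-neuropathic",
                                  "scs", "sham", "null")) {
  name <- match.arg(name)
  movie <- switch(name,
    "noxious-naive"         = list(ipsiAmp = 0.005, contraAmp = 0.002),
    "noxious-neuropathic"   = list(ipsiAmp = 0.005, contraAmp = 0.002),
    "palpation-naive"       = list(ipsiAmp = 0,     contraAmp = 0),
    "palpation-neuropathic" = list(ipsiAmp = 0.003, contraAmp = 0),
    "scs"                   = list(ipsiAmp = 0.005, contraAmp = 0.002),
    "sham"                  = list(ipsiAmp = 0.005, contraAmp = 0.002),
    "null"                  = list(ipsiAmp = 0,     contraAmp = 0))
  cohort <- switch(name,
    "noxious-naive"       = list(intensityMean = c(ipsi = 0.50, contra = 0.45),
                                 intensitySd = 0.15,
                                 areaMean = c(ipsi = 300, contra = 280),
                                 areaSd = 100),
    "noxious-neuropathic" = list(intensityMean = c(ipsi = 0.50, contra = 0.45),
                                 intensitySd = 0.15,
                                 areaMean = c(ipsi = 300, contra = 280),
                                 areaSd = 100),
    "palpation-naive"       = list(intensityMean = c(ipsi = 0.00, contra = 0.05),
                                   intensitySd = 0.10,
                                   areaMean = c(ipsi = 0, contra = 10),
                                   areaSd = 15),
    "palpation-neuropathic" = list(intensityMean = c(ipsi = 0.30, contra = 0.05),
                                   intensitySd = 0.10,
                                   areaMean = c(ipsi = 120, contra = 10),
                                   areaSd = 40),
    "null" = list(intensityMean = c(ipsi = 0.30, contra = 0.30),
                  intensitySd = 0.10,
                  areaMean = c(ipsi = 150, contra = 150), areaSd = 50),
    NULL)
  timecourse <- switch(name,
    # Within-animal SDs fixed by inverting the target test statistics of the
    # emulated experiment (see the methods vignette): SCS slope 0.92 %/min
    # detected at p ~ 0.02, sham nominal slope 0.19 %/min with p ~ 0.7.
    "scs"  = list(s0 = 45,   slope = 0.92, betweenSd = 10, withinSd = 60,
                  areaT0 = 35,  areaT0Sd = 68),
    "sham" = list(s0 = 94.3, slope = 0.19, betweenSd = 10, withinSd = 85,
                  areaT0 = 100, areaT0Sd = 30),
    "null" = list(s0 = 100,  slope = 0,    betweenSd = 10, withinSd = 60,
                  areaT0 = 100, areaT0Sd = 30),
    NULL)
  structure(list(name = name, movie = movie, cohort = cohort,
                 timecourse = timecourse), class = "EffectPreset")
}

#' Render a synthetic AFI movie with ground truth
#'
#' Renders a [FluorescenceStack-class] as
#' `B * (1 - bleach * t) * (1 + k(t) * G(r, c)) + shot noise`, where `k` is
#' the [biphasicKernel()] rescaled to unit peak on the movie's frame grid
#' (so a preset amplitude `a` is the realized peak dF/F at the blob core)
#' and `G` is the per-side flat-top spatial profile.  Vein rows are set to a
#' constant low count.  With shot noise the counts are rounded and clipped
#' to the 16-bit range and the clipping fraction is reported; noiseless
#' renders keep continuous counts so ground truth survives to numerical
#' precision.
#'
#' @param scene a [sceneParams()] list.
#' @param effect optional [effectPreset()]; its movie amplitudes override
#'   the scene's.
#' @param seed integer seed (mandatory; the generator is a pure function of
#'   parameters and seed).
#' @param quantize round and clip counts to 16-bit integers; default
#'   (`NULL`) quantizes exactly when shot noise is present.
#' @return list with `stack` (a [FluorescenceStack-class]) and `truth`
#'   (ground-truth sidecar: realized amplitudes, blob geometry, kernel
#'   parameters, clip fraction, seed).
#' @examples
#' mv <- renderMovie(sceneParams(noiseScale = 0), seed = 1)
#' mv$truth$ipsiAmp
#' @export
renderMovie <- function(scene = sceneParams(), effect = NULL, seed,
                        quantize = NULL) {
  stopifnot(inherits(scene, "SceneParams"))
  if (missing(seed)) stop("seed is mandatory")
  if (!is.null(effect)) {
    stopifnot(inherits(effect, "EffectPreset"))
    scene$ipsiAmp <- effect$movie$ipsiAmp
    scene$contraAmp <- effect$movie$contraAmp
    if (abs(scene$ipsiAmp) >= scene$ampLimit ||
        abs(scene$contraAmp) >= scene$ampLimit)
      stop("preset amplitude outside the display range")
  }
  if (is.null(quantize)) quantize <- scene$noiseScale > 0
  set.seed(as.integer(seed))

  nFrames <- round(scene$duration * scene$frameRate)
  times <- (seq_len(nFrames) - 1) / scene$frameRate
  nr <- scene$dim[1L]; nc <- scene$dim[2L]

  kraw <- biphasicKernel(times - scene$stimOnset, a = 1, tau1 = scene$tau1,
                         tau2 = scene$tau2, tau3 = scene$tau3, u = scene$u)
  kmax <- max(kraw)
  if (kmax <= 0) stop("kernel has no positive lobe on the frame grid")
  kn <- kraw / kmax  # unit peak on the frame grid

  blobProfile <- function(center) {
    dr <- matrix(seq_len(nr) - center[1L], nr, nc)
    dc <- matrix(seq_len(nc) - center[2L], nr, nc, byrow = TRUE)
    d <- sqrt(dr^2 + dc^2)
    ifelse(d <= scene$coreRadius, 1,
           exp(-(d - scene$coreRadius)^2 / (2 * scene$sigma^2)))
  }
  G <- scene$ipsiAmp * blobProfile(scene$blobCenters$ipsi) +
       scene$contraAmp * blobProfile(scene$blobCenters$contra)

  # expected counts: time x rows x cols via outer structure
  bleach <- 1 - scene$bleachRate * times
  if (any(bleach <= 0)) stop("bleaching exhausts the signal within the recording")
  spatial <- as.vector(G)
  expected <- outer(bleach, rep(1, nr * nc)) * scene$baselineLevel *
    (1 + outer(kn, spatial))
  peak <- max(expected); low <- min(expected)
  if (peak > 65535 || low < 0)
    stop("expected dynamic range exceeds 16-bit headroom")

  if (scene$noiseScale > 0) {
    expected <- expected + stats::rnorm(length(expected)) *
      scene$noiseScale * sqrt(expected)
  }
  dim(expected) <- c(nFrames, nr, nc)
  if (length(scene$veinRows))
    expected[, scene$veinRows, ] <- scene$veinLevel

  clipFraction <- 0
  if (quantize) {
    expected <- round(expected)
    clipFraction <- mean(expected < 0 | expected > 65535)
    expected[expected < 0] <- 0
    expected[expected > 65535] <- 65535
  }

  stack <- FluorescenceStack(expected, frameTimes = times,
                             stimOnset = scene$stimOnset,
                             stimOffset = scene$stimOffset,
                             pixelSize = scene$pixelSize,
                             orientation = "top-left")
  truth <- list(seed = as.integer(seed), ipsiAmp = scene$ipsiAmp,
                contraAmp = scene$contraAmp,
                blobCenters = scene$blobCenters,
                coreRadius = scene$coreRadius, sigma = scene$sigma,
                kernel = list(tau1 = scene$tau1, tau2 = scene$tau2,
                              tau3 = scene$tau3, u = scene$u,
                              gridPeakScale = kmax),
                baselineLevel = scene$baselineLevel,
                noiseScale = scene$noiseScale,
                bleachRate = scene$bleachRate,
                veinRows = scene$veinRows, veinLevel = scene$veinLevel,
                quantize = quantize, clipFraction = clipFraction)
  list(stack = stack, truth = truth)
}

#' Simulate an SCS/sham treatment cohort time course
#'
#' Generates per-animal relative AFI responses (percent of the
#' before-treatment recording) at 5-minute timepoints after cessation of
#' spinal cord stimulation (SCS) or sham stimulation.  The before-treatment
#' timepoint is coded -30 min and is 100 by construction.  SCS animals
#' follow `s0 + slope * t + animal effect + noise`; sham animals the same
#' model with the sham preset's near-flat parameters.  Relative areas are
#' generated at T = 0 only (the before/after area comparison).
#'
#' @param nScs,nSham animals per arm (>= 2).
#' @param seed integer seed (mandatory).
#' @param scs,sham [effectPreset()] objects supplying `timecourse`
#'   parameters.
#' @param timepoints minutes after treatment cessation (default 0 to 60 by
#'   5).
#' @return long data.frame: `animal_id`, `group` (`"SCS"`/`"sham"`),
#'   `timepoint_min` (-30 = before), `relative_intensity`, `relative_area`
#'   (non-NA only at -30 and 0).
#' @examples
#' tc <- generateScsCohort(seed = 1)
#' timecourseRegression(subset(tc, group == "SCS"))
#' @export
generateScsCohort <- function(nScs = 7, nSham = 6, seed,
                              scs = effectPreset("scs"),
                              sham = effectPreset("sham"),
                              timepoints = seq(0, 60, by = 5)) {
  if (missing(seed)) stop("seed is mandatory")
  if (nScs < 2 || nSham < 2) stop("need at least 2 animals per arm")
  set.seed(as.integer(seed))
  simArm <- function(n, preset, group, prefix) {
    p <- preset$timecourse
    do.call(rbind, lapply(seq_len(n), function(i) {
      b <- stats::rnorm(1, 0, p$betweenSd)
      rel <- p$s0 + p$slope * timepoints + b +
        stats::rnorm(length(timepoints), 0, p$withinSd)
      areaT0 <- p$areaT0 + stats::rnorm(1, 0, p$areaT0Sd)
      data.frame(animal_id = sprintf("%s%d", prefix, i), group = group,
                 timepoint_min = c(-30, timepoints),
                 relative_intensity = c(100, rel),
                 relative_area = c(100, areaT0,
                                   rep(NA_real_, length(timepoints) - 1L)))
    }))
  }
  rbind(simArm(nScs, scs, "SCS", "SCS"),
        simArm(nSham, sham, "sham", "SHAM"))
}

#' Simulate per-animal AFI group outcomes
#'
#' Cohort-level generator for the group-comparison experiment: draws one AFI
#' intensity (percent dF/F) and one area of excitation (pixels) per animal
#' and side from the preset's Gaussian effect model, bypassing movie
#' rendering.  Used for the naive/neuropathic noxious contrast, the
#' palpation contrast, and null calibration.
#'
#' @param n animals.
#' @param preset an [effectPreset()] with a `cohort` element.
#' @param seed integer seed (mandatory).
#' @param idPrefix animal id prefix.
#' @param typeLabel group label for the `type` column; defaults to the
#'   preset name.  Letting the label differ from the preset allows null
#'   calibration runs where both groups share one distribution.
#' @return data.frame: `animal_id`, `type`, `side`, `intensity_pct`,
#'   `area_px`.
#' @export
generateAfiCohort <- function(n, preset, seed, idPrefix = "A",
                              typeLabel = preset$name) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(inherits(preset, "EffectPreset"), n >= 1)
  if (is.null(preset$cohort))
    stop("preset '", preset$name, "' has no cohort-level effect model")
  set.seed(as.integer(seed))
  p <- preset$cohort
  sides <- c("ipsilateral", "contralateral")
  out <- expand.grid(animal_id = sprintf("%s%d", idPrefix, seq_len(n)),
                     side = sides, stringsAsFactors = FALSE)
  key <- ifelse(out$side == "ipsilateral", "ipsi", "contra")
  out$type <- typeLabel
  out$intensity_pct <- p$intensityMean[key] +
    stats::rnorm(nrow(out), 0, p$intensitySd)
  out$area_px <- pmax(0, p$areaMean[key] + stats::rnorm(nrow(out), 0, p$areaSd))
  rownames(out) <- NULL
  out[, c("animal_id", "type", "side", "intensity_pct", "area_px")]
}

#' Default parameters of the behavioral generator
#'
#' Baseline von Frey thresholds and hotplate latencies, the neuropathy
#' effect sizes, and the noise structure of the synthetic behavioral cohort.
#' Baseline values and post-operative drops are chosen so that noiseless
#' simulation lands exactly on filament forces (15 g baseline dropping to
#' 4 g; 12 s latency dropping to 7 s), emulating pronounced tactile and
#' thermal hypersensitivity after partial sciatic nerve ligation.
#'
#' @param vfBaseline baseline latent von Frey threshold, grams.
#' @param vfDrop post-operative latent drop under neuropathy, grams.
#' @param vfBetweenSd,vfWithinSd between/within-animal SDs, grams.
#' @param hpBaseline baseline hotplate latency, seconds.
#' @param hpDrop post-operative latency drop under neuropathy, seconds.
#' @param hpBetweenSd,hpWithinSd between/within-animal SDs, seconds.
#' @param days testing days (0 = pre-operative baseline).
#' @param filaments ascending filament force series, grams.
#' @return list of class `"BehaviorParams"`.
#' @export
behaviorParams <- function(vfBaseline = 15, vfDrop = 11,
                           vfBetweenSd = 1.5, vfWithinSd = 2,
                           hpBaseline = 12, hpDrop = 5,
                           hpBetweenSd = 1, hpWithinSd = 1.5,
                           days = c(0, 10, 12, 14),
                           filaments = stoeltingFilaments()) {
  stopifnot(vfBaseline > 0, hpBaseline > 0, length(days) >= 2,
            all(diff(filaments) > 0), all(filaments > 0))
  structure(list(vfBaseline = vfBaseline, vfDrop = vfDrop,
                 vfBetweenSd = vfBetweenSd, vfWithinSd = vfWithinSd,
                 hpBaseline = hpBaseline, hpDrop = hpDrop,
                 hpBetweenSd = hpBetweenSd, hpWithinSd = hpWithinSd,
                 days = days, filaments = filaments),
            class = "BehaviorParams")
}

#' Simulate a behavioral cohort
#'
#' Draws von Frey thresholds and hotplate latencies for `n` animals across
#' the testing days.  Under `neuropathy = TRUE` the post-operative days get
#' the configured latent drops; thresholds are snapped to the nearest
#' filament force (censored high above the largest filament) and latencies
#' censored at 30 s via [hotplateLatency()].
#'
#' @param n animals (>= 1).
#' @param neuropathy apply the post-operative effect (default TRUE).
#' @param seed integer seed (mandatory).
#' @param params a [behaviorParams()] list.
#' @return long data.frame: `animal_id`, `group`, `day`, `vf_threshold`,
#'   `vf_censored`, `hp_latency`, `hp_censored`.
#' @export
generateBehaviorCohort <- function(n, neuropathy = TRUE, seed,
                                   params = behaviorParams()) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n >= 1, inherits(params, "BehaviorParams"))
  set.seed(as.integer(seed))
  p <- params
  nd <- length(p$days)
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    bvf <- stats::rnorm(1, 0, p$vfBetweenSd)
    bhp <- stats::rnorm(1, 0, p$hpBetweenSd)
    postDrop <- as.numeric(p$days > 0) * neuropathy
    vfLatent <- p$vfBaseline + bvf - postDrop * p$vfDrop +
      stats::rnorm(nd, 0, p$vfWithinSd)
    hpLatent <- p$hpBaseline + bhp - postDrop * p$hpDrop +
      stats::rnorm(nd, 0, p$hpWithinSd)
    hpLatent <- pmax(hpLatent, 0.5)  # reaction times are physically positive
    vf <- vapply(vfLatent, function(x) .snapToFilament(x, p$filaments),
                 numeric(2))
    hp <- vapply(hpLatent, function(x) {
      h <- hotplateLatency(x); c(h$latency, h$censored)
    }, numeric(2))
    data.frame(animal_id = sprintf("B%d", i),
               group = if (neuropathy) "neuropathic" else "control",
               day = p$days,
               vf_threshold = vf[1, ], vf_censored = as.logical(vf[2, ]),
               hp_latency = hp[1, ], hp_censored = as.logical(hp[2, ]))
  }))
  rownames(out) <- NULL
  out
}

# Snap a latent threshold to the filament series: nearest force; above the
# largest filament -> censored high at the maximum force.
.snapToFilament <- function(x, filaments) {
  if (x > max(filaments)) return(c(max(filaments), 1))
  x <- max(x, min(filaments))
  c(filaments[which.min(abs(filaments - x))], 0)
}
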