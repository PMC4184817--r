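#' Write a FluorescenceStack as 16-bit multi-page TIFF plus sidecar
#'
#' Counts are quantized to 16-bit integers in the TIFF; the YAML sidecar
#' carries the time base, stimulus epoch, pixel size and orientation.
#'
#' @param stack a [FluorescenceStack-class].
#' @param tiffPath output TIFF path.
#' @param configPath output YAML sidecar path; default `tiffPath` with a
#'   `.yaml` extension.
#' @return invisibly, the sidecar path.
#' @export
writeFluorescenceStack <- function(stack, tiffPath, configPath = NULL) {
  if (is.null(configPath)) configPath <- sub("\\.tiff?$", ".yaml", tiffPath)
  f <- stack@frames
  pages <- lapply(seq_len(dim(f)[1L]), function(t)
    round(f[t, , ]) / 65535)
  tiff::writeTIFF(pages, tiffPath, bits.per.sample = 16,
                  compression = "none")
  yaml::write_yaml(list(frame_times = as.numeric(stack@frameTimes),
                        stim_onset = stack@stimOnset,
                        stim_offset = stack@stimOffset,
                        pixel_size_um = stack@pixelSize,
                        orientation = stack@orientation),
                   configPath)
  invisible(configPath)
}

#' Read a FluorescenceStack from TIFF plus sidecar
#'
#' The sidecar must provide either `frame_times` (seconds per frame) or a
#' fixed `frame_interval_s`, plus `stim_onset`, `stim_offset`,
#' `pixel_size_um` and `orientation`.
#'
#' @param tiffPath 16-bit grayscale multi-page TIFF.
#' @param configPath YAML sidecar; default `tiffPath` with `.yaml`
#'   extension.
#' @return a [FluorescenceStack-class].
#' @export
readFluorescenceStack <- function(tiffPath, configPath = NULL) {
  if (is.null(configPath)) configPath <- sub("\\.tiff?$", ".yaml", tiffPath)
  cfg <- yaml::read_yaml(configPath)
  pages <- tiff::readTIFF(tiffPath, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nT <- length(pages)
  d <- dim(pages[[1L]])
  f <- array(0, c(nT, d[1L], d[2L]))
  for (t in seq_len(nT)) f[t, , ] <- pages[[t]]
  ft <- if (!is.null(cfg$frame_times)) as.numeric(cfg$frame_times)
        else (seq_len(nT) - 1) * cfg$frame_interval_s
  FluorescenceStack(f, frameTimes = ft, stimOnset = cfg$stim_onset,
                    stimOffset = cfg$stim_offset,
                    pixelSize = cfg$pixel_size_um,
                    orientation = cfg$orientation)
}

#' Write a dF/F stack as 32-bit float TIFF plus sidecar
#'
#' Signed dF/F values are affinely rescaled into [0, 1] for storage (the
#' 32-bit float TIFF writer clamps values outside that range); the scale and
#' offset are recorded in the sidecar so [readDffStack()] restores the
#' original values to float32 precision.  Masked pixels are stored as the
#' minimum and restored to NA via the mask in the sidecar.
#'
#' @param x a [DffStack-class].
#' @param tiffPath output TIFF path.
#' @param configPath output YAML sidecar path; default derived from
#'   `tiffPath`.
#' @return invisibly, the sidecar path.
#' @export
writeDffStack <- function(x, tiffPath, configPath = NULL) {
  if (is.null(configPath)) configPath <- sub("\\.tiff?$", ".yaml", tiffPath)
  d <- x@dff
  rng <- range(d, na.rm = TRUE)
  span <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(d)[1L]), function(t) {
    m <- (d[t, , ] - rng[1]) / span
    m[is.na(m)] <- 0
    m
  })
  tiff::writeTIFF(pages, tiffPath, bits.per.sample = 32,
                  compression = "none")
  yaml::write_yaml(list(dff_min = rng[1], dff_span = span,
                        frame_times = as.numeric(x@frameTimes),
                        stim_onset = x@stimOnset, stim_offset = x@stimOffset,
                        pixel_size_um = x@pixelSize,
                        orientation = x@orientation,
                        baseline_window = as.integer(x@baselineWindow),
                        invalid_pixels = which(!x@valid)),
                   configPath)
  invisible(configPath)
}

#' Read a dF/F stack written by [writeDffStack()]
#'
#' @param tiffPath 32-bit float TIFF.
#' @param configPath YAML sidecar; default derived from `tiffPath`.
#' @return a [DffStack-class] (baseline F0 is not stored; it is restored
#'   as 1 on valid pixels).
#' @export
readDffStack <- function(tiffPath, configPath = NULL) {
  if (is.null(configPath)) configPath <- sub("\\.tiff?$", ".yaml", tiffPath)
  cfg <- yaml::read_yaml(configPath)
  pages <- tiff::readTIFF(tiffPath, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nT <- length(pages)
  dims <- dim(pages[[1L]])
  d <- array(0, c(nT, dims[1L], dims[2L]))
  for (t in seq_len(nT))
    d[t, , ] <- pages[[t]] * cfg$dff_span + cfg$dff_min
  valid <- matrix(TRUE, dims[1L], dims[2L])
  if (length(cfg$invalid_pixels)) {
    valid[cfg$invalid_pixels] <- FALSE
    for (t in seq_len(nT)) { m <- d[t, , ]; m[!valid] <- NA; d[t, , ] <- m }
  }
  DffStack(d, frameTimes = as.numeric(cfg$frame_times),
           stimOnset = cfg$stim_onset, stimOffset = cfg$stim_offset,
           pixelSize = cfg$pixel_size_um, orientation = cfg$orientation,
           valid = valid,
           baselineWindow = as.integer(cfg$baseline_window))
}

#' Write an ROI trace as CSV
#'
#' Two columns: `time_s` and `dff` (unitless fractional change).
#'
#' @param trace numeric dF/F trace (as from [roiTrace()]).
#' @param frameTimes seconds, one per sample.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeRoiTraceCsv <- function(trace, frameTimes, path) {
  utils::write.csv(data.frame(time_s = frameTimes, dff = as.numeric(trace)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format treatment time-course CSV
#'
#' Expected columns: `animal_id`, `group`, `timepoint_min`,
#' `relative_intensity` and optionally `relative_area`.  Rows with
#' non-numeric or missing mandatory fields are rejected with the offending
#' data line number (header = line 1).
#'
#' @param path CSV path.
#' @return data.frame in the [generateScsCohort()] schema.
#' @export
readTimecourseCsv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("animal_id", "group", "timepoint_min", "relative_intensity")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("time-course CSV is missing column(s): ", paste(miss, collapse = ", "))
  numOrNa <- function(x) suppressWarnings(as.numeric(x))
  tp <- numOrNa(d$timepoint_min)
  ri <- numOrNa(d$relative_intensity)
  bad <- which(is.na(tp) | d$animal_id == "" |
               (is.na(ri) & d$relative_intensity != "" &
                !toupper(d$relative_intensity) %in% "NA"))
  if (length(bad))
    stop("corrupted time-course CSV row at line ", bad[1L] + 1L,
         " of ", basename(path))
  d$timepoint_min <- tp
  d$relative_intensity <- ri
  if ("relative_area" %in% names(d))
    d$relative_area <- numOrNa(d$relative_area)
  d
}

#' Read a wide-format behavioral table
#'
#' Wide schema: `animal_id`, `group`, then `VF<day>` and `HP<day>` columns
#' (von Frey grams, hotplate seconds), e.g. `VF0, VF10, VF12, VF14`.
#' Returns the long format used by [rmAnovaDays()].
#'
#' @param path CSV path.
#' @return long data.frame: `animal_id`, `group`, `day`, `vf_threshold`,
#'   `hp_latency`, `hp_censored`.
#' @export
readBehaviorWideCsv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  vfCols <- grep("^VF[0-9]+$", names(d), value = TRUE)
  hpCols <- grep("^HP[0-9]+$", names(d), value = TRUE)
  if (!length(vfCols) || !length(hpCols))
    stop("behavioral CSV must contain VF<day> and HP<day> columns")
  days <- sort(unique(as.integer(c(sub("VF", "", vfCols), sub("HP", "", hpCols)))))
  out <- do.call(rbind, lapply(days, function(dy) {
    hp <- d[[paste0("HP", dy)]]
    data.frame(animal_id = d$animal_id, group = d$group, day = dy,
               vf_threshold = d[[paste0("VF", dy)]],
               hp_latency = pmin(hp, 30), hp_censored = hp >= 30)
  }))
  out[order(out$animal_id, out$day), ]
}

#' Write a per-recording AFI report CSV
#'
#' One row per recording/ROI with the schema `recording_id, side,
#' roi_center_row, roi_center_col, intensity_pct, area_pixels, area_mm2,
#' threshold_pct, no_response, light_phase_start_s, light_phase_end_s`.
#'
#' @param responses list of [AfiResponse-class] objects.
#' @param rois list of matching [RoiSpec-class] objects.
#' @param frameTimes seconds per frame of the source recording(s) (one
#'   vector, or a list parallel to `responses`).
#' @param recordingIds character ids, one per response.
#' @param path output CSV path.
#' @return the report data.frame, invisibly written to `path`.
#' @export
writeAfiReportCsv <- function(responses, rois, frameTimes, recordingIds, path) {
  stopifnot(length(responses) == length(rois),
            length(responses) == length(recordingIds))
  ftList <- if (is.list(frameTimes)) frameTimes
            else rep(list(frameTimes), length(responses))
  rows <- lapply(seq_along(responses), function(i) {
    r <- responses[[i]]; roi <- rois[[i]]; ft <- ftList[[i]]
    seg <- r@segmentation
    data.frame(recording_id = recordingIds[i], side = roi@side,
               roi_center_row = roi@center[1L], roi_center_col = roi@center[2L],
               intensity_pct = r@intensity, area_pixels = r@areaPixels,
               area_mm2 = r@areaMm2, threshold_pct = r@threshold,
               no_response = r@noResponse,
               light_phase_start_s = if (seg@noResponse) NA_real_
                                     else ft[seg@lightStart],
               light_phase_end_s = if (seg@noResponse) NA_real_
                                   else ft[seg@lightEnd])
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a pipeline run: package version,
#' seed, timestamp and the full option set.
#'
#' @param config named list of run options (must include `seed`).
#' @param path output YAML path.
#' @return invisibly, `path`.
#' @export
writeRunManifest <- function(config, path) {
  manifest <- list(package = "spinalAFI",
                   version = as.character(utils::packageVersion("spinalAFI")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = config)
  yaml::write_yaml(manifest, path)
  invisible(path)
}
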