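#' Group-comparison experiment: naive vs neuropathic AFI responses
#'
#' Runs the first emulated experiment end to end: AFI intensities and areas
#' of excitation of naive and neuropathic animals after noxious electrical
#' sciatic-nerve stimulation are compared by two-way ANOVA (animal type x
#' cord side), and responses to innocuous palpation by unpaired t-tests per
#' side.  Inputs come either from per-animal CSV tables (config fields
#' `noxiousCsv` / `palpationCsv` in the [generateAfiCohort()] schema) or
#' from the synthetic generator presets.
#'
#' @param config named list: `seed` (mandatory for generated data),
#'   `nNaive` (default 20), `nNeuropathic` (13), `nPalpation` (5 per group),
#'   `ssType` (2), `welch` (TRUE), optional `noxiousCsv`, `palpationCsv`,
#'   `outDir`.
#' @return list with `noxious` (the per-animal table), `palpation`,
#'   `anovaIntensity`, `anovaArea`, `palpationIpsi`, `palpationContra` and
#'   `config`.  With `outDir` set, CSV reports and a YAML manifest are
#'   written there.
#' @examples
#' rep1 <- runExperiment1(list(seed = 1))
#' rep1$palpationIpsi$p
#' @export
runExperiment1 <- function(config = list()) {
  cfg <- utils::modifyList(
    list(seed = NULL, nNaive = 20, nNeuropathic = 13, nPalpation = 5,
         ssType = 2, welch = TRUE,
         noxiousPresetNaive = "noxious-naive",
         noxiousPresetNeuropathic = "noxious-neuropathic",
         palpationPresetNaive = "palpation-naive",
         palpationPresetNeuropathic = "palpation-neuropathic",
         noxiousCsv = NULL, palpationCsv = NULL, outDir = NULL),
    config)

  readArm <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(cfg$noxiousCsv)) {
    nox <- readArm(cfg$noxiousCsv)
  } else {
    if (is.null(cfg$seed)) stop("config$seed is required to generate data")
    nox <- rbind(
      generateAfiCohort(cfg$nNaive, effectPreset(cfg$noxiousPresetNaive),
                        seed = cfg$seed, idPrefix = "N",
                        typeLabel = "naive"),
      generateAfiCohort(cfg$nNeuropathic,
                        effectPreset(cfg$noxiousPresetNeuropathic),
                        seed = cfg$seed + 1L, idPrefix = "S",
                        typeLabel = "neuropathic"))
  }
  if (!is.null(cfg$palpationCsv)) {
    palp <- readArm(cfg$palpationCsv)
  } else {
    if (is.null(cfg$seed)) stop("config$seed is required to generate data")
    palp <- rbind(
      generateAfiCohort(cfg$nPalpation, effectPreset(cfg$palpationPresetNaive),
                        seed = cfg$seed + 2L, idPrefix = "PN",
                        typeLabel = "naive"),
      generateAfiCohort(cfg$nPalpation,
                        effectPreset(cfg$palpationPresetNeuropathic),
                        seed = cfg$seed + 3L, idPrefix = "PS",
                        typeLabel = "neuropathic"))
  }
  for (arm in c("nox", "palp")) {
    d <- get(arm)
    if (length(unique(d$type)) < 2L)
      stop("experiment arm '", arm, "' is missing a group: found only '",
           unique(d$type)[1], "'")
  }

  anovaI <- groupAnova(nox, "intensity_pct", ssType = cfg$ssType)
  anovaA <- groupAnova(nox, "area_px", ssType = cfg$ssType)
  contrastSide <- function(sideName) {
    types <- unique(palp$type)
    naiveType <- grep("naive", types, value = TRUE)[1]
    neuroType <- setdiff(types, naiveType)[1]
    palpationContrast(
      palp$intensity_pct[palp$type == naiveType & palp$side == sideName],
      palp$intensity_pct[palp$type == neuroType & palp$side == sideName],
      welch = cfg$welch)
  }
  res <- list(noxious = nox, palpation = palp,
              anovaIntensity = anovaI, anovaArea = anovaA,
              palpationIpsi = contrastSide("ipsilateral"),
              palpationContra = contrastSide("contralateral"),
              config = cfg)

  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(nox, file.path(cfg$outDir, "noxious_afi.csv"),
                     row.names = FALSE)
    utils::write.csv(palp, file.path(cfg$outDir, "palpation_afi.csv"),
                     row.names = FALSE)
    stats <- rbind(
      cbind(endpoint = "intensity", anovaI),
      cbind(endpoint = "area", anovaA))
    utils::write.csv(stats, file.path(cfg$outDir, "experiment1_anova.csv"),
                     row.names = FALSE)
    utils::write.csv(rbind(cbind(side = "ipsilateral", res$palpationIpsi),
                           cbind(side = "contralateral", res$palpationContra)),
                     file.path(cfg$outDir, "experiment1_palpation.csv"),
                     row.names = FALSE)
    writeRunManifest(cfg, file.path(cfg$outDir, "experiment1_manifest.yaml"))
    .writeExperiment1Text(res, file.path(cfg$outDir, "experiment1_report.txt"))
  }
  res
}

.writeExperiment1Text <- function(res, path) {
  con <- file(path, "w"); on.exit(close(con))
  fmt <- function(df) paste(utils::capture.output(print(df, row.names = FALSE)),
                            collapse = "\n")
  writeLines(c(
    "Experiment 1: AFI responses in naive vs neuropathic animals",
    "",
    "Two-way ANOVA (type x side), AFI intensity:", fmt(res$anovaIntensity), "",
    "Two-way ANOVA (type x side), area of excitation:", fmt(res$anovaArea), "",
    "Palpation contrast, ipsilateral:", fmt(res$palpationIpsi), "",
    "Palpation contrast, contralateral:", fmt(res$palpationContra)), con)
}

#' Treatment experiment: AFI time course after SCS vs sham
#'
#' Runs the second emulated experiment: relative AFI responses (percent of
#' before-treatment) after 30 minutes of spinal cord stimulation or sham,
#' recorded at T = 0 and every 5 minutes up to an hour.  Per arm it computes
#' the paired before/after tests at T = 0 (intensity and area) and the OLS
#' recovery slope of the mean relative intensity over 0-60 min with
#' Pearson's r and p.
#'
#' @param config named list: `seed` (mandatory for generated data), `nScs`
#'   (7), `nSham` (6), `tRange` (`c(0, 60)`), `regressionMode`
#'   (`"means"`), optional `timecourseCsv` (long CSV in the
#'   [generateScsCohort()] schema) and `outDir`.
#' @return list with `timecourse` (the per-animal table), per-arm
#'   `beforeAfterIntensity`, `beforeAfterArea`, `regression`, and `config`.
#' @examples
#' rep2 <- runExperiment2(list(seed = 1))
#' rep2$regression
#' @export
runExperiment2 <- function(config = list()) {
  cfg <- utils::modifyList(
    list(seed = NULL, nScs = 7, nSham = 6, tRange = c(0, 60),
         regressionMode = "means", scsPreset = "scs", shamPreset = "sham",
         timecourseCsv = NULL, outDir = NULL),
    config)
  if (!is.null(cfg$timecourseCsv)) {
    tc <- readTimecourseCsv(cfg$timecourseCsv)
  } else {
    if (is.null(cfg$seed)) stop("config$seed is required to generate data")
    tc <- generateScsCohort(cfg$nScs, cfg$nSham, seed = cfg$seed,
                            scs = effectPreset(cfg$scsPreset),
                            sham = effectPreset(cfg$shamPreset))
  }
  arms <- unique(tc$group)
  perArm <- lapply(arms, function(g) {
    arm <- tc[tc$group == g, ]
    list(beforeAfterIntensity = beforeAfterTest(arm, "intensity"),
         beforeAfterArea = if (all(is.na(arm$relative_area))) NULL
                           else beforeAfterTest(arm, "area"),
         regression = timecourseRegression(arm, tRange = cfg$tRange,
                                           mode = cfg$regressionMode))
  })
  names(perArm) <- arms
  regTab <- do.call(rbind, lapply(arms, function(g)
    cbind(group = g, perArm[[g]]$regression)))
  res <- list(timecourse = tc, arms = perArm, regression = regTab,
              config = cfg)

  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tc, file.path(cfg$outDir, "timecourse.csv"),
                     row.names = FALSE)
    utils::write.csv(regTab, file.path(cfg$outDir, "experiment2_regression.csv"),
                     row.names = FALSE)
    ba <- do.call(rbind, lapply(arms, function(g) rbind(
      cbind(group = g, metric = "intensity", perArm[[g]]$beforeAfterIntensity),
      if (!is.null(perArm[[g]]$beforeAfterArea))
        cbind(group = g, metric = "area", perArm[[g]]$beforeAfterArea))))
    utils::write.csv(ba, file.path(cfg$outDir, "experiment2_before_after.csv"),
                     row.names = FALSE)
    writeRunManifest(cfg, file.path(cfg$outDir, "experiment2_manifest.yaml"))
  }
  res
}

#' Behavioral statistics across testing days
#'
#' Convenience wrapper running [rmAnovaDays()] for both endpoints of a
#' behavioral cohort (von Frey threshold and hotplate latency).
#'
#' @param records long data.frame as from [generateBehaviorCohort()] or
#'   [readBehaviorWideCsv()].
#' @param gg apply Greenhouse-Geisser correction (default FALSE).
#' @return list with `vonFrey` and `hotplate`, each as returned by
#'   [rmAnovaDays()].
#' @export
behaviorStats <- function(records, gg = FALSE) {
  list(vonFrey = rmAnovaDays(records, "vf_threshold", gg = gg),
       hotplate = rmAnovaDays(records, "hp_latency", gg = gg))
}
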