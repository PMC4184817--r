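#' Relative response as percent of before-treatment
#'
#' `100 * after / before` for a response metric (AFI intensity or area of
#' excitation).  Baselines with magnitude below `floor` make the ratio
#' undefined: the result is NA with a warning, and such animals are excluded
#' from group means downstream.
#'
#' @param before,after numeric response values (same units), vectorized.
#' @param floor smallest usable baseline magnitude (default 1e-8).
#' @return numeric percent of before-treatment (NA where undefined).
#' @examples
#' relativeResponse(0.50, 0.30)  # 60
#' @export
relativeResponse <- function(before, after, floor = 1e-8) {
  stopifnot(length(before) == length(after), floor >= 0)
  bad <- !is.na(before) & abs(before) < floor
  if (any(bad)) {
    warning(sum(bad), " baseline value(s) below the floor of ", floor,
            "; relative response undefined (NA)")
    before[bad] <- NA_real_
  }
  100 * after / before
}

#' OLS recovery slope of a treatment time course
#'
#' Ordinary least-squares fit of relative AFI response against time in
#' minutes over the post-treatment window.  In the default `"means"` mode
#' the fit is to the per-timepoint cohort mean (animals averaged at each
#' timepoint, missing values dropped pairwise), matching reporting of mean
#' trajectories; `"pooled"` fits all animal-by-timepoint points as a
#' sensitivity analysis.  Pearson's r and the two-sided p-value for a
#' nonzero slope accompany the estimate.
#'
#' A response constant across timepoints has no estimable trend: slope 0,
#' r = 0, p = 1 by convention.
#'
#' @param cohort long data.frame with columns `timepoint_min`, a value
#'   column, and (for `"means"`) any per-animal replication.
#' @param metric name of the value column (default `"relative_intensity"`).
#' @param tRange inclusive time window in minutes (default `c(0, 60)`).
#' @param mode `"means"` (default) or `"pooled"`.
#' @return one-row data.frame: `slope` (percent per minute), `intercept`,
#'   `r`, `p`, `n` (points entering the fit), `mode`.
#' @export
timecourseRegression <- function(cohort, metric = "relative_intensity",
                                 tRange = c(0, 60),
                                 mode = c("means", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(all(c("timepoint_min", metric) %in% names(cohort)))
  d <- cohort[cohort$timepoint_min >= tRange[1] &
              cohort$timepoint_min <= tRange[2] &
              !is.na(cohort[[metric]]), ]
  if (mode == "means") {
    agg <- stats::aggregate(d[[metric]], by = list(t = d$timepoint_min), FUN = mean)
    tt <- agg$t; yy <- agg$x
  } else {
    tt <- d$timepoint_min; yy <- d[[metric]]
  }
  if (length(unique(tt)) < 3L)
    stop("need at least 3 distinct timepoints for the regression")
  if (stats::sd(yy) == 0) {
    return(data.frame(slope = 0, intercept = yy[1], r = 0, p = 1,
                      n = length(yy), mode = mode))
  }
  fit <- stats::lm(yy ~ tt)
  sm <- summary(fit)$coefficients
  p <- if (nrow(sm) < 2 || is.nan(sm[2, 4])) 1 else sm[2, 4]
  data.frame(slope = unname(stats::coef(fit)[2L]),
             intercept = unname(stats::coef(fit)[1L]),
             r = stats::cor(tt, yy), p = p, n = length(yy), mode = mode)
}

#' Monte-Carlo sweep of recovery-slope estimates
#'
#' Replicates the treatment time-course experiment under a preset and
#' refits the OLS recovery slope each time: the mean recovered slope
#' estimates the preset slope (0.92 percent/min for SCS, 0.19 for sham) and
#' the spread of per-replicate p-values calibrates the significance of the
#' sham drift.  Replicate seeds are drawn once from `baseSeed`, making the
#' whole sweep a pure function of (`arm`, `nReplicates`, `baseSeed`).
#'
#' @param arm `"scs"` or `"sham"`.
#' @param nReplicates number of simulated cohorts (default 200).
#' @param baseSeed integer seed for the replicate-seed stream.
#' @param nScs,nSham cohort sizes per replicate.
#' @return data.frame with one row per replicate: `seed`, `slope`, `p`.
#' @export
slopeRecoverySweep <- function(arm = c("scs", "sham"), nReplicates = 200,
                               baseSeed, nScs = 7, nSham = 6) {
  arm <- match.arg(arm)
  if (missing(baseSeed)) stop("baseSeed is mandatory")
  set.seed(as.integer(baseSeed))
  seeds <- sample.int(.Machine$integer.max - 1L, nReplicates)
  group <- if (arm == "scs") "SCS" else "sham"
  res <- vapply(seeds, function(s) {
    tc <- generateScsCohort(nScs = nScs, nSham = nSham, seed = s)
    r <- timecourseRegression(tc[tc$group == group, ])
    c(r$slope, r$p)
  }, numeric(2))
  data.frame(seed = seeds, slope = res[1, ], p = res[2, ])
}

#' Paired before/after treatment test
#'
#' Tests whether the relative response directly after treatment cessation
#' (T = 0) differs from the before-treatment level.  Because every animal's
#' before value is 100 by construction, the paired t-test reduces to a
#' one-sample t-test of the T = 0 relative values against 100 (two-sided),
#' which is how it is computed.  Degenerate inputs with zero variance use
#' the documented conventions t = 0, p = 1 (all exactly at 100) or
#' p = 0 (all at a common value different from 100).
#'
#' @param cohort long data.frame as from [generateScsCohort()] (columns
#'   `animal_id`, `timepoint_min` and the metric column); pass one treatment
#'   arm at a time.
#' @param metric `"intensity"` or `"area"` (columns `relative_intensity` /
#'   `relative_area`).
#' @return one-row data.frame: `test`, `n`, `statistic`, `df`, `p`,
#'   `meanRelative`.
#' @export
beforeAfterTest <- function(cohort, metric = c("intensity", "area")) {
  metric <- match.arg(metric)
  col <- paste0("relative_", metric)
  stopifnot(col %in% names(cohort))
  x <- cohort[cohort$timepoint_min == 0, col]
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) stop("need at least 2 animals with a T = 0 value")
  if (stats::sd(x) == 0) {
    if (isTRUE(all.equal(x[1], 100))) {
      stat <- 0; p <- 1
    } else {
      stat <- sign(x[1] - 100) * Inf; p <- 0
    }
  } else {
    tt <- stats::t.test(x, mu = 100)
    stat <- unname(tt$statistic); p <- tt$p.value
  }
  data.frame(test = "paired-t", n = n, statistic = stat, df = n - 1L,
             p = p, meanRelative = mean(x))
}

#' Two-way ANOVA of AFI outcomes by animal type and side
#'
#' Crossed two-factor ANOVA (animal type x cord side) with interaction for
#' AFI intensities or areas of excitation, handling unbalanced designs with
#' Type II sums of squares by default (the type used is recorded in the
#' output).  Requires at least 2 observations per cell; an empty cell is an
#' error naming the cell, and one observation per cell leaves no residual
#' degrees of freedom for the interaction model.
#'
#' @param data data.frame with factor columns `type` and `side` and the
#'   response column.
#' @param response response column name (default `"intensity_pct"`).
#' @param ssType sum-of-squares type, 2 (default) or 3.
#' @return data.frame with one row per term: `term`, `sumsq`, `df`, `F`,
#'   `p`; attribute `ssType`.
#' @export
groupAnova <- function(data, response = "intensity_pct", ssType = 2) {
  stopifnot(all(c("type", "side", response) %in% names(data)))
  data$type <- factor(data$type)
  data$side <- factor(data$side)
  if (nlevels(data$type) < 2L || nlevels(data$side) < 2L)
    stop("both factors need at least 2 levels (crossed design)")
  tab <- table(data$type, data$side)
  if (any(tab == 0L)) {
    bad <- which(tab == 0L, arr.ind = TRUE)[1, ]
    stop("empty design cell: type '", levels(data$type)[bad[1]],
         "' x side '", levels(data$side)[bad[2]], "'")
  }
  if (nrow(data) <= nlevels(data$type) * nlevels(data$side))
    stop("no residual degrees of freedom: need >1 observation per cell")
  fml <- stats::as.formula(paste(response, "~ type * side"))
  fit <- stats::lm(fml, data = data)
  an <- car::Anova(fit, type = ssType)
  out <- data.frame(term = rownames(an), sumsq = an[["Sum Sq"]],
                    df = an[["Df"]], F = an[["F value"]],
                    p = an[["Pr(>F)"]], row.names = NULL)
  attr(out, "ssType") <- ssType
  out
}

#' Unpaired contrast of palpation responses
#'
#' Two-sided unpaired t-test of AFI intensities between two independent
#' groups (e.g. naive vs neuropathic animals under innocuous palpation).
#' Welch's unequal-variance form is the default; the pooling mode is
#' recorded in the output.
#'
#' @param naive,neuropathic numeric vectors of per-animal intensities
#'   (percent dF/F), n >= 2 each.
#' @param welch use Welch's correction (default TRUE); FALSE pools
#'   variances.
#' @return one-row data.frame: `test`, `statistic`, `df`, `p`,
#'   `meanNaive`, `meanNeuropathic`, `welch`.
#' @export
palpationContrast <- function(naive, neuropathic, welch = TRUE) {
  naive <- naive[!is.na(naive)]; neuropathic <- neuropathic[!is.na(neuropathic)]
  if (length(naive) < 2L || length(neuropathic) < 2L)
    stop("need at least 2 observations per group")
  if (stats::sd(naive) == 0 && stats::sd(neuropathic) == 0) {
    same <- isTRUE(all.equal(mean(naive), mean(neuropathic)))
    return(data.frame(test = "unpaired-t", statistic = if (same) 0 else Inf,
                      df = length(naive) + length(neuropathic) - 2L,
                      p = if (same) 1 else 0,
                      meanNaive = mean(naive),
                      meanNeuropathic = mean(neuropathic), welch = welch))
  }
  tt <- stats::t.test(neuropathic, naive, var.equal = !welch)
  data.frame(test = "unpaired-t", statistic = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value,
             meanNaive = mean(naive), meanNeuropathic = mean(neuropathic),
             welch = welch)
}
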