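#' Standard ascending filament series
#'
#' Calibrated von Frey filament forces (grams) covering the rat hind-paw
#' range, strictly ascending.  Used as the default series for threshold
#' determination and for snapping simulated thresholds.
#'
#' @return numeric vector of forces in grams.
#' @export
stoeltingFilaments <- function() c(0.4, 0.6, 1, 2, 4, 6, 8, 15, 26)

#' Von Frey withdrawal threshold (3-of-5 rule)
#'
#' Filaments of increasing force are each applied five times; the threshold
#' is the force of the first (lowest) filament evoking at least three
#' withdrawal responses out of five.  When no filament reaches the
#' criterion the maximum force is returned with a censored-high flag.
#'
#' @param counts integer withdrawal counts out of 5, one per filament,
#'   in ascending filament order.
#' @param filaments strictly increasing positive forces in grams,
#'   same length as `counts`.
#' @return list with `threshold` (grams) and `censored` (logical).
#' @examples
#' vonFreyThreshold(c(0, 1, 3, 5), c(2, 4, 8, 15))  # 8 g
#' @export
vonFreyThreshold <- function(counts, filaments = stoeltingFilaments()) {
  if (length(counts) != length(filaments))
    stop("one withdrawal count per filament required")
  if (any(counts < 0) || any(counts > 5) || any(counts != round(counts)))
    stop("withdrawal counts must be integers in 0..5")
  if (any(filaments <= 0) || is.unsorted(filaments, strictly = TRUE))
    stop("filament series must be strictly increasing and positive")
  idx <- which(counts >= 3)
  if (length(idx) == 0L)
    list(threshold = max(filaments), censored = TRUE)
  else
    list(threshold = filaments[idx[1L]], censored = FALSE)
}

#' Hotplate latency with 30-second censoring
#'
#' Latency to hind-paw lick or flick on a 51 degree C plate.  Animals not
#' responding within 30 s are removed to prevent tissue injury, so raw
#' latencies at or above 30 s are censored at exactly 30 s (the boundary
#' value 30 s itself counts as "did not respond within the window").
#'
#' @param raw raw latency in seconds (> 0), vectorized.
#' @param cutoff censoring cutoff in seconds (default 30).
#' @return list with `latency` (seconds, capped at `cutoff`) and
#'   `censored` (logical).
#' @examples
#' hotplateLatency(12.4)
#' hotplateLatency(45)   # 30 s, censored
#' @export
hotplateLatency <- function(raw, cutoff = 30) {
  if (any(is.na(raw)) || any(raw <= 0))
    stop("raw latency must be positive")
  list(latency = pmin(raw, cutoff), censored = raw >= cutoff)
}

#' Repeated-measures ANOVA across testing days
#'
#' One-way repeated-measures ANOVA (within factor: day) for a behavioral
#' endpoint, followed by pairwise paired t-tests of day 0 against each
#' later day with Bonferroni correction (factor = number of comparisons).
#' Animals missing any day are dropped complete-case with a warning.
#' When the endpoint is constant for every animal on every day the F
#' statistic is 0 and p = 1 by convention.  Greenhouse-Geisser correction
#' of the day degrees of freedom is available (`gg = TRUE`, off by
#' default); whether it was applied is recorded in the output.
#'
#' @param records long data.frame with columns `animal_id`, `day` and the
#'   endpoint column (as from [generateBehaviorCohort()]).
#' @param endpoint endpoint column name, e.g. `"vf_threshold"` or
#'   `"hp_latency"`.
#' @param gg apply the Greenhouse-Geisser sphericity correction.
#' @return list with `anova` (one-row data.frame: `F`, `df1`, `df2`, `p`,
#'   `gg`, `epsilon`, `nComplete`) and `pairwise` (data.frame of day-0
#'   contrasts: `day`, `t`, `df`, `p`, `pBonferroni`).
#' @export
rmAnovaDays <- function(records, endpoint = "vf_threshold", gg = FALSE) {
  stopifnot(all(c("animal_id", "day", endpoint) %in% names(records)))
  days <- sort(unique(records$day))
  wide <- stats::reshape(
    records[, c("animal_id", "day", endpoint)],
    idvar = "animal_id", timevar = "day", direction = "wide")
  complete <- stats::complete.cases(wide)
  if (any(!complete))
    warning(sum(!complete), " animal(s) without all ", length(days),
            " days dropped (complete-case analysis)")
  wide <- wide[complete, ]
  if (nrow(wide) < 2L) stop("need at least 2 complete animals")
  Y <- as.matrix(wide[, -1L])  # animals x days

  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  ssDay <- n * sum((colMeans(Y) - grand)^2)
  ssSubj <- k * sum((rowMeans(Y) - grand)^2)
  ssTot <- sum((Y - grand)^2)
  ssErr <- ssTot - ssDay - ssSubj
  df1 <- k - 1L; df2 <- (k - 1L) * (n - 1L)
  eps <- 1
  if (ssDay < 1e-12 * max(ssTot, 1) && ssErr < 1e-12 * max(ssTot, 1)) {
    Fval <- 0; p <- 1
  } else {
    Fval <- (ssDay / df1) / (ssErr / df2)
    if (gg) {
      eps <- .ggEpsilon(Y)
      p <- stats::pf(Fval, df1 * eps, df2 * eps, lower.tail = FALSE)
    } else {
      p <- stats::pf(Fval, df1, df2, lower.tail = FALSE)
    }
  }

  laterCols <- which(days > min(days))
  nComp <- length(laterCols)
  pw <- do.call(rbind, lapply(laterCols, function(j) {
    x0 <- Y[, which.min(days)]; xj <- Y[, j]
    d <- xj - x0
    if (stats::sd(d) == 0) {
      t0 <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p0 <- if (mean(d) == 0) 1 else 0
    } else {
      tt <- stats::t.test(xj, x0, paired = TRUE)
      t0 <- unname(tt$statistic); p0 <- tt$p.value
    }
    data.frame(day = days[j], t = t0, df = n - 1L, p = p0,
               pBonferroni = min(1, p0 * nComp))
  }))
  list(anova = data.frame(F = Fval, df1 = df1, df2 = df2, p = p,
                          gg = gg, epsilon = eps, nComplete = n),
       pairwise = pw)
}

# Greenhouse-Geisser epsilon from the double-centered covariance matrix.
.ggEpsilon <- function(Y) {
  k <- ncol(Y)
  S <- stats::cov(Y)
  C <- diag(k) - 1 / k
  Sc <- C %*% S %*% C
  num <- (sum(diag(Sc)))^2
  den <- (k - 1) * sum(Sc^2)
  if (den <= 0) return(1)
  max(1 / (k - 1), min(1, num / den))
}
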