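# Shared fixtures and independent scalar oracles.  Oracles are deliberately
# written as plain loops so they stay independent of the vectorized
# implementation they check.

# A small random integer stack; `baselineFrames` frames precede the stimulus.
randomStack <- function(seed, nT = 6, nr = 4, nc = 4, baselineFrames = 2) {
  set.seed(seed)
  counts <- array(sample(500:2000, nT * nr * nc, replace = TRUE),
                  c(nT, nr, nc))
  FluorescenceStack(counts, frameTimes = seq_len(nT) - 1,
                    stimOnset = baselineFrames - 0.5,
                    stimOffset = nT + 1)
}

# Brute-force per-pixel dF/F: scalar triple loop.
dffOracle <- function(frames, baselineWindow) {
  d <- dim(frames)
  out <- array(NA_real_, d)
  for (r in seq_len(d[2])) for (cc in seq_len(d[3])) {
    f0 <- 0
    for (t in baselineWindow) f0 <- f0 + frames[t, r, cc]
    f0 <- f0 / length(baselineWindow)
    if (f0 > 0)
      for (t in seq_len(d[1])) out[t, r, cc] <- (frames[t, r, cc] - f0) / f0
  }
  out
}

# Brute-force ROI mean trace over valid pixels.
roiTraceOracle <- function(dffArr, valid, rows, cols) {
  nT <- dim(dffArr)[1]
  out <- numeric(nT)
  for (t in seq_len(nT)) {
    s <- 0; n <- 0
    for (r in rows) for (cc in cols) {
      if (valid[r, cc]) { s <- s + dffArr[t, r, cc]; n <- n + 1 }
    }
    out[t] <- s / n
  }
  out
}

# Exhaustive supra-threshold pixel count (strict >, valid pixels only).
areaOracle <- function(dffArr, valid, window, thrFrac) {
  d <- dim(dffArr)
  cnt <- 0
  for (r in seq_len(d[2])) for (cc in seq_len(d[3])) {
    if (!valid[r, cc]) next
    mx <- -Inf
    for (t in window) mx <- max(mx, dffArr[t, r, cc])
    if (mx > thrFrac) cnt <- cnt + 1
  }
  cnt
}

# Closed-form OLS via the normal equations.
olsOracle <- function(t, y) {
  n <- length(t)
  sb <- (n * sum(t * y) - sum(t) * sum(y)) / (n * sum(t^2) - sum(t)^2)
  a <- mean(y) - sb * mean(t)
  list(slope = sb, intercept = a)
}

# A DffStack wrapping a given dF/F field (1 baseline frame at t = 0).
dffFieldStack <- function(dffArr, pixelSize = 10, valid = NULL) {
  nT <- dim(dffArr)[1]
  DffStack(dffArr, frameTimes = seq_len(nT) - 1, stimOnset = 0.5,
           stimOffset = nT + 1, pixelSize = pixelSize, valid = valid)
}

# Noiseless treatment preset (all variance components zeroed).
noiselessPreset <- function(name) {
  p <- effectPreset(name)
  p$timecourse$betweenSd <- 0
  p$timecourse$withinSd <- 0
  p$timecourse$areaT0Sd <- 0
  p
}

# Two-sided rejection probability of a one-sample/paired t-test at level
# alpha, from the noncentral t distribution.
tTestPower <- function(ncp, df, alpha = 0.05) {
  crit <- qt(1 - alpha / 2, df)
  pt(-crit, df, ncp) + 1 - pt(crit, df, ncp)
}
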