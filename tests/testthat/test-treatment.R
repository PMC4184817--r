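# Treatment time-course statistics and group comparisons

test_that("relative response is a plain percentage of the baseline", {
  expect_equal(relativeResponse(0.5, 0.5), 100)
  expect_equal(relativeResponse(0.5, 0), 0)
  expect_equal(relativeResponse(0.50, 0.30), 60)
  expect_warning(out <- relativeResponse(c(0.5, 1e-12), c(0.3, 0.3)),
                 "below the floor")
  expect_equal(out, c(60, NA_real_))
})

test_that("regression recovers an exact line and handles constants", {
  d <- data.frame(timepoint_min = c(0, 30, 60),
                  relative_intensity = c(40, 70, 100))
  r <- timecourseRegression(d)
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 40)
  expect_equal(r$r, 1)

  dconst <- data.frame(timepoint_min = seq(0, 60, 5),
                       relative_intensity = 80)
  rc <- timecourseRegression(dconst)
  expect_equal(rc$slope, 0)
  expect_equal(rc$p, 1)

  expect_error(timecourseRegression(d[1:2, ]), "3 distinct timepoints")
})

test_that("regression equals the normal-equations oracle on random cohorts", {
  set.seed(21)
  tp <- seq(0, 60, 5)
  for (rep in 1:5) {
    cohort <- do.call(rbind, lapply(1:6, function(i)
      data.frame(animal_id = i, timepoint_min = tp,
                 relative_intensity = 50 + 0.5 * tp + rnorm(length(tp), 0, 20))))
    r <- timecourseRegression(cohort)
    means <- aggregate(relative_intensity ~ timepoint_min, cohort, mean)
    o <- olsOracle(means$timepoint_min, means$relative_intensity)
    expect_equal(r$slope, o$slope, tolerance = 1e-10)
    expect_equal(r$intercept, o$intercept, tolerance = 1e-10)
    # Pearson r consistent with slope sign and regression R^2
    fit <- lm(relative_intensity ~ timepoint_min, means)
    expect_equal(r$r^2, summary(fit)$r.squared, tolerance = 1e-10)
    expect_equal(sign(r$r), sign(r$slope))
    # pooled mode uses every point
    rp <- timecourseRegression(cohort, mode = "pooled")
    op <- olsOracle(cohort$timepoint_min, cohort$relative_intensity)
    expect_equal(rp$slope, op$slope, tolerance = 1e-10)
  }
})

test_that("regression is equivariant under shift and scale of the response", {
  set.seed(31)
  tp <- seq(0, 60, 5)
  base <- data.frame(timepoint_min = tp,
                     relative_intensity = 60 + 0.7 * tp + rnorm(length(tp), 0, 10))
  r0 <- timecourseRegression(base)
  shifted <- transform(base, relative_intensity = relative_intensity + 13)
  scaled <- transform(base, relative_intensity = relative_intensity * 2.5)
  expect_equal(timecourseRegression(shifted)$slope, r0$slope, tolerance = 1e-10)
  expect_equal(timecourseRegression(scaled)$slope, 2.5 * r0$slope,
               tolerance = 1e-10)
})

test_that("before/after test reduces to the closed-form one-sample t", {
  atBaseline <- data.frame(animal_id = 1:4, timepoint_min = 0,
                           relative_intensity = 100)
  r <- beforeAfterTest(atBaseline, "intensity")
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  x <- c(60, 70, 80)
  d <- data.frame(animal_id = 1:3, timepoint_min = 0, relative_intensity = x)
  r2 <- beforeAfterTest(d, "intensity")
  # hand-computed: mean 70, sd 10 -> t = (70-100)/(10/sqrt(3)), df = 2
  tHand <- (mean(x) - 100) / (sd(x) / sqrt(3))
  expect_equal(r2$statistic, tHand, tolerance = 1e-12)
  expect_equal(r2$df, 2L)
  expect_equal(r2$p, 2 * pt(tHand, 2), tolerance = 1e-12)

  expect_error(beforeAfterTest(d[1, ], "intensity"), "at least 2 animals")
})

test_that("paired t on data mirrored about 100 is symmetric", {
  x <- c(60, 75, 90, 85)
  mk <- function(v) data.frame(animal_id = seq_along(v), timepoint_min = 0,
                               relative_intensity = v)
  lo <- beforeAfterTest(mk(x), "intensity")
  hi <- beforeAfterTest(mk(200 - x), "intensity")
  expect_equal(lo$statistic, -hi$statistic, tolerance = 1e-12)
  expect_equal(lo$p, hi$p, tolerance = 1e-12)
})

test_that("SCS suppression detection rate matches the preset's analytic power", {
  # The preset implies a noncentral-t rejection rate for the T=0 paired test;
  # the Monte-Carlo rate must be binomially compatible with it.
  p <- effectPreset("scs")$timecourse
  ncp <- (100 - p$s0) / sqrt(p$withinSd^2 + p$betweenSd^2) * sqrt(7)
  power <- tTestPower(ncp, df = 6)
  hits <- vapply(1:200, function(s) {
    tc <- generateScsCohort(seed = 4000 + s)
    beforeAfterTest(tc[tc$group == "SCS", ], "intensity")$p < 0.05
  }, logical(1))
  expect_gt(binom.test(sum(hits), 200, power)$p.value, 0.01)
  # and it is far above the 5% false-positive floor
  expect_gt(mean(hits), 0.25)
})

test_that("two-way ANOVA matches the classical balanced decomposition", {
  set.seed(41)
  d <- expand.grid(type = c("naive", "neuropathic"),
                   side = c("ipsilateral", "contralateral"),
                   rep = 1:6)
  d$intensity_pct <- rnorm(nrow(d), 0.4, 0.1)
  res <- groupAnova(d)
  # balanced design: Type II sums of squares equal the sequential ones and
  # SS_A + SS_B + SS_AB + SS_res = SS_total
  grand <- mean(d$intensity_pct)
  ssTot <- sum((d$intensity_pct - grand)^2)
  expect_equal(sum(res$sumsq), ssTot, tolerance = 1e-9)
  a1 <- anova(lm(intensity_pct ~ type * side, d))
  keep <- res$term != "Residuals"
  expect_equal(res$F[keep], a1$`F value`[1:3], tolerance = 1e-9)
  expect_true(all(res$p[keep] >= 0 & res$p[keep] <= 1))
})

test_that("an injected side effect is detected, degenerate designs error", {
  set.seed(42)
  d <- expand.grid(type = c("naive", "neuropathic"),
                   side = c("ipsilateral", "contralateral"), rep = 1:8)
  d$intensity_pct <- rnorm(nrow(d), 0.4, 0.05) +
    ifelse(d$side == "ipsilateral", 0.3, 0)
  res <- groupAnova(d)
  expect_lt(res$p[res$term == "side"], 0.01)

  one <- expand.grid(type = c("a", "b"), side = c("i", "c"))
  one$intensity_pct <- 1:4
  expect_error(groupAnova(one), "residual degrees of freedom")

  empty <- data.frame(type = c("a", "a", "b", "b", "b"),
                      side = c("i", "c", "i", "i", "i"),
                      intensity_pct = 1:5)
  expect_error(groupAnova(empty), "empty design cell: type 'b' x side 'c'")

  oneLevel <- data.frame(type = rep(c("a", "b"), 2), side = "i",
                         intensity_pct = 1:4)
  expect_error(groupAnova(oneLevel), "at least 2 levels")
})

test_that("unpaired palpation contrast behaves at the extremes", {
  expect_equal(palpationContrast(c(1, 2, 3), c(1, 2, 3))$p, 1)
  r <- palpationContrast(c(0, 0, 0, 0, 0), c(0.3, 0.4, 0.5, 0.35, 0.45))
  expect_lt(r$p, 0.01)
  # Welch with one zero-variance group: closed form t = diff / (s2 / sqrt(n2))
  x2 <- c(0.3, 0.4, 0.5, 0.35, 0.45)
  expect_equal(r$statistic, mean(x2) / (sd(x2) / sqrt(5)), tolerance = 1e-12)
  expect_true(r$welch)
  expect_error(palpationContrast(1, c(1, 2)), "at least 2")
})

test_that("palpation detection rate matches the preset's analytic power", {
  pn <- effectPreset("palpation-naive")$cohort
  ps <- effectPreset("palpation-neuropathic")$cohort
  diff <- ps$intensityMean["ipsi"] - pn$intensityMean["ipsi"]
  ncp <- diff / (ps$intensitySd * sqrt(2 / 5))
  power <- tTestPower(ncp, df = 8)  # pooled-df approximation (equal SDs)
  hits <- vapply(1:200, function(s) {
    a <- generateAfiCohort(5, effectPreset("palpation-naive"), seed = 7000 + s)
    b <- generateAfiCohort(5, effectPreset("palpation-neuropathic"),
                           seed = 17000 + s)
    palpationContrast(a$intensity_pct[a$side == "ipsilateral"],
                      b$intensity_pct[b$side == "ipsilateral"])$p < 0.05
  }, logical(1))
  expect_gt(binom.test(sum(hits), 200, power)$p.value, 0.01)
  expect_gt(mean(hits), 0.8)
})
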