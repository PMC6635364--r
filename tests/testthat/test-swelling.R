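test_that("swelling percent is relative to the dry dimension", {
  expect_equal(swellingPercent(20, 20), 0)
  expect_equal(swellingPercent(21.86, 20), 9.3)
  expect_warning(s <- swellingPercent(19, 20), "below the dry reference")
  expect_equal(s, -5)
  expect_error(swellingPercent(20, 0), "positive")
})

test_that("stream joining interpolates mass linearly onto image times", {
  series <- MassSeries("s", data.frame(
    t = c(0, 10, 20), mass = c(306, 312.12, 315.18),
    rh_set = 50, rh_meas = 50, temp = 20), m0 = 306)
  dims <- data.frame(t = c(0, 5, 10, 20), w_r_mm = 20, w_t_mm = 20)
  joined <- joinStreams(dims, series)
  expect_equal(joined$mc[1], 0)
  expect_equal(joined$mc[3], 2)                       # exact record time
  expect_equal(joined$mc[2], mean(c(0, 2)))           # midway
  # frames beyond the mass range are dropped, disjoint ranges error
  expect_warning(j2 <- joinStreams(rbind(dims, data.frame(
    t = 99, w_r_mm = 20, w_t_mm = 20)), series), "dropped")
  expect_equal(nrow(j2), 4)
  expect_error(joinStreams(data.frame(t = 500, w_r_mm = 20, w_t_mm = 20),
                           series), "disjoint")
  expect_error(joinStreams(dims, MassSeries("s", massRecords(series))),
               "dry mass")
})

test_that("joined synthetic streams reproduce the generator coupling law", {
  run <- runVirtualExperiment(seed = 23)
  series <- seriesFromLog(run$massLog)
  ms <- analyzeMassSeries(series)
  joined <- joinStreams(dimsFromRun(run), ms$series)
  sw <- swellingSeries(joined, 20, 20)
  below <- sw$mc > 1 & sw$mc < 25
  # tangential: S = qT * mc below onset, up to instrument noise
  resid <- sw$S_t[below] - 0.31 * sw$mc[below]
  expect_lt(max(abs(resid)), 5 * 0.3 * testScaleNoise())
})

test_that("differential swelling reproduces the printed arithmetic", {
  expect_equal(differentialSwelling(9.3, 30), 0.31)
  expect_equal(differentialSwelling(5.6, 30), 0.19)
  expect_equal(differentialSwelling(16.4, 40), 0.41)
  expect_equal(differentialSwelling(6.0, 40), 0.15)
  expect_equal(differentialSwelling(0, 30), 0)
  expect_error(differentialSwelling(9.3, 0), "positive")
})

test_that("maximum swelling scans the whole series (outliers included when unfiltered)", {
  sw <- data.frame(S_r = c(0, 1, 5.7, 3), S_t = c(0, 2, 9.2, 9.3))
  expect_equal(maxSwelling(sw), c(max_S_r = 5.7, max_S_t = 9.3))
  expect_equal(maxSwelling(data.frame(S_r = rep(0, 4), S_t = rep(0, 4))),
               c(max_S_r = 0, max_S_t = 0))
  # a single-frame outlier dominates when no filtering is applied
  sw$S_t[2] <- 50
  expect_equal(maxSwelling(sw)[["max_S_t"]], 50)
})

test_that("shrink onset: fixed mode returns species defaults, detect recovers the breakpoint", {
  expect_equal(shrinkOnset(NULL, mode = "fixed", fixedMc = 30), 30)
  expect_equal(shrinkOnset(NULL, mode = "fixed", fixedMc = 40), 40)

  set.seed(3)
  mc <- seq(0, 60, by = 0.75)
  s <- 0.31 * pmin(mc, 30) + stats::rnorm(length(mc), sd = 0.05)
  onset <- shrinkOnset(data.frame(mc = mc, S_t = s), mode = "detect")
  expect_lt(abs(onset - 30), 2)

  # strictly linear data has no plateau
  lin <- data.frame(mc = mc, S_t = 0.31 * mc +
                      stats::rnorm(length(mc), sd = 0.05))
  expect_error(shrinkOnset(lin, mode = "detect"), "plateau|fixed")
  expect_error(shrinkOnset(data.frame(mc = 1:4, S_t = 1:4),
                           mode = "detect"), "6 points")
})

test_that("step normalization pins the extrema at 0 and 1", {
  expect_equal(normalizeStep(c(2, 4, 6)), c(0, 0.5, 1))
  x <- c(0, 0.25, 0.8, 1)
  expect_equal(normalizeStep(x), x)          # idempotent on [0,1] series
  expect_error(normalizeStep(rep(3, 5)), "constant")
  set.seed(11)
  y <- stats::rnorm(50)
  ny <- normalizeStep(y)
  expect_equal(range(ny), c(0, 1))
})

test_that("normalized dynamics correlation returns slope, intercept and R2", {
  x <- seq(0, 1, length.out = 20)
  fit <- correlateDynamics(x, x)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r2, 1)
  fit2 <- correlateDynamics(x, 1 - x)
  expect_equal(fit2$slope, -1)
  expect_equal(fit2$r2, 1)
  expect_error(correlateDynamics(x[1:2], x[1:2]), "3")
  expect_error(correlateDynamics(x, x[1:5]), "equal length")
})

test_that("time to approximate equilibrium applies the 3-decimal rounding rule", {
  # first zero successive difference after rounding is at index 2
  expect_equal(timeToEquilibrium(c(0, 15, 30, 45),
                                 c(10.0005, 10.0004, 10.0004, 10.0010)),
               15 / 60)
  # constant series: time of the first point
  expect_equal(timeToEquilibrium(c(7, 20, 40), rep(9.1, 3)), 7 / 60)
  # strictly changing third decimal: no equilibrium
  expect_true(is.na(timeToEquilibrium(seq(0, 45, 15),
                                      10 + (0:3) * 0.002)))
  expect_error(timeToEquilibrium(c(10, 0), c(1, 1)), "sorted")
})

test_that("time to equilibrium never decreases when tau doubles", {
  times <- seq(0, 200 * 60, by = 15)
  taus <- 30 * 2^(0:6)
  tte <- vapply(taus, function(tau) {
    timeToEquilibrium(times, stepKinetics(80, 18, tau, times))
  }, numeric(1))
  expect_true(all(is.finite(tte)))
  expect_true(all(diff(tte) >= 0))
})

test_that("isotherm points show hysteresis against r.h. but not against moisture content", {
  run <- runVirtualExperiment(seed = 29)
  res <- analyzeExperiment(dimsFromRun(run), seriesFromLog(run$massLog))
  iso <- res$isotherms
  shared <- intersect(iso$rh_pct[iso$branch == "desorption"],
                      iso$rh_pct[iso$branch == "absorption"])
  shared <- shared[shared > 0]
  des <- iso[iso$branch == "desorption", ]
  abs_ <- iso[iso$branch == "absorption", ]
  kin <- KineticsParams()
  for (rh in shared) {
    gapTrue <- emcModel(rh, "desorption", kin) -
      emcModel(rh, "absorption", kin)
    gap <- des$emc_pct[match(rh, des$rh_pct)] -
      abs_$emc_pct[match(rh, abs_$rh_pct)]
    expect_gt(gap, 0.9 * gapTrue)                 # hysteresis vs r.h.
    gapS <- des$S_t_pct[match(rh, des$rh_pct)] -
      abs_$S_t_pct[match(rh, abs_$rh_pct)]
    expect_gt(gapS, 0)                            # swelling vs r.h. too
  }
  # against moisture content the branches collapse onto one line
  sw <- res$joined
  sigmaS <- 0.3 * testScaleNoise()
  for (br in c("desorption", "absorption")) {
    stepsBr <- Filter(function(s) s@direction == br, res$steps)
    tRanges <- lapply(stepsBr, function(s) c(s@tStart, s@tEnd))
    inBr <- Reduce(`|`, lapply(tRanges, function(r)
      sw$t >= r[1] & sw$t <= r[2]))
    sub <- sw[inBr & sw$mc > 2 & sw$mc < 15, ]
    fit <- stats::lm(S_t ~ mc, data = sub)
    assign(paste0("fit_", br), fit)
  }
  grid <- data.frame(mc = seq(3, 14, by = 1))
  gapMc <- abs(stats::predict(fit_desorption, grid) -
               stats::predict(fit_absorption, grid))
  expect_lt(max(gapMc), 3 * sigmaS)
})

test_that("per-step dynamics tables fit each direction within each step", {
  run <- runVirtualExperiment(seed = 31)
  res <- analyzeExperiment(dimsFromRun(run), seriesFromLog(run$massLog))
  dyn <- res$dynamics
  expect_true(all(c("step_index", "dir", "slope", "r2") %in% names(dyn)))
  expect_true(all(dyn$r2 >= 0 & dyn$r2 <= 1))
  # the first desorption step crosses the shrink onset, where swelling is
  # flat in MC, so its fit must be visibly worse than the best
  # below-onset absorption step
  first <- dyn[dyn$step_index == 1 & dyn$dir == "t", ]
  bestAbs <- max(dyn$r2[dyn$direction == "absorption" & dyn$dir == "t"])
  expect_gt(bestAbs, 0.9)
  expect_lt(first$r2, bestAbs)
})
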