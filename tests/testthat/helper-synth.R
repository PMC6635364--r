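# Shared fixtures: all synthetic, built in code at test time.

# Downscaled render geometry used throughout the suite: 320 px frames at
# 0.09 mm/px so a 20 mm specimen spans ~222 px and the default f = 81 band
# fits comfortably.
testScale <- 20 / 222.22

testRenderParams <- function(rotationDeg = 0, ...) {
  RenderParams(imageSize = 320L, scale = testScale,
               rotationDeg = rotationDeg, ...)
}

# solid axis-aligned rectangle mask
rectMask <- function(nr, nc, rows, cols) {
  m <- matrix(0L, nr, nc)
  m[rows, cols] <- 1L
  SampleMask(m)
}

# MassSeries straight from a generated mass log
seriesFromLog <- function(massLog) {
  MassSeries(massLog$sample_id[1], data.frame(
    t = massLog$t_min, mass = massLog$mass_mg,
    rh_set = massLog$rh_set_pct, rh_meas = massLog$rh_meas_pct,
    temp = massLog$temp_C))
}

dimsFromRun <- function(run) run$dims[c("t", "w_r_mm", "w_t_mm")]

# swelling noise (percent) implied by 1 px of dimension noise at the
# default 0.018 mm/px on a 20 mm specimen; multiply by dimNoiseSdPx
testScaleNoise <- function() 0.018 / 20 * 100

# naive double-loop centre-band width (independent oracle for the
# estimators): explicit sums over the f-column (or f-row) band
bruteWidth <- function(m, f, radial = TRUE) {
  if (!radial) m <- t(m)
  idx <- which(m == 1L, arr.ind = TRUE)
  c0 <- floor(mean(idx[, 2]) + 0.5)
  h <- (f - 1) / 2
  s <- 0
  for (j in (c0 - h):(c0 + h))
    for (i in seq_len(nrow(m)))
      s <- s + m[i, j]
  s / f
}

# random blob-plus-speckle mask guaranteed non-empty with the band inside
randomMask <- function(nr, nc, f) {
  m <- matrix(as.integer(stats::runif(nr * nc) < 0.2), nr, nc)
  h <- (f - 1) / 2
  c0 <- floor(nc / 2)
  r0 <- floor(nr / 2)
  m[max(1, r0 - 4):min(nr, r0 + 4),
    max(h + 1, c0 - 4):min(nc - h, c0 + 4)] <- 1L
  m
}
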