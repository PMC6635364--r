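test_that("CIELAB conversion maps black and white to the scale anchors and is deterministic", {
  black <- ImageFrame(array(0, dim = c(4, 5, 3)))
  labB <- toCielab(black)
  expect_equal(max(abs(labB[, , 1])), 0)

  white <- ImageFrame(array(1, dim = c(4, 5, 3)))
  labW <- toCielab(white)
  expect_equal(labW[, , 1], matrix(100, 4, 5))
  expect_lt(max(abs(labW[, , 2:3])), 1e-6)

  mixed <- array(stats::runif(4 * 5 * 3), dim = c(4, 5, 3))
  expect_identical(toCielab(mixed), toCielab(mixed))

  expect_error(toCielab(matrix(0, 3, 3)), "3")
})

test_that("binarization marks background only when all three channels are in range", {
  thr <- LabThresholds()
  lab <- array(0, dim = c(60, 80, 3))
  lab[, , 1] <- 10; lab[, , 2] <- 0; lab[, , 3] <- 0   # in all intervals
  expect_equal(foregroundArea(binarize(lab, thr)), 0)

  # a rectangle with L out of range becomes foreground, pixel for pixel
  lab[10:39, 20:59, 1] <- 60
  mask <- binarize(lab, thr)
  expect_equal(foregroundArea(mask), 30 * 40)
  expect_equal(maskMatrix(mask)[10:39, 20:59], matrix(1L, 30, 40))

  # one channel out of range is enough
  lab2 <- array(0, dim = c(5, 5, 3))
  lab2[, , 1] <- 10
  lab2[3, 3, 3] <- -20   # b below its interval
  expect_equal(foregroundArea(binarize(lab2, thr)), 1)
})

test_that("rendered frames segment to within 1% of the true specimen area", {
  rp <- testRenderParams()
  fr <- renderFrame(20, 20, rp, seed = 11)
  mask <- fillMaskHoles(removeArtifacts(binarize(toCielab(fr))))
  trueArea <- (20 / testScale) * (20 / testScale)
  expect_lt(abs(foregroundArea(mask) - trueArea) / trueArea, 0.01)
})

test_that("artifact removal deletes components up to the inclusive bound", {
  m <- matrix(0L, 300, 300)
  m[50:199, 50:199] <- 1L            # 22500 px specimen
  m[250:256, 230:239] <- 1L          # 70 px speck
  out <- removeArtifacts(SampleMask(m), maxSize = 7000)
  expect_equal(foregroundArea(out), 22500)
  expect_equal(sum(maskMatrix(out)[250:256, ]), 0)

  # exactly 7000 px is removed, 7001 px is retained
  m2 <- matrix(0L, 300, 300)
  m2[1:70, 1:100] <- 1L              # 7000 px
  m2[150:269, 150:269] <- 1L         # big carrier so the mask is not empty
  out2 <- removeArtifacts(SampleMask(m2), maxSize = 7000)
  expect_equal(sum(maskMatrix(out2)[1:70, 1:100]), 0)

  m3 <- matrix(0L, 300, 300)
  m3[1:70, 1:100] <- 1L
  m3[71, 1] <- 1L                    # 7001 px, 8-connected
  out3 <- removeArtifacts(SampleMask(m3), maxSize = 7000)
  expect_equal(foregroundArea(out3), 7001)

  # all components at or below the bound -> no specimen
  m4 <- matrix(0L, 50, 50); m4[1:5, 1:5] <- 1L
  expect_error(removeArtifacts(SampleMask(m4), maxSize = 7000),
               "no specimen")
})

test_that("components are labelled with 8-connectivity", {
  m <- matrix(0L, 200, 200)
  m[10:109, 10:109] <- 1L            # 10000 px block
  m[110, 110] <- 1L                  # diagonal neighbour
  m[112, 112] <- 1L                  # separate 1-px speck
  out <- removeArtifacts(SampleMask(m), maxSize = 7000)
  expect_equal(maskMatrix(out)[110, 110], 1L)   # merged diagonally
  expect_equal(maskMatrix(out)[112, 112], 0L)   # removed as artifact
})

test_that("hole filling closes interior holes, keeps border notches, and is idempotent", {
  # rectangle with a ~110-px-diameter disk hole (a 2 mm hole at 0.018 mm/px)
  m <- matrix(0L, 400, 400)
  m[100:299, 100:299] <- 1L
  cx <- 199.5; cy <- 199.5; r <- 55
  disk <- outer(seq_len(400), seq_len(400),
                function(i, j) (i - cy)^2 + (j - cx)^2 <= r^2)
  m[disk] <- 0L
  holeArea <- sum(disk)
  filled <- fillMaskHoles(SampleMask(m))
  expect_equal(foregroundArea(filled), 200 * 200)
  expect_equal(foregroundArea(filled) - sum(m), holeArea)

  # idempotence and no-hole identity
  expect_identical(maskMatrix(fillMaskHoles(filled)), maskMatrix(filled))
  solid <- rectMask(50, 50, 10:40, 10:40)
  expect_identical(maskMatrix(fillMaskHoles(solid)), maskMatrix(solid))

  # notch open to the border is not a hole
  m2 <- matrix(0L, 50, 50)
  m2[10:40, 10:40] <- 1L
  m2[1:20, 25] <- 0L
  expect_identical(maskMatrix(fillMaskHoles(SampleMask(m2))), m2)
})

test_that("cleanup (artifacts + holes) applied twice equals applied once", {
  rp <- testRenderParams(rotationDeg = 3)
  fr <- renderFrame(20, 20, rp, seed = 21)
  once <- fillMaskHoles(removeArtifacts(binarize(toCielab(fr))))
  twice <- fillMaskHoles(removeArtifacts(once))
  expect_identical(maskMatrix(once), maskMatrix(twice))
})

test_that("rotation alignment recovers rendered tilts and leaves aligned masks alone", {
  aligned <- rectMask(200, 200, 40:160, 50:150)
  out <- alignRotation(aligned)
  expect_equal(out$angle, 0)
  expect_identical(maskMatrix(out$mask), maskMatrix(aligned))

  for (rot in c(-10, -5, -2, 2, 5, 10)) {
    fr <- renderFrame(20, 18, testRenderParams(rotationDeg = rot),
                      seed = 31)
    mask <- fillMaskHoles(removeArtifacts(binarize(toCielab(fr))))
    al <- alignRotation(mask)
    expect_lt(abs(al$angle + rot), 0.2)
    expect_lt(abs(measureWidthRadial(al$mask) - 20 / testScale), 2)
    expect_lt(abs(measureWidthTangential(al$mask) - 18 / testScale), 2)
  }

  expect_error(alignRotation(SampleMask(matrix(c(1L, rep(0L, 99)), 10))),
               "degenerate")
})

test_that("a perfect square at 45 degrees is aligned via the tie rule", {
  fr <- renderFrame(15, 15, testRenderParams(rotationDeg = 45,
                                             artifactCount = 0L),
                    seed = 41, holeDiameter = 0)
  mask <- fillMaskHoles(removeArtifacts(binarize(toCielab(fr))))
  al <- alignRotation(mask)
  expect_equal(abs(al$angle), 45, tolerance = 0.01)
  expect_lt(abs(measureWidthRadial(al$mask) - 15 / testScale), 2)
})

test_that("centre-band widths are exact on axis-aligned rectangles", {
  big <- rectMask(1300, 1200, 100:1210, 80:1129)   # 1111 x 1050
  expect_equal(measureWidthRadial(big, f = 81), 1111)
  expect_equal(measureWidthTangential(big, f = 81), 1050)
  expect_equal(measureWidthRadial(big, f = 1), 1111)

  for (dims in list(c(7, 13), c(40, 21), c(121, 121))) {
    m <- rectMask(dims[1] + 20, dims[2] + 20,
                  10 + seq_len(dims[1]), 10 + seq_len(dims[2]))
    expect_equal(measureWidthRadial(m, f = 5), dims[1])
    expect_equal(measureWidthTangential(m, f = 5), dims[2])
  }
})

test_that("width estimators reject invalid bands and empty masks", {
  m <- rectMask(100, 100, 20:80, 20:80)
  expect_error(measureWidthRadial(m, f = 4), "odd")
  expect_error(measureWidthRadial(m, f = 0), "positive")
  expect_error(measureWidthRadial(m, f = 121), "outside")
  expect_error(measureWidthRadial(SampleMask(matrix(0L, 5, 5))), "empty")
})

test_that("width estimators match the naive double-loop oracle on random masks", {
  set.seed(42)
  for (k in 1:60) {
    nr <- sample(32:64, 1); nc <- sample(32:64, 1)
    f <- sample(c(1, 3, 5, 7, 9), 1)
    m <- randomMask(nr, nc, f)
    sm <- SampleMask(m)
    expect_equal(measureWidthRadial(sm, f = f), bruteWidth(m, f, TRUE))
    expect_equal(measureWidthTangential(sm, f = f),
                 bruteWidth(m, f, FALSE))
    # transpose symmetry
    expect_equal(measureWidthTangential(sm, f = f),
                 measureWidthRadial(SampleMask(t(m)), f = f))
  }
})

test_that("whole-pixel translations do not change measured widths", {
  base <- rectMask(200, 200, 50:150, 60:140)
  w0 <- c(measureWidthRadial(base), measureWidthTangential(base))
  for (shift in list(c(7, 0), c(0, -11), c(13, 5))) {
    m <- rectMask(200, 200, 50:150 + shift[1], 60:140 + shift[2])
    expect_equal(c(measureWidthRadial(m), measureWidthTangential(m)), w0)
  }
})

test_that("a filled interior hole does not change the centre-band width", {
  m <- matrix(0L, 400, 400)
  m[100:299, 120:279] <- 1L
  holed <- m
  disk <- outer(seq_len(400), seq_len(400),
                function(i, j) (i - 199.5)^2 + (j - 199.5)^2 <= 55.5^2)
  holed[disk] <- 0L
  restored <- fillMaskHoles(SampleMask(holed))
  expect_equal(measureWidthRadial(restored, f = 81),
               measureWidthRadial(SampleMask(m), f = 81))
})

test_that("pixel-to-mm conversion multiplies by the optical scale", {
  expect_equal(pxToMm(1111, 0.018), 19.998)
  expect_equal(pxToMm(0, 0.5), 0)
  expect_equal(pxToMm(2, 0.018), 0.036)   # Nyquist-limited minimum object
  expect_error(pxToMm(10, -1), "positive")
})
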