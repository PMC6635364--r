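#' Equilibrium moisture content model of the virtual instrument
#'
#' GAB-shaped sorption isotherm for the desorption branch with a
#' multiplicative hysteresis ratio for absorption (absorption EMC =
#' \code{hysteresisRatio} x desorption EMC, so desorption >= absorption at
#' every shared r.h.). Monotone non-decreasing in r.h. per branch with
#' EMC(0) = 0. The functional form is a generator choice emulating the
#' type-II shape of wood isotherms, not an estimate of any measured curve.
#'
#' @param rh relative humidity, percent (vectorized, in \[0, 100\]).
#' @param branch \code{"desorption"} or \code{"absorption"}.
#' @param params a \code{\link{KineticsParams}} object.
#' @return EMC in percent.
#' @export
emcModel <- function(rh, branch = c("desorption", "absorption"),
                     params = KineticsParams()) {
  branch <- match.arg(branch)
  stopifnot(is(params, "KineticsParams"))
  if (any(rh < 0 | rh > 100))
    stop("relative humidity must lie in [0, 100]", call. = FALSE)
  h <- rh / 100
  kh <- params@gabK * h
  emc <- params@gabMm * params@gabC * kh /
    ((1 - kh) * (1 + (params@gabC - 1) * kh))
  if (branch == "absorption") emc <- params@hysteresisRatio * emc
  emc
}

#' Exponential approach to the step equilibrium
#'
#' Single-time-constant sorption kinetics within one humidity step:
#' \code{MC(t) = target + (start - target) * exp(-t/tau)}.
#'
#' @param mcStart moisture content at step start, percent.
#' @param emcTarget equilibrium target of the step, percent.
#' @param tau time constant, minutes (> 0).
#' @param times times since step start, minutes (vectorized).
#' @return moisture contents at \code{times}, percent.
#' @export
stepKinetics <- function(mcStart, emcTarget, tau, times) {
  if (!is.finite(tau) || tau <= 0)
    stop("tau must be positive", call. = FALSE)
  emcTarget + (mcStart - emcTarget) * exp(-times / tau)
}

#' Swelling from moisture content (ground-truth coupling law)
#'
#' Branch-independent coupling: swelling is linear in moisture content
#' below the shrink-onset MC and constant above it,
#' \code{S = q_dir * min(mc, mcOnset)}.
#'
#' @param mc moisture content, percent (vectorized, >= 0).
#' @param sample a \code{\link{VirtualSample}}.
#' @param dir \code{"radial"} or \code{"tangential"}.
#' @return swelling in percent.
#' @examples
#' swellingFromMc(30, VirtualSample("pine"), "tangential")  # 9.3
#' @export
swellingFromMc <- function(mc, sample = VirtualSample("pine"),
                           dir = c("tangential", "radial")) {
  dir <- match.arg(dir)
  stopifnot(is(sample, "VirtualSample"))
  if (any(mc < 0)) stop("moisture content must be >= 0", call. = FALSE)
  q <- if (dir == "radial") sample@qR else sample@qT
  q * pmin(mc, sample@mcOnset)
}

# tau for a given thickness under the diffusion-type scaling
tauForThickness <- function(params, thickness, refThickness = 1.5) {
  params@tauRef * (thickness / refThickness)^params@thicknessExponent
}

#' Run a complete virtual sorption experiment
#'
#' Simulates the coupled mass/dimension response of one virtual specimen
#' over a humidity step schedule. Within each step the true moisture
#' content follows \code{\link{stepKinetics}} toward the branch EMC target
#' and is weighed every \code{cycleMin} minutes with Gaussian balance
#' noise; the step advances when the analyzer's own equilibrium criterion
#' holds on the observed masses and at least \code{minCycleH} hours have
#' elapsed, or unconditionally at \code{maxCycleH} hours. Dimensions follow
#' the ground-truth coupling law \code{\link{swellingFromMc}} plus Gaussian
#' dimension noise. Fully deterministic for a given seed.
#'
#' @param sample a \code{\link{VirtualSample}}.
#' @param kinetics a \code{\link{KineticsParams}}.
#' @param schedule step schedule data.frame (\code{\link{defaultSchedule}}).
#' @param seed integer seed (mandatory).
#' @param policy an \code{\link{EquilibriumPolicy}}.
#' @param mcInitial true moisture content at experiment start, percent
#'   (default 80: water-soaked, well above fibre saturation).
#' @param sampleId identifier written to the log.
#' @return list with \code{massLog} (data.frame \code{sample_id},
#'   \code{t_min}, \code{mass_mg}, \code{rh_set_pct}, \code{rh_meas_pct},
#'   \code{temp_C}), \code{dims} (data.frame \code{t}, noisy
#'   \code{w_r_mm}, \code{w_t_mm} plus true widths and true \code{mc}),
#'   and \code{truth} (all generator parameters, per-step EMC targets and
#'   equilibrium flags).
#' @export
runVirtualExperiment <- function(sample = VirtualSample("pine"),
                                 kinetics = KineticsParams(),
                                 schedule = defaultSchedule(), seed = 1L,
                                 policy = EquilibriumPolicy(),
                                 mcInitial = 80, sampleId = "virtual-1") {
  stopifnot(is(sample, "VirtualSample"), is(kinetics, "KineticsParams"),
            is(policy, "EquilibriumPolicy"))
  validateSchedule(schedule)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))

  tau <- tauForThickness(kinetics, sample@thickness)
  cyc <- kinetics@cycleMin
  minMin <- policy@minCycleH * 60
  maxMin <- policy@maxCycleH * 60
  m0 <- sample@dryMassMg
  dimNoiseMm <- kinetics@dimNoiseSdPx * kinetics@scaleMmPerPx

  mcPrev <- mcInitial
  tOffset <- 0
  logs <- list()
  dims <- list()
  targets <- numeric(nrow(schedule))
  reached <- logical(nrow(schedule))
  for (k in seq_len(nrow(schedule))) {
    branch <- schedule$direction[k]
    target <- emcModel(schedule$rh[k], branch, kinetics)
    targets[k] <- target
    tl <- seq(0, maxMin, by = cyc)
    mcTrue <- stepKinetics(mcPrev, target, tau, tl)
    massTrue <- m0 * (1 + mcTrue / 100)
    massObs <- massTrue + stats::rnorm(length(tl),
                                       sd = kinetics@balanceNoiseSdMg)
    massObs <- pmax(massObs, 1e-6)
    # advance at the first weighing past the minimum cycle time where the
    # analyzer's criterion holds on the observed masses, else at maxMin
    endIdx <- length(tl)
    stepEq <- FALSE
    np <- policy@minPoints
    for (i in seq_along(tl)) {
      if (tl[i] < minMin || i < np) next
      win <- data.frame(t = tl[(i - np + 1L):i],
                        mass = massObs[(i - np + 1L):i])
      if (diff(range(win$t)) < policy@window * (1 - 1e-9)) next
      if (isEquilibrium(win, policy)) { endIdx <- i; stepEq <- TRUE; break }
    }
    if (!stepEq) {
      i <- length(tl)
      win <- data.frame(t = tl[(i - np + 1L):i],
                        mass = massObs[(i - np + 1L):i])
      stepEq <- tryCatch(isEquilibrium(win, policy),
                         error = function(e) FALSE)
    }
    reached[k] <- stepEq
    sel <- seq_len(endIdx)
    sR <- swellingFromMc(pmax(mcTrue[sel], 0), sample, "radial")
    sT <- swellingFromMc(pmax(mcTrue[sel], 0), sample, "tangential")
    wR <- sample@wRdry * (1 + sR / 100)
    wT <- sample@wTdry * (1 + sT / 100)
    logs[[k]] <- data.frame(
      sample_id = sampleId, t_min = tOffset + tl[sel],
      mass_mg = massObs[sel], rh_set_pct = schedule$rh[k],
      rh_meas_pct = schedule$rh[k] +
        stats::rnorm(endIdx, sd = 0.2),
      temp_C = 20)
    dims[[k]] <- data.frame(
      t = tOffset + tl[sel],
      w_r_mm = wR + stats::rnorm(endIdx, sd = dimNoiseMm),
      w_t_mm = wT + stats::rnorm(endIdx, sd = dimNoiseMm),
      w_r_true_mm = wR, w_t_true_mm = wT, mc_true = mcTrue[sel])
    mcPrev <- mcTrue[endIdx]
    tOffset <- tOffset + tl[endIdx] + cyc
  }
  list(
    massLog = do.call(rbind, logs),
    dims = do.call(rbind, dims),
    truth = list(
      sampleId = sampleId, species = sample@species, m0 = m0,
      qR = sample@qR, qT = sample@qT, mcOnset = sample@mcOnset,
      wRdry = sample@wRdry, wTdry = sample@wTdry, tau = tau,
      mcInitial = mcInitial, seed = as.integer(seed),
      schedule = schedule, emcTargets = targets,
      reachedEquilibrium = reached))
}

#' Render a specimen frame
#'
#' Draws a uniform background whose colour lies inside the CIELAB
#' background thresholds, a rotated rectangular specimen of the given true
#' widths in a colour far outside them, a central hole of background
#' colour, and a few small out-of-threshold artifact blobs (each below the
#' artifact-removal bound). Per-pixel Gaussian colour noise emulates sensor
#' noise at a level that essentially never crosses the threshold
#' intervals. Deterministic for a given seed.
#'
#' @param wRmm,wTmm true radial (vertical) and tangential (horizontal)
#'   widths, mm.
#' @param params a \code{\link{RenderParams}}.
#' @param seed integer seed.
#' @param capturedAt capture time, seconds.
#' @param holeDiameter central hole diameter, mm (0 for none).
#' @param drawSample set FALSE to render background and artifacts only.
#' @return an \code{\link{ImageFrame}}.
#' @export
renderFrame <- function(wRmm, wTmm, params = RenderParams(), seed = 1L,
                        capturedAt = 0, holeDiameter = 2,
                        drawSample = TRUE) {
  stopifnot(is(params, "RenderParams"))
  n <- params@imageSize
  sc <- params@scale
  if (drawSample && (wRmm > n * sc || wTmm > n * sc))
    stop("specimen does not fit in the frame", call. = FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))

  cy <- (n + 1) / 2; cx <- (n + 1) / 2
  x <- (rep(seq_len(n), each = n) - cx) * sc    # column offset, mm
  y <- (rep(seq_len(n), times = n) - cy) * sc   # row offset, mm
  inside <- rep(FALSE, n * n)
  if (drawSample) {
    th <- params@rotationDeg * pi / 180
    ct <- cos(th); st <- sin(th)
    u <- ct * x + st * y
    v <- -st * x + ct * y
    inside <- abs(u) <= wTmm / 2 & abs(v) <= wRmm / 2
    if (holeDiameter > 0)
      inside <- inside & (x^2 + y^2 > (holeDiameter / 2)^2)
  }
  # artifact blobs: small discs of sample colour on the background, kept
  # clear of the specimen edges (rejection sampling; a blob that cannot be
  # placed after 200 tries is skipped)
  if (params@artifactCount > 0L) {
    th <- params@rotationDeg * pi / 180
    ct <- cos(th); st <- sin(th)
    for (j in seq_len(params@artifactCount)) {
      area <- stats::runif(1, params@artifactSizeRange[1],
                           params@artifactSizeRange[2])
      rad <- sqrt(area / pi) * sc
      margin <- rad / sc + 2
      for (try in 1:200) {
        ax <- (stats::runif(1, margin, n - margin) - cx) * sc
        ay <- (stats::runif(1, margin, n - margin) - cy) * sc
        if (!drawSample) break
        # disc-rectangle clearance in the specimen frame
        au <- ct * ax + st * ay
        av <- -st * ax + ct * ay
        du <- max(abs(au) - wTmm / 2, 0)
        dv <- max(abs(av) - wRmm / 2, 0)
        if (sqrt(du^2 + dv^2) > rad + 3 * sc) break
        ax <- NA
      }
      if (is.na(ax)) next
      inside <- inside | ((x - ax)^2 + (y - ay)^2 <= rad^2)
    }
  }
  px <- array(0, dim = c(n, n, 3))
  for (ch in 1:3) {
    base <- ifelse(inside, params@sampleRgb[ch], params@backgroundRgb[ch])
    if (params@colorNoiseSd > 0)
      base <- base + stats::rnorm(n * n, sd = params@colorNoiseSd)
    px[, , ch] <- matrix(pmin(pmax(base, 0), 1), n, n)
  }
  ImageFrame(px, capturedAt = capturedAt, scale = sc)
}

#' Write a complete virtual dataset to disk
#'
#' Emits exactly the files the analysis modules consume: the mass log CSV,
#' a frame index CSV plus rendered PNG frames (optionally subsampled with
#' \code{frameStride}), and a manifest JSON with every true parameter for
#' test assertions.
#'
#' @param dir output directory (created if missing).
#' @param sample a \code{\link{VirtualSample}}.
#' @param kinetics a \code{\link{KineticsParams}}.
#' @param render a \code{\link{RenderParams}}; its scale should match
#'   \code{kinetics@scaleMmPerPx}.
#' @param schedule step schedule data.frame.
#' @param seed integer seed.
#' @param policy an \code{\link{EquilibriumPolicy}}.
#' @param frameStride render every \code{frameStride}-th weighing time
#'   (default 1 = all).
#' @param renderFrames set FALSE to skip image rendering entirely.
#' @param mcInitial starting moisture content, percent.
#' @return invisibly, the \code{\link{runVirtualExperiment}} result.
#' @export
writeVirtualDataset <- function(dir, sample = VirtualSample("pine"),
                                kinetics = KineticsParams(),
                                render = RenderParams(),
                                schedule = defaultSchedule(), seed = 1L,
                                policy = EquilibriumPolicy(),
                                frameStride = 1L, renderFrames = TRUE,
                                mcInitial = 80) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir,
                             call. = FALSE)
  run <- runVirtualExperiment(sample, kinetics, schedule, seed = seed,
                              policy = policy, mcInitial = mcInitial)
  utils::write.csv(run$massLog, file.path(dir, "mass_log.csv"),
                   row.names = FALSE)
  idx <- NULL
  if (renderFrames) {
    frameDir <- file.path(dir, "frames")
    dir.create(frameDir, showWarnings = FALSE)
    sel <- seq(1L, nrow(run$dims), by = as.integer(frameStride))
    paths <- character(length(sel))
    for (j in seq_along(sel)) {
      i <- sel[j]
      fr <- renderFrame(run$dims$w_r_true_mm[i], run$dims$w_t_true_mm[i],
                        params = render, seed = seed * 1000L + j,
                        capturedAt = run$dims$t[i] * 60,
                        holeDiameter = sample@holeDiameter)
      paths[j] <- file.path("frames", sprintf("frame_%05d.png", j))
      png::writePNG(fr@pixels, file.path(dir, paths[j]))
    }
    idx <- data.frame(frame_path = paths,
                      captured_at_s = run$dims$t[sel] * 60,
                      sample_id = run$truth$sampleId)
    utils::write.csv(idx, file.path(dir, "frame_index.csv"),
                     row.names = FALSE)
  }
  manifest <- run$truth
  manifest$schedule <- NULL
  manifest$scheduleRh <- run$truth$schedule$rh
  manifest$scheduleDirection <- run$truth$schedule$direction
  manifest$renderScale <- render@scale
  manifest$imageSize <- render@imageSize
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(run)
}
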