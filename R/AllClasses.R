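#' @import methods
NULL

#' Single time-lapse frame of a specimen
#'
#' An RGB frame of a flat specimen on a uniform background, together with its
#' capture time and the fixed optical scale of the imaging system. Pixel
#' values are stored as doubles in \[0, 1\] in an H x W x 3 array
#' (rows x columns x channel).
#'
#' @slot pixels numeric H x W x 3 array, sRGB values in \[0, 1\].
#' @slot capturedAt numeric(1), seconds since experiment start.
#' @slot scale numeric(1), millimetres per pixel (default 0.018).
#' @export
setClass("ImageFrame",
  representation(pixels = "array", capturedAt = "numeric", scale = "numeric"),
  prototype(capturedAt = 0, scale = 0.018))

setValidity("ImageFrame", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (d[1] < 1L || d[2] < 1L)
    return("frame must have at least one row and one column")
  if (!all(is.finite(object@pixels)) ||
      min(object@pixels) < 0 || max(object@pixels) > 1)
    return("pixel values must be finite and in [0, 1]")
  if (length(object@scale) != 1L || !is.finite(object@scale) ||
      object@scale <= 0)
    return("scale must be a single positive number (mm per pixel)")
  if (length(object@capturedAt) != 1L || !is.finite(object@capturedAt) ||
      object@capturedAt < 0)
    return("capturedAt must be a single non-negative number (seconds)")
  TRUE
})

#' @describeIn ImageFrame-class Constructor.
#' @param pixels numeric H x W x 3 array of sRGB values in \[0, 1\].
#' @param capturedAt capture time, seconds since experiment start.
#' @param scale optical scale, mm per pixel.
#' @export
ImageFrame <- function(pixels, capturedAt = 0, scale = 0.018) {
  new("ImageFrame", pixels = pixels, capturedAt = as.numeric(capturedAt),
      scale = as.numeric(scale))
}

setMethod("show", "ImageFrame", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageFrame: %d x %d px, %.4g mm/px, t = %.0f s\n",
              d[1], d[2], object@scale, object@capturedAt))
})

#' CIELAB background thresholds
#'
#' Per-channel \[lo, hi\] intervals describing the image background in CIELAB
#' coordinates (D65 white point, L in \[0, 100\]). A pixel is classified as
#' background when all three of its channel values fall inside their
#' interval; everything else is specimen. Defaults are the calibrated
#' thresholds of the reference measurement system.
#'
#' @slot L,a,b numeric(2) each, \code{c(lo, hi)} bounds per channel.
#' @export
setClass("LabThresholds",
  representation(L = "numeric", a = "numeric", b = "numeric"))

setValidity("LabThresholds", function(object) {
  for (ch in c("L", "a", "b")) {
    v <- slot(object, ch)
    if (length(v) != 2L || !all(is.finite(v)))
      return(sprintf("%s must be c(lo, hi) with finite values", ch))
    if (v[1] > v[2])
      return(sprintf("%s: lo must not exceed hi", ch))
  }
  TRUE
})

#' @describeIn LabThresholds-class Constructor with the calibrated defaults.
#' @param L,a,b numeric(2), \code{c(lo, hi)} background bounds per channel.
#' @export
LabThresholds <- function(L = c(1.821, 17.536),
                          a = c(-2.656, 7.803),
                          b = c(-11.501, 3.916)) {
  new("LabThresholds", L = as.numeric(L), a = as.numeric(a),
      b = as.numeric(b))
}

setMethod("show", "LabThresholds", function(object) {
  cat(sprintf("LabThresholds (background): L [%g, %g], a [%g, %g], b [%g, %g]\n",
              object@L[1], object@L[2], object@a[1], object@a[2],
              object@b[1], object@b[2]))
})

#' Binary specimen mask
#'
#' Binary matrix I with 1 marking specimen pixels, the working object of the
#' geometric pipeline. After cleanup (artifact removal + hole filling) the
#' foreground is a single connected component.
#'
#' @slot mask integer matrix with entries in \{0, 1\}.
#' @export
setClass("SampleMask", representation(mask = "matrix"))

setValidity("SampleMask", function(object) {
  m <- object@mask
  if (!is.numeric(m) && !is.integer(m))
    return("mask must be a numeric/integer matrix")
  if (nrow(m) < 1L || ncol(m) < 1L)
    return("mask must be non-empty")
  if (!all(m == 0L | m == 1L))
    return("mask entries must be 0 or 1")
  TRUE
})

#' @describeIn SampleMask-class Constructor.
#' @param mask matrix of 0/1 values (coerced to integer).
#' @export
SampleMask <- function(mask) {
  storage.mode(mask) <- "integer"
  new("SampleMask", mask = mask)
}

setMethod("show", "SampleMask", function(object) {
  cat(sprintf("SampleMask: %d x %d px, foreground %d px\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask)))
})

#' @describeIn SampleMask-class Extract the underlying 0/1 matrix.
#' @param x a \code{SampleMask}.
#' @export
maskMatrix <- function(x) {
  stopifnot(is(x, "SampleMask"))
  x@mask
}

#' @describeIn SampleMask-class Number of foreground (specimen) pixels.
#' @export
foregroundArea <- function(x) {
  stopifnot(is(x, "SampleMask"))
  sum(x@mask)
}

#' Timestamped balance and climate log for one specimen
#'
#' Ordered records of (time, mass, r.h. setpoint, measured r.h.,
#' temperature) for a single specimen, with the dry reference mass m0 (mass
#' at the equilibrated 0% r.h. state) attached once known.
#'
#' @slot sampleId character(1) specimen identifier.
#' @slot records data.frame with columns \code{t} (minutes), \code{mass}
#'   (mg), \code{rh_set}, \code{rh_meas} (percent), \code{temp} (deg C).
#' @slot m0 numeric(1) dry mass in mg, \code{NA} until determined.
#' @export
setClass("MassSeries",
  representation(sampleId = "character", records = "data.frame",
                 m0 = "numeric"),
  prototype(m0 = NA_real_))

setValidity("MassSeries", function(object) {
  r <- object@records
  need <- c("t", "mass", "rh_set", "rh_meas", "temp")
  if (!all(need %in% names(r)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (nrow(r) > 0) {
    if (is.unsorted(r$t)) return("record times must be non-decreasing")
    if (any(r$mass <= 0)) return("masses must be positive")
    if (any(r$rh_set < 0 | r$rh_set > 100, na.rm = TRUE))
      return("rh_set must lie in [0, 100]")
  }
  if (!is.na(object@m0) && object@m0 <= 0)
    return("m0 must be positive once assigned")
  TRUE
})

#' @describeIn MassSeries-class Constructor.
#' @param sampleId specimen identifier.
#' @param records data.frame of timestamped balance/climate readings.
#' @param m0 dry mass in mg (optional; usually set by
#'   \code{\link{estimateDryMass}}).
#' @export
MassSeries <- function(sampleId, records, m0 = NA_real_) {
  new("MassSeries", sampleId = as.character(sampleId),
      records = as.data.frame(records), m0 = as.numeric(m0))
}

setMethod("show", "MassSeries", function(object) {
  r <- object@records
  cat(sprintf("MassSeries '%s': %d records", object@sampleId, nrow(r)))
  if (nrow(r)) cat(sprintf(", t = [%.0f, %.0f] min", min(r$t), max(r$t)))
  if (!is.na(object@m0)) cat(sprintf(", m0 = %.3f mg", object@m0))
  cat("\n")
})

#' @describeIn MassSeries-class Records accessor.
#' @param x a \code{MassSeries}.
#' @export
massRecords <- function(x) {
  stopifnot(is(x, "MassSeries"))
  x@records
}

#' @describeIn MassSeries-class Specimen identifier accessor.
#' @export
sampleId <- function(x) {
  stopifnot(is(x, "MassSeries"))
  x@sampleId
}

#' @describeIn MassSeries-class Dry mass accessor (NA until assigned).
#' @export
dryMass <- function(x) {
  stopifnot(is(x, "MassSeries"))
  x@m0
}

#' @describeIn MassSeries-class Dry mass replacement.
#' @param value positive dry mass in mg.
#' @export
`dryMass<-` <- function(x, value) {
  stopifnot(is(x, "MassSeries"))
  x@m0 <- as.numeric(value)
  validObject(x)
  x
}

#' Equilibrium detection policy
#'
#' Parameters of the mass-stability criterion: the humidity step is
#' considered equilibrated when the absolute slope of an ordinary
#' least-squares fit of the last \code{minPoints} masses against time,
#' expressed in percent of the window-mean mass per \code{window} minutes,
#' is strictly below \code{threshold}.
#'
#' @slot threshold numeric(1), percent mass change per window (default 0.01).
#' @slot window numeric(1), minutes (default 60).
#' @slot cycle numeric(1), minutes between weighings (default 15).
#' @slot minPoints integer(1), points in the regression window (default 5).
#' @slot minCycleH,maxCycleH numeric(1), minimum/maximum step duration in
#'   hours (36 / 48); enforced by the virtual instrument, not the analyzer.
#' @export
setClass("EquilibriumPolicy",
  representation(threshold = "numeric", window = "numeric", cycle = "numeric",
                 minPoints = "integer", minCycleH = "numeric",
                 maxCycleH = "numeric"))

setValidity("EquilibriumPolicy", function(object) {
  v <- c(object@threshold, object@window, object@cycle,
         object@minPoints, object@minCycleH, object@maxCycleH)
  if (any(!is.finite(v)) || any(v <= 0))
    return("all policy parameters must be positive")
  if (object@minPoints * object@cycle < object@window)
    return("minPoints weighings at the given cycle must cover the window")
  TRUE
})

#' @describeIn EquilibriumPolicy-class Constructor with instrument defaults.
#' @param threshold percent change per window.
#' @param window window length, minutes.
#' @param cycle weighing interval, minutes.
#' @param minPoints regression points.
#' @param minCycleH,maxCycleH step duration bounds, hours.
#' @export
EquilibriumPolicy <- function(threshold = 0.01, window = 60, cycle = 15,
                              minPoints = 5L, minCycleH = 36,
                              maxCycleH = 48) {
  new("EquilibriumPolicy", threshold = threshold, window = window,
      cycle = cycle, minPoints = as.integer(minPoints),
      minCycleH = minCycleH, maxCycleH = maxCycleH)
}

setMethod("show", "EquilibriumPolicy", function(object) {
  cat(sprintf(
    "EquilibriumPolicy: |slope| < %g %%/%g min, %d pts every %g min, cycle %g-%g h\n",
    object@threshold, object@window, object@minPoints, object@cycle,
    object@minCycleH, object@maxCycleH))
})

#' One humidity-setpoint interval of a sorption experiment
#'
#' A slice of a \code{MassSeries} at a constant r.h. setpoint, tagged with
#' its sorption direction, its equilibrium status at step end, and (once the
#' dry mass is known) the equilibrium moisture content.
#'
#' @slot direction "desorption" or "absorption".
#' @slot rhSet setpoint, percent r.h.
#' @slot records data.frame slice of the series records.
#' @slot reachedEquilibrium logical(1).
#' @slot emc numeric(1), percent moisture content at step end (NA until the
#'   dry mass is known or when the step did not equilibrate).
#' @slot tStart,tEnd numeric(1), minutes.
#' @export
setClass("SorptionStep",
  representation(direction = "character", rhSet = "numeric",
                 records = "data.frame", reachedEquilibrium = "logical",
                 emc = "numeric", tStart = "numeric", tEnd = "numeric"),
  prototype(emc = NA_real_))

setMethod("show", "SorptionStep", function(object) {
  cat(sprintf("SorptionStep: %s @ %g%% r.h., t = [%.0f, %.0f] min, %s%s\n",
              object@direction, object@rhSet, object@tStart, object@tEnd,
              if (object@reachedEquilibrium) "equilibrated" else
                "not equilibrated",
              if (is.na(object@emc)) "" else
                sprintf(", EMC = %.2f%%", object@emc)))
})

#' Virtual specimen parameters
#'
#' Ground-truth description of a simulated wood specimen: dry in-plane
#' dimensions, thickness, dry mass, the true differential swelling
#' coefficients per anatomical direction, and the shrink-onset moisture
#' content below which dimensional change is linear in moisture content.
#' Species defaults follow measured means for Scots pine and European beech
#' specimens of 20 x 20 x 1.5 mm with a 2 mm central hole.
#'
#' @slot species character(1), "pine" or "beech" (tag only).
#' @slot wTdry,wRdry numeric(1), dry tangential/radial width, mm.
#' @slot thickness numeric(1), longitudinal thickness, mm.
#' @slot dryMassMg numeric(1), dry mass at 0% r.h., mg.
#' @slot qR,qT numeric(1), differential swelling (percent length change per
#'   percent moisture content), radial/tangential.
#' @slot mcOnset numeric(1), shrink-onset moisture content, percent.
#' @slot holeDiameter numeric(1), central hole diameter, mm.
#' @export
setClass("VirtualSample",
  representation(species = "character", wTdry = "numeric", wRdry = "numeric",
                 thickness = "numeric", dryMassMg = "numeric",
                 qR = "numeric", qT = "numeric", mcOnset = "numeric",
                 holeDiameter = "numeric"))

setValidity("VirtualSample", function(object) {
  v <- c(object@wTdry, object@wRdry, object@thickness, object@dryMassMg,
         object@qR, object@qT, object@mcOnset, object@holeDiameter)
  if (any(!is.finite(v)) || any(v <= 0))
    return("all sample parameters must be positive")
  if (object@qT < object@qR)
    return("tangential differential swelling must be >= radial")
  TRUE
})

#' @describeIn VirtualSample-class Constructor; unset parameters take
#'   species defaults (pine: 306 mg, qR 0.19, qT 0.31, onset 30%; beech:
#'   394 mg, qR 0.15, qT 0.41, onset 40%).
#' @param species "pine" or "beech".
#' @param wTdry,wRdry dry in-plane widths, mm.
#' @param thickness longitudinal thickness, mm.
#' @param dryMassMg dry mass, mg.
#' @param qR,qT differential swelling coefficients.
#' @param mcOnset shrink-onset moisture content, percent.
#' @param holeDiameter central hole diameter, mm.
#' @export
VirtualSample <- function(species = c("pine", "beech"), wTdry = 20,
                          wRdry = 20, thickness = 1.5, dryMassMg = NULL,
                          qR = NULL, qT = NULL, mcOnset = NULL,
                          holeDiameter = 2) {
  species <- match.arg(species)
  def <- switch(species,
    pine  = list(m = 306, qR = 0.19, qT = 0.31, onset = 30),
    beech = list(m = 394, qR = 0.15, qT = 0.41, onset = 40))
  new("VirtualSample", species = species, wTdry = wTdry, wRdry = wRdry,
      thickness = thickness,
      dryMassMg = if (is.null(dryMassMg)) def$m else dryMassMg,
      qR = if (is.null(qR)) def$qR else qR,
      qT = if (is.null(qT)) def$qT else qT,
      mcOnset = if (is.null(mcOnset)) def$onset else mcOnset,
      holeDiameter = holeDiameter)
}

setMethod("show", "VirtualSample", function(object) {
  cat(sprintf(
    "VirtualSample '%s': %g x %g x %g mm, m0 = %g mg, qR = %g, qT = %g, onset = %g%% MC\n",
    object@species, object@wTdry, object@wRdry, object@thickness,
    object@dryMassMg, object@qR, object@qT, object@mcOnset))
})

#' Kinetics and noise parameters of the virtual instrument
#'
#' Exponential single-time-constant sorption kinetics with a diffusion-type
#' thickness scaling (tau proportional to thickness^exponent), a GAB-shaped
#' sorption isotherm with multiplicative absorption/desorption hysteresis,
#' and Gaussian instrument noise for balance and image-edge readings.
#'
#' @slot tauRef numeric(1), time constant in minutes at the reference
#'   thickness of 1.5 mm.
#' @slot thicknessExponent numeric(1), default 2 (Fickian scaling).
#' @slot gabMm,gabC,gabK numeric(1), GAB monolayer capacity (percent MC) and
#'   shape constants of the desorption isotherm.
#' @slot hysteresisRatio numeric(1) in (0, 1]; absorption EMC =
#'   ratio x desorption EMC.
#' @slot balanceNoiseSdMg numeric(1), balance noise SD in mg (default 0.005,
#'   i.e. 5 ug repeatability).
#' @slot dimNoiseSdPx numeric(1), dimension reading noise SD in pixels.
#' @slot scaleMmPerPx numeric(1), scale used to convert pixel noise to mm.
#' @slot cycleMin numeric(1), weighing/frame interval, minutes.
#' @export
setClass("KineticsParams",
  representation(tauRef = "numeric", thicknessExponent = "numeric",
                 gabMm = "numeric", gabC = "numeric", gabK = "numeric",
                 hysteresisRatio = "numeric", balanceNoiseSdMg = "numeric",
                 dimNoiseSdPx = "numeric", scaleMmPerPx = "numeric",
                 cycleMin = "numeric"))

setValidity("KineticsParams", function(object) {
  pos <- c(object@tauRef, object@thicknessExponent, object@gabMm,
           object@gabC, object@gabK, object@hysteresisRatio,
           object@scaleMmPerPx, object@cycleMin)
  if (any(!is.finite(pos)) || any(pos <= 0))
    return("kinetics parameters must be positive")
  if (object@gabK >= 1) return("gabK must be < 1")
  if (object@hysteresisRatio > 1)
    return("hysteresisRatio must be <= 1 (desorption >= absorption)")
  if (object@balanceNoiseSdMg < 0 || object@dimNoiseSdPx < 0)
    return("noise SDs must be non-negative")
  TRUE
})

#' @describeIn KineticsParams-class Constructor with defaults.
#' @param tauRef time constant at 1.5 mm thickness, minutes.
#' @param thicknessExponent thickness scaling exponent.
#' @param gabMm,gabC,gabK GAB isotherm parameters.
#' @param hysteresisRatio absorption/desorption EMC ratio.
#' @param balanceNoiseSdMg balance noise SD, mg.
#' @param dimNoiseSdPx dimension noise SD, px.
#' @param scaleMmPerPx mm per pixel for dimension noise.
#' @param cycleMin weighing interval, minutes.
#' @export
KineticsParams <- function(tauRef = 180, thicknessExponent = 2,
                           gabMm = 6.5, gabC = 8, gabK = 0.75,
                           hysteresisRatio = 0.85,
                           balanceNoiseSdMg = 0.005, dimNoiseSdPx = 0.3,
                           scaleMmPerPx = 0.018, cycleMin = 15) {
  new("KineticsParams", tauRef = tauRef,
      thicknessExponent = thicknessExponent, gabMm = gabMm, gabC = gabC,
      gabK = gabK, hysteresisRatio = hysteresisRatio,
      balanceNoiseSdMg = balanceNoiseSdMg, dimNoiseSdPx = dimNoiseSdPx,
      scaleMmPerPx = scaleMmPerPx, cycleMin = cycleMin)
}

setMethod("show", "KineticsParams", function(object) {
  cat(sprintf(
    "KineticsParams: tau(1.5 mm) = %g min (~thickness^%g), GAB(%g, %g, %g), hysteresis %g\n",
    object@tauRef, object@thicknessExponent, object@gabMm, object@gabC,
    object@gabK, object@hysteresisRatio))
})

#' Rendering parameters of the virtual camera
#'
#' Geometry and appearance of rendered frames: frame size and optical scale,
#' background/sample colours (background inside the CIELAB threshold
#' intervals, sample outside), specimen rotation, and small background
#' artifact blobs below the artifact-removal bound.
#'
#' @slot imageSize integer(1), frame edge length in pixels (default 2046).
#' @slot scale numeric(1), mm per pixel (default 0.018).
#' @slot backgroundRgb,sampleRgb numeric(3), sRGB in \[0, 1\].
#' @slot rotationDeg numeric(1), specimen rotation, degrees.
#' @slot artifactCount integer(1), number of background blobs.
#' @slot artifactSizeRange numeric(2), blob area bounds in pixels (< 7000).
#' @slot colorNoiseSd numeric(1), per-pixel Gaussian colour noise SD.
#' @export
setClass("RenderParams",
  representation(imageSize = "integer", scale = "numeric",
                 backgroundRgb = "numeric", sampleRgb = "numeric",
                 rotationDeg = "numeric", artifactCount = "integer",
                 artifactSizeRange = "numeric", colorNoiseSd = "numeric"))

setValidity("RenderParams", function(object) {
  if (object@imageSize < 8L) return("imageSize too small")
  if (object@scale <= 0) return("scale must be positive")
  for (ch in c("backgroundRgb", "sampleRgb")) {
    v <- slot(object, ch)
    if (length(v) != 3L || any(v < 0) || any(v > 1))
      return(sprintf("%s must be sRGB in [0, 1]", ch))
  }
  if (object@artifactCount < 0L) return("artifactCount must be >= 0")
  r <- object@artifactSizeRange
  if (length(r) != 2L || r[1] <= 0 || r[1] > r[2])
    return("artifactSizeRange must be c(lo, hi) with 0 < lo <= hi")
  if (object@colorNoiseSd < 0) return("colorNoiseSd must be >= 0")
  TRUE
})

#' @describeIn RenderParams-class Constructor with full-resolution defaults.
#' @param imageSize frame edge length, px.
#' @param scale mm per pixel.
#' @param backgroundRgb,sampleRgb sRGB colours in \[0, 1\].
#' @param rotationDeg specimen rotation, degrees.
#' @param artifactCount number of background blobs.
#' @param artifactSizeRange blob area range, px.
#' @param colorNoiseSd per-pixel colour noise SD.
#' @export
RenderParams <- function(imageSize = 2046L, scale = 0.018,
                         backgroundRgb = c(0.105, 0.105, 0.105),
                         sampleRgb = c(0.82, 0.70, 0.55),
                         rotationDeg = 0, artifactCount = 3L,
                         artifactSizeRange = c(50, 3000),
                         colorNoiseSd = 0.003) {
  new("RenderParams", imageSize = as.integer(imageSize), scale = scale,
      backgroundRgb = backgroundRgb, sampleRgb = sampleRgb,
      rotationDeg = rotationDeg, artifactCount = as.integer(artifactCount),
      artifactSizeRange = artifactSizeRange, colorNoiseSd = colorNoiseSd)
}

setMethod("show", "RenderParams", function(object) {
  cat(sprintf("RenderParams: %d x %d px at %g mm/px, rotation %g deg, %d artifacts\n",
              object@imageSize, object@imageSize, object@scale,
              object@rotationDeg, object@artifactCount))
})
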