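#' Convert an RGB frame to CIELAB
#'
#' Channel-wise sRGB to CIELAB conversion under the D65 white point, with
#' lightness on the standard \[0, 100\] scale. The conversion is
#' deterministic: identical inputs map to identical Lab arrays.
#'
#' @param frame an \code{\link{ImageFrame}} or an H x W x 3 sRGB array with
#'   values in \[0, 1\].
#' @return numeric H x W x 3 array of (L, a, b) coordinates.
#' @examples
#' f <- ImageFrame(array(1, dim = c(2, 2, 3)))
#' lab <- toCielab(f)          # white: L = 100, a = b = 0
#' @export
toCielab <- function(frame) {
  px <- if (is(frame, "ImageFrame")) frame@pixels else frame
  d <- dim(px)
  if (length(d) != 3L || d[3] != 3L)
    stop("expected an H x W x 3 RGB array", call. = FALSE)
  lab <- grDevices::convertColor(matrix(px, ncol = 3L),
                                 from = "sRGB", to = "Lab")
  array(lab, dim = d)
}

#' Binarize a CIELAB image against background thresholds
#'
#' A pixel is background (0) when all three Lab channel values fall
#' inside their \code{[lo, hi]} interval (inclusive); any pixel with at
#' least one channel out of range is specimen (1). An empty foreground is
#' allowed at this stage; downstream cleanup reports it.
#'
#' @param lab numeric H x W x 3 CIELAB array (see \code{\link{toCielab}}).
#' @param thresholds a \code{\link{LabThresholds}} object.
#' @return a raw \code{\link{SampleMask}}.
#' @export
binarize <- function(lab, thresholds = LabThresholds()) {
  stopifnot(is(thresholds, "LabThresholds"))
  d <- dim(lab)
  if (length(d) != 3L || d[3] != 3L)
    stop("expected an H x W x 3 Lab array", call. = FALSE)
  if (!all(is.finite(lab))) stop("Lab image must be finite", call. = FALSE)
  bg <- lab[, , 1] >= thresholds@L[1] & lab[, , 1] <= thresholds@L[2] &
        lab[, , 2] >= thresholds@a[1] & lab[, , 2] <= thresholds@a[2] &
        lab[, , 3] >= thresholds@b[1] & lab[, , 3] <= thresholds@b[2]
  SampleMask(matrix(as.integer(!bg), d[1], d[2]))
}

# 8-connected labelling: EBImage::bwlabel (4-connected) plus a union-find
# merge of diagonally adjacent labels.
label8 <- function(m) {
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(round(lab)), nrow(m), ncol(m))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]),  as.vector(lab[-nr, -1])))  # up-right
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  pairs <- unique(pairs)
  parent <- seq_len(nl)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    r1 <- findRoot(pairs[k, 1]); r2 <- findRoot(pairs[k, 2])
    if (r1 != r2) parent[max(r1, r2)] <- min(r1, r2)
  }
  root <- vapply(seq_len(nl), findRoot, integer(1))
  root <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- root[lab[lab > 0L]]
  out
}

#' Remove small connected artifacts from a mask
#'
#' Deletes every 8-connected foreground component whose area is at most
#' \code{maxSize} pixels (the bound is inclusive: a component of exactly
#' \code{maxSize} pixels is removed). Components larger than the bound are
#' retained.
#'
#' @param mask a \code{\link{SampleMask}}.
#' @param maxSize inclusive artifact area bound in pixels (default 7000).
#' @return cleaned \code{\link{SampleMask}}.
#' @export
removeArtifacts <- function(mask, maxSize = 7000) {
  stopifnot(is(mask, "SampleMask"))
  m <- mask@mask
  lab <- label8(m)
  nl <- max(lab)
  if (nl == 0L)
    stop("no specimen found: mask has no foreground component",
         call. = FALSE)
  areas <- tabulate(lab[lab > 0L], nbins = nl)
  keep <- which(areas > maxSize)
  if (length(keep) == 0L)
    stop(sprintf(
      "no specimen found: all %d components have area <= %g px", nl,
      maxSize), call. = FALSE)
  SampleMask(matrix(as.integer(lab %in% keep), nrow(m), ncol(m)))
}

#' Fill interior holes of a mask
#'
#' Every 4-connected background region that does not touch the image border
#' is turned into foreground; border-connected background is left unchanged,
#' so notches open to the border are not treated as holes.
#'
#' @param mask a \code{\link{SampleMask}} with at least one foreground
#'   component.
#' @return \code{\link{SampleMask}} with interior holes filled.
#' @export
fillMaskHoles <- function(mask) {
  stopifnot(is(mask, "SampleMask"))
  m <- mask@mask
  if (sum(m) == 0L)
    stop("mask has no foreground component", call. = FALSE)
  bg <- 1L - m
  lab <- EBImage::bwlabel(bg)                 # 4-connected background
  lab <- matrix(as.integer(round(lab)), nrow(m), ncol(m))
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                     lab[, ncol(lab)]))
  border <- border[border > 0L]
  hole <- lab > 0L & !(lab %in% border)
  m[hole] <- 1L
  SampleMask(m)
}

# Rotate a 0/1 mask about its centre by `angle` degrees in the (col, row)
# frame, bilinear interpolation, re-threshold at 0.5.
rotateMask <- function(m, angle) {
  if (abs(angle) < 1e-12) return(m)
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  nr <- nrow(m); nc <- ncol(m)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  x0 <- rep(seq_len(nc) - cx, each = nr)
  y0 <- rep(seq_len(nr) - cy, times = nc)
  # inverse map: source coordinate of each output pixel
  xs <- ct * x0 + st * y0 + cx
  ys <- -st * x0 + ct * y0 + cy
  x1 <- floor(xs); y1 <- floor(ys)
  dx <- xs - x1; dy <- ys - y1
  pick <- function(r, c) {
    ok <- r >= 1L & r <= nr & c >= 1L & c <= nc
    v <- numeric(length(r))
    v[ok] <- m[cbind(r[ok], c[ok])]
    v
  }
  v <- (1 - dx) * (1 - dy) * pick(y1, x1) +
       dx * (1 - dy) * pick(y1, x1 + 1L) +
       (1 - dx) * dy * pick(y1 + 1L, x1) +
       dx * dy * pick(y1 + 1L, x1 + 1L)
  matrix(as.integer(v >= 0.5), nr, nc)
}

# Tilt of the foreground in degrees, from the minimum-area bounding
# rectangle of the convex hull (rotating calipers over hull-edge angles,
# then a local continuous refinement). Well-posed for square specimens,
# where inertia-tensor principal axes are degenerate.
estimateTilt <- function(m) {
  idx <- which(m == 1L, arr.ind = TRUE)
  if (nrow(idx) < 9L)
    stop("degenerate component: fewer than 9 foreground pixels",
         call. = FALSE)
  x <- idx[, 2]; y <- idx[, 1]
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  k <- length(h)
  if (k < 3L) return(0)
  bboxArea <- function(phi) {
    cp <- cos(phi); sp <- sin(phi)
    xr <- cp * hx + sp * hy
    yr <- -sp * hx + cp * hy
    (diff(range(xr)) + 1) * (diff(range(yr)) + 1)
  }
  ex <- hx[c(2:k, 1)] - hx
  ey <- hy[c(2:k, 1)] - hy
  phis <- unique(atan2(ey, ex) %% (pi / 2))
  areas <- vapply(phis, bboxArea, numeric(1))
  phi0 <- phis[which.min(areas)]
  # refine on a continuous neighbourhood of the best edge angle
  opt <- stats::optimize(bboxArea, interval = phi0 + c(-1, 1) * pi / 90)
  phi <- opt$minimum %% (pi / 2)
  deg <- phi * 180 / pi
  if (deg > 45) deg <- deg - 90          # wrap to (-45, 45]
  # tie toward the smaller-magnitude rotation
  if (abs(abs(deg) - 45) < 1e-9) deg <- abs(deg)
  if (abs(deg) < 1e-4) deg <- 0
  deg
}

#' Align a specimen mask with the image axes
#'
#' Estimates the in-plane tilt of the (single-component) foreground and
#' rotates the mask so its edges are parallel to the image axes; tangential
#' direction is assumed mounted horizontally, and only tilts of at most 45
#' degrees are corrected (ties at exactly 45 degrees resolve toward the
#' smaller-magnitude rotation). The tilt is estimated from the minimum-area
#' bounding rectangle of the foreground convex hull; the mask is resampled
#' bilinearly and re-binarized at 0.5.
#'
#' @param mask a cleaned \code{\link{SampleMask}} (one foreground
#'   component).
#' @return list with elements \code{mask} (aligned \code{SampleMask}) and
#'   \code{angle} (applied correction, degrees; the negative of the
#'   detected tilt).
#' @export
alignRotation <- function(mask) {
  stopifnot(is(mask, "SampleMask"))
  m <- mask@mask
  if (sum(m) < 9L)
    stop("degenerate component: fewer than 9 foreground pixels",
         call. = FALSE)
  tilt <- estimateTilt(m)
  list(mask = SampleMask(rotateMask(m, -tilt)), angle = -tilt)
}

# shared band machinery for the two width estimators
bandWidth <- function(m, f, alongRows) {
  if (length(f) != 1L || !is.finite(f) || f < 1 || f != round(f))
    stop("f must be a positive integer", call. = FALSE)
  f <- as.integer(f)
  if (f %% 2L == 0L)
    stop("f must be odd so that h = (f - 1)/2 is integral", call. = FALSE)
  if (sum(m) == 0L) stop("empty mask: no foreground", call. = FALSE)
  h <- (f - 1L) %/% 2L
  idx <- which(m == 1L, arr.ind = TRUE)
  centre <- if (alongRows) mean(idx[, 2]) else mean(idx[, 1])
  c0 <- floor(centre + 0.5)                       # round half-up
  limit <- if (alongRows) ncol(m) else nrow(m)
  if (c0 - h < 1L || c0 + h > limit)
    stop(sprintf("band [%d, %d] falls outside the image (1..%d)",
                 c0 - h, c0 + h, limit), call. = FALSE)
  band <- (c0 - h):(c0 + h)
  s <- if (alongRows) sum(m[, band]) else sum(m[band, ])
  list(w = s / f, centre = as.integer(c0), h = h)
}

#' Radial (vertical) centre-band width
#'
#' Mean column sum of the binary mask over a band of \code{f} columns
#' centred at the rounded foreground column centroid: the average vertical
#' extent of the specimen across its centre, in pixels.
#'
#' @param mask an aligned \code{\link{SampleMask}}.
#' @param f odd band width in columns (default 81).
#' @return radial width in pixels.
#' @examples
#' m <- matrix(0L, 200, 200); m[40:160, 50:150] <- 1L
#' measureWidthRadial(SampleMask(m), f = 81)   # 121 rows exactly
#' @export
measureWidthRadial <- function(mask, f = 81) {
  stopifnot(is(mask, "SampleMask"))
  bandWidth(mask@mask, f, alongRows = TRUE)$w
}

#' Tangential (horizontal) centre-band width
#'
#' Transpose-symmetric counterpart of \code{\link{measureWidthRadial}}:
#' mean row sum over an \code{f}-row band centred at the rounded foreground
#' row centroid.
#'
#' @inheritParams measureWidthRadial
#' @param f odd band width in rows (default 81).
#' @return tangential width in pixels.
#' @export
measureWidthTangential <- function(mask, f = 81) {
  stopifnot(is(mask, "SampleMask"))
  bandWidth(mask@mask, f, alongRows = FALSE)$w
}

#' Convert a pixel width to millimetres
#'
#' @param wPx width in pixels.
#' @param scale optical scale, mm per pixel (> 0).
#' @return width in mm (\code{wPx * scale}).
#' @export
pxToMm <- function(wPx, scale = 0.018) {
  if (!is.finite(scale) || scale <= 0)
    stop("scale must be positive", call. = FALSE)
  wPx * scale
}

#' Measure one frame end to end
#'
#' Runs the full geometric chain on a frame: CIELAB conversion, background
#' thresholding, artifact removal, hole filling, rotation alignment and the
#' two centre-band width estimators.
#'
#' @param frame an \code{\link{ImageFrame}}.
#' @param thresholds \code{\link{LabThresholds}} background intervals.
#' @param f odd centre-band width (default 81).
#' @param maxArtifactPx inclusive artifact area bound (default 7000).
#' @return one-row data.frame with columns \code{captured_at_s},
#'   \code{angle_deg}, \code{w_cr_px}, \code{w_ct_px}, \code{w_cr_mm},
#'   \code{w_ct_mm}, \code{foreground_area_px}.
#' @export
measureFrame <- function(frame, thresholds = LabThresholds(), f = 81,
                         maxArtifactPx = 7000) {
  stopifnot(is(frame, "ImageFrame"))
  mask <- binarize(toCielab(frame), thresholds)
  mask <- removeArtifacts(mask, maxSize = maxArtifactPx)
  mask <- fillMaskHoles(mask)
  al <- alignRotation(mask)
  wcr <- measureWidthRadial(al$mask, f = f)
  wct <- measureWidthTangential(al$mask, f = f)
  data.frame(
    captured_at_s = frame@capturedAt,
    angle_deg = al$angle,
    w_cr_px = wcr, w_ct_px = wct,
    w_cr_mm = pxToMm(wcr, frame@scale),
    w_ct_mm = pxToMm(wct, frame@scale),
    foreground_area_px = foregroundArea(al$mask))
}
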