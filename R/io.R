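#' Read a single frame from PNG or TIFF
#'
#' Grayscale images are expanded to three channels; an alpha channel is
#' dropped.
#'
#' @param path file path (extension .png, .tif or .tiff).
#' @param capturedAt capture time, seconds since experiment start.
#' @param scale optical scale, mm per pixel.
#' @return an \code{\link{ImageFrame}}.
#' @export
readImageFrame <- function(path, capturedAt = 0, scale = 0.018) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("package 'tiff' is required to read TIFF frames",
             call. = FALSE)
      tiff::readTIFF(path)
    },
    stop("unsupported frame format: .", ext, call. = FALSE))
  if (length(dim(px)) == 2L)
    px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  ImageFrame(px, capturedAt = capturedAt, scale = scale)
}

#' Read a frame index
#'
#' Reads the CSV index of an image sequence (columns \code{frame_path},
#' \code{captured_at_s}, \code{sample_id}), or, when \code{path} is a
#' directory without an index, lists its PNG/TIFF files in filename sort
#' order with capture times \code{NA}.
#'
#' @param path index CSV file or frame directory.
#' @return data.frame \code{frame_path}, \code{captured_at_s},
#'   \code{sample_id}.
#' @export
readFrameIndex <- function(path) {
  if (dir.exists(path)) {
    idxFile <- file.path(path, "frame_index.csv")
    if (file.exists(idxFile)) return(readFrameIndex(idxFile))
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE))
    if (length(files) == 0L)
      stop("no frames found in ", path, call. = FALSE)
    return(data.frame(frame_path = files, captured_at_s = NA_real_,
                      sample_id = "sample"))
  }
  idx <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_path", "captured_at_s", "sample_id")
  if (!all(need %in% names(idx)))
    stop(paste("frame index must have columns:",
               paste(need, collapse = ", ")), call. = FALSE)
  idx
}

#' Read a mass/climate log CSV
#'
#' Expected columns: \code{sample_id}, \code{t_min}, \code{mass_mg},
#' \code{rh_set_pct}, \code{rh_meas_pct}, \code{temp_C} (header
#' mandatory).
#'
#' @param path CSV file path.
#' @return named list of \code{\link{MassSeries}}, one per sample id.
#' @export
readMassLog <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "t_min", "mass_mg", "rh_set_pct", "rh_meas_pct",
            "temp_C")
  if (!all(need %in% names(d)))
    stop(paste("mass log must have columns:", paste(need, collapse = ", ")),
         call. = FALSE)
  if (nrow(d) == 0L) stop("mass log is empty", call. = FALSE)
  out <- lapply(split(d, d$sample_id), function(g) {
    g <- g[order(g$t_min), ]
    MassSeries(g$sample_id[1], data.frame(
      t = g$t_min, mass = g$mass_mg, rh_set = g$rh_set_pct,
      rh_meas = g$rh_meas_pct, temp = g$temp_C))
  })
  out[unique(d$sample_id)]
}

#' Write a per-frame width table
#'
#' @param widths data.frame of \code{\link{measureFrame}} rows with a
#'   \code{sample_id} column.
#' @param path output CSV path.
#' @export
writeWidthTable <- function(widths, path) {
  cols <- c("sample_id", "captured_at_s", "angle_deg", "w_cr_px",
            "w_ct_px", "w_cr_mm", "w_ct_mm", "foreground_area_px")
  utils::write.csv(widths[, intersect(cols, names(widths)), drop = FALSE],
                   path, row.names = FALSE)
}

#' Write a sorption step table
#'
#' @param steps list of \code{\linkS4class{SorptionStep}} objects or a
#'   \code{\link{stepTable}} data.frame.
#' @param path output CSV path.
#' @param sampleId identifier used when \code{steps} is a list.
#' @export
writeStepTable <- function(steps, path, sampleId = "sample") {
  tab <- if (is.data.frame(steps)) steps else stepTable(steps, sampleId)
  utils::write.csv(tab, path, row.names = FALSE)
}
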