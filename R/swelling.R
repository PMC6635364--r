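#' Swelling relative to the dry dimension
#'
#' Percent dimensional change relative to the dry reference,
#' \code{(w - wDry)/wDry * 100}; negative values (dimension below the dry
#' reference) are allowed but flagged with a warning.
#'
#' @param w measured width, mm (vectorized).
#' @param wDry dry reference width, mm (> 0).
#' @return swelling in percent.
#' @export
swellingPercent <- function(w, wDry) {
  if (length(wDry) != 1L || !is.finite(wDry) || wDry <= 0)
    stop("dry reference width must be a single positive number",
         call. = FALSE)
  s <- (w - wDry) / wDry * 100
  if (any(s < 0, na.rm = TRUE))
    warning("negative swelling: dimension below the dry reference",
            call. = FALSE)
  s
}

#' Join dimension and mass streams on a common time axis
#'
#' Maps each image time to a moisture content by linear interpolation of
#' the mass stream (no extrapolation: frames outside the mass record range
#' are dropped with a warning). Requires the dry mass of the series.
#'
#' @param dims data.frame with columns \code{t} (minutes), \code{w_r_mm},
#'   \code{w_t_mm}.
#' @param series a \code{\link{MassSeries}} with the dry mass assigned.
#' @return data.frame \code{t}, \code{w_r_mm}, \code{w_t_mm}, \code{mc}.
#' @export
joinStreams <- function(dims, series) {
  stopifnot(is(series, "MassSeries"))
  if (is.na(dryMass(series)))
    stop("series has no dry mass: run analyzeMassSeries first",
         call. = FALSE)
  need <- c("t", "w_r_mm", "w_t_mm")
  if (!all(need %in% names(dims)))
    stop(paste("dims must have columns:", paste(need, collapse = ", ")),
         call. = FALSE)
  r <- massRecords(series)
  if (nrow(r) < 2L) stop("mass series too short to interpolate",
                         call. = FALSE)
  if (max(dims$t) < min(r$t) || min(dims$t) > max(r$t))
    stop("dimension and mass streams cover disjoint time ranges",
         call. = FALSE)
  mcMass <- suppressWarnings(moistureContent(r$mass, dryMass(series)))
  mc <- stats::approx(r$t, mcMass, xout = dims$t, rule = 1, ties = "ordered")$y
  keep <- !is.na(mc)
  if (!all(keep))
    warning(sprintf("%d frame(s) outside the mass record range dropped",
                    sum(!keep)), call. = FALSE)
  data.frame(t = dims$t[keep], w_r_mm = dims$w_r_mm[keep],
             w_t_mm = dims$w_t_mm[keep], mc = mc[keep])
}

#' Dry reference dimensions at the equilibrated dry state
#'
#' Widths interpolated at the end time of the first equilibrated 0\% r.h.
#' step.
#'
#' @param dims data.frame with columns \code{t}, \code{w_r_mm},
#'   \code{w_t_mm}.
#' @param steps list of \code{\linkS4class{SorptionStep}} objects.
#' @return named numeric: \code{w_r_dry}, \code{w_t_dry} (mm).
#' @export
dryDimensions <- function(dims, steps) {
  tDry <- NA_real_
  for (s in steps) {
    if (s@rhSet == 0 && s@reachedEquilibrium) { tDry <- s@tEnd; break }
  }
  if (is.na(tDry))
    stop("no equilibrated 0% r.h. step: dry dimensions undefined",
         call. = FALSE)
  c(w_r_dry = stats::approx(dims$t, dims$w_r_mm, xout = tDry, rule = 2,
                            ties = "ordered")$y,
    w_t_dry = stats::approx(dims$t, dims$w_t_mm, xout = tDry, rule = 2,
                            ties = "ordered")$y)
}

#' Add swelling columns to a joined series
#'
#' @param joined output of \code{\link{joinStreams}}.
#' @param wRdry,wTdry dry reference widths, mm.
#' @return the input with columns \code{S_r} and \code{S_t} (percent)
#'   appended.
#' @export
swellingSeries <- function(joined, wRdry, wTdry) {
  joined$S_r <- suppressWarnings(swellingPercent(joined$w_r_mm, wRdry))
  joined$S_t <- suppressWarnings(swellingPercent(joined$w_t_mm, wTdry))
  joined
}

#' Isotherm points at the equilibrated step ends
#'
#' One point per equilibrated step: branch, r.h. setpoint, EMC, and the
#' swelling of both directions interpolated at the step-end time. Provides
#' both the EMC-versus-r.h. view (hysteresis visible) and the
#' swelling-versus-MC view (hysteresis collapses).
#'
#' @param steps annotated step list (see \code{\link{assignEmc}}).
#' @param sw swelling series (see \code{\link{swellingSeries}}).
#' @return data.frame \code{branch}, \code{rh_pct}, \code{emc_pct},
#'   \code{S_r_pct}, \code{S_t_pct}.
#' @export
buildIsotherms <- function(steps, sw) {
  keep <- Filter(function(s) s@reachedEquilibrium && !is.na(s@emc), steps)
  if (length(keep) == 0L)
    stop("no equilibrated steps with EMC", call. = FALSE)
  tEnd <- vapply(keep, function(s) s@tEnd, numeric(1))
  data.frame(
    branch = vapply(keep, function(s) s@direction, character(1)),
    rh_pct = vapply(keep, function(s) s@rhSet, numeric(1)),
    emc_pct = vapply(keep, function(s) s@emc, numeric(1)),
    S_r_pct = stats::approx(sw$t, sw$S_r, xout = tEnd, rule = 2,
                            ties = "ordered")$y,
    S_t_pct = stats::approx(sw$t, sw$S_t, xout = tEnd, rule = 2,
                            ties = "ordered")$y)
}

#' Differential swelling
#'
#' Maximum swelling of a direction divided by the shrink-onset moisture
#' content (percent length change per percent MC), rounded for reporting.
#'
#' @param maxS maximum swelling, percent.
#' @param mcOnset shrink-onset moisture content, percent (> 0).
#' @param digits decimals kept for reporting (default 2); use \code{NULL}
#'   for full precision.
#' @return differential swelling coefficient q.
#' @examples
#' differentialSwelling(9.3, 30)    # 0.31
#' differentialSwelling(16.4, 40)   # 0.41
#' @export
differentialSwelling <- function(maxS, mcOnset, digits = 2L) {
  if (!is.finite(mcOnset) || mcOnset <= 0)
    stop("shrink-onset moisture content must be positive", call. = FALSE)
  q <- maxS / mcOnset
  if (is.null(digits)) q else round(q, digits)
}

#' Maximum swelling per direction
#'
#' @param sw swelling series with columns \code{S_r}, \code{S_t}.
#' @return named numeric: \code{max_S_r}, \code{max_S_t} (percent).
#' @export
maxSwelling <- function(sw) {
  if (nrow(sw) == 0L) stop("empty swelling series", call. = FALSE)
  c(max_S_r = max(sw$S_r), max_S_t = max(sw$S_t))
}

#' Shrink-onset moisture content
#'
#' Fixed mode returns the species value (pine 30\%, beech 40\% by
#' default). Detect mode fits a continuous two-segment model, linear below
#' a breakpoint and flat above it, over candidate breakpoints on the
#' observed moisture-content grid and returns the least-squares breakpoint;
#' it requires data on both sides of the plateau and fails on strictly
#' linear data (advising fixed mode).
#'
#' @param joined data.frame with columns \code{mc} and a swelling column.
#' @param mode \code{"fixed"} or \code{"detect"}.
#' @param fixedMc onset used in fixed mode, percent.
#' @param column swelling column used in detect mode (default
#'   \code{"S_t"}).
#' @return onset moisture content, percent.
#' @export
shrinkOnset <- function(joined, mode = c("fixed", "detect"), fixedMc = 30,
                        column = "S_t") {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (!is.finite(fixedMc) || fixedMc <= 0)
      stop("fixedMc must be positive", call. = FALSE)
    return(fixedMc)
  }
  mc <- joined$mc
  s <- joined[[column]]
  ok <- is.finite(mc) & is.finite(s)
  mc <- mc[ok]; s <- s[ok]
  if (length(mc) < 6L)
    stop("detect mode needs at least 6 points; use fixed mode",
         call. = FALSE)
  grid <- sort(unique(mc))
  # candidates must leave at least 2 points on each side
  cand <- grid[grid > grid[2] & grid < grid[length(grid) - 1L]]
  if (length(cand) == 0L)
    stop("no plateau detectable; use fixed mode", call. = FALSE)
  sse <- function(b) {
    x <- pmin(mc, b)
    fit <- stats::lm.fit(cbind(1, x), s)
    sum(fit$residuals^2)
  }
  sses <- vapply(cand, sse, numeric(1))
  sseLin <- sum(stats::lm.fit(cbind(1, mc), s)$residuals^2)
  best <- which.min(sses)
  # a real plateau must beat the single straight line decisively
  if (sses[best] > 0.95 * sseLin)
    stop("no plateau detected (data consistent with a single line); use fixed mode",
         call. = FALSE)
  cand[best]
}

#' Min-max normalization within one sorption step
#'
#' Rescales a step's values so the extrema are exactly 0 and 1.
#'
#' @param x numeric values of one step.
#' @return normalized values in \[0, 1\].
#' @export
normalizeStep <- function(x) {
  x <- as.numeric(x)
  r <- range(x, na.rm = TRUE)
  if (!all(is.finite(r)) || r[1] == r[2])
    stop("normalization undefined: step values are constant",
         call. = FALSE)
  (x - r[1]) / (r[2] - r[1])
}

#' Correlate normalized step dynamics
#'
#' Ordinary least-squares fit (free intercept) of normalized swelling on
#' normalized moisture content within one step, with the coefficient of
#' determination.
#'
#' @param normMc,normS equal-length normalized series (n >= 3).
#' @return list with \code{slope}, \code{intercept}, \code{r2}.
#' @export
correlateDynamics <- function(normMc, normS) {
  if (length(normMc) != length(normS))
    stop("series must have equal length", call. = FALSE)
  if (length(normMc) < 3L)
    stop("at least 3 paired points required", call. = FALSE)
  fit <- stats::lm(normS ~ normMc)
  res <- stats::residuals(fit)
  tss <- sum((normS - mean(normS))^2)
  if (tss == 0)
    stop("swelling series is constant: R^2 undefined", call. = FALSE)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = 1 - sum(res^2) / tss)
}

#' Time to approximate equilibrium
#'
#' Rounds the moisture-content series to three decimals (half away from
#' zero in decimal terms, with a one-ulp guard so values written as .0005
#' round up despite binary representation) and returns the time of the
#' first point whose rounded value equals that of its successor;
#' \code{NA} when no such point exists (no-equilibrium signal).
#'
#' @param t times in minutes (sorted).
#' @param mc moisture contents, percent.
#' @return time in hours, or \code{NA_real_}.
#' @examples
#' timeToEquilibrium(c(0, 15, 30, 45), c(10.0005, 10.0004, 10.0004, 10.0010))
#' # 0.5 h (index 2: first zero successive difference after rounding)
#' @export
timeToEquilibrium <- function(t, mc) {
  if (length(t) != length(mc))
    stop("t and mc must have equal length", call. = FALSE)
  if (length(t) < 2L) return(NA_real_)
  if (is.unsorted(t)) stop("times must be sorted", call. = FALSE)
  r <- sign(mc) * floor(abs(mc) * 1000 + 0.5 + 1e-9) / 1000
  i <- which(diff(r) == 0)
  if (length(i) == 0L) return(NA_real_)
  t[i[1]] / 60
}

#' Per-step normalized dynamics table
#'
#' For every step with at least \code{minFrames} joined frames and
#' non-constant signals, min-max-normalizes moisture content and swelling
#' within the step and fits \code{\link{correlateDynamics}} for each
#' direction.
#'
#' @param steps list of \code{\linkS4class{SorptionStep}} objects.
#' @param sw swelling series (see \code{\link{swellingSeries}}).
#' @param minFrames minimum frames per step (default 5).
#' @return data.frame \code{step_index}, \code{direction}, \code{rh_pct},
#'   \code{dir}, \code{slope}, \code{intercept}, \code{r2}, \code{n}.
#' @export
stepDynamicsTable <- function(steps, sw, minFrames = 5L) {
  rows <- list()
  for (k in seq_along(steps)) {
    s <- steps[[k]]
    sub <- sw[sw$t >= s@tStart & sw$t <= s@tEnd, , drop = FALSE]
    if (nrow(sub) < minFrames) next
    for (dir in c("r", "t")) {
      col <- paste0("S_", dir)
      fit <- tryCatch({
        nm <- normalizeStep(sub$mc)
        ns <- normalizeStep(sub[[col]])
        correlateDynamics(nm, ns)
      }, error = function(e) NULL)
      if (is.null(fit)) next
      rows[[length(rows) + 1L]] <- data.frame(
        step_index = k, direction = s@direction, rh_pct = s@rhSet,
        dir = dir, slope = fit$slope, intercept = fit$intercept,
        r2 = fit$r2, n = nrow(sub))
    }
  }
  if (length(rows) == 0L)
    return(data.frame(step_index = integer(), direction = character(),
                      rh_pct = numeric(), dir = character(),
                      slope = numeric(), intercept = numeric(),
                      r2 = numeric(), n = integer()))
  do.call(rbind, rows)
}
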