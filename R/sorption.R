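#' Moisture content from current and dry mass
#'
#' Moisture content in percent of dry mass, \code{(mU - m0)/m0 * 100}.
#' Negative values (sub-dry transients, balance noise near dryness) are
#' allowed but raise a warning.
#'
#' @param mU current mass, mg (vectorized).
#' @param m0 dry mass at the equilibrated 0\% r.h. state, mg (> 0).
#' @return moisture content in percent.
#' @examples
#' moistureContent(433.4, 394)   # 10
#' @export
moistureContent <- function(mU, m0) {
  if (length(m0) != 1L || !is.finite(m0) || m0 <= 0)
    stop("dry mass m0 must be a single positive number", call. = FALSE)
  mc <- (mU - m0) / m0 * 100
  if (any(mc < 0, na.rm = TRUE))
    warning("negative moisture content: mass below the dry reference",
            call. = FALSE)
  mc
}

#' Mass-stability slope in percent per window
#'
#' Ordinary least-squares slope of mass against time over the supplied
#' records, expressed as percent change of the reference mass per
#' \code{window} minutes. The reference mass is the window mean by default
#' (\code{basis = "mean"}) or the first mass of the window
#' (\code{basis = "first"}). Sign is preserved; the equilibrium criterion
#' applies to the absolute value.
#'
#' @param t times in minutes.
#' @param mass masses in mg.
#' @param window window length in minutes (default 60).
#' @param basis reference-mass convention, \code{"mean"} or \code{"first"}.
#' @return signed slope in percent per window.
#' @export
regressionSlopePct <- function(t, mass, window = 60,
                               basis = c("mean", "first")) {
  basis <- match.arg(basis)
  if (length(t) != length(mass))
    stop("t and mass must have equal length", call. = FALSE)
  if (length(t) < 2L)
    stop("insufficient data: at least 2 records required", call. = FALSE)
  if (diff(range(t)) <= 0)
    stop("records must span a positive time range", call. = FALSE)
  tc <- t - mean(t)
  slopePerMin <- sum(tc * mass) / sum(tc^2)
  ref <- if (basis == "mean") mean(mass) else mass[1]
  slopePerMin * window / ref * 100
}

#' Equilibrium test on the tail of a series
#'
#' TRUE when the absolute regression slope of the last
#' \code{policy@minPoints} records, in percent of the window-mean mass per
#' \code{policy@window} minutes, is strictly below
#' \code{policy@threshold} (a slope of exactly the threshold is not
#' equilibrium).
#'
#' @param x a \code{\link{MassSeries}} or a data.frame with columns
#'   \code{t} and \code{mass}; the last \code{minPoints} records are used.
#' @param policy an \code{\link{EquilibriumPolicy}}.
#' @return logical(1).
#' @export
isEquilibrium <- function(x, policy = EquilibriumPolicy()) {
  stopifnot(is(policy, "EquilibriumPolicy"))
  r <- if (is(x, "MassSeries")) x@records else as.data.frame(x)
  n <- nrow(r)
  if (n < policy@minPoints)
    stop(sprintf("insufficient data: %d records, %d required", n,
                 policy@minPoints), call. = FALSE)
  tail <- r[(n - policy@minPoints + 1L):n, ]
  if (diff(range(tail$t)) < policy@window * (1 - 1e-9))
    stop(sprintf("window records span %.1f min, %g min required",
                 diff(range(tail$t)), policy@window), call. = FALSE)
  slope <- regressionSlopePct(tail$t, tail$mass, window = policy@window)
  abs(slope) < policy@threshold
}

#' Restate the equilibrium threshold per minute
#'
#' The per-window stability threshold expressed per minute, truncated to
#' \code{sigDigits} significant digits (0.01\%/60 min becomes
#' 0.00016\%/min).
#'
#' @param policy an \code{\link{EquilibriumPolicy}}.
#' @param sigDigits significant digits kept (default 2).
#' @return threshold in percent per minute.
#' @export
thresholdPerMinute <- function(policy = EquilibriumPolicy(),
                               sigDigits = 2L) {
  x <- policy@threshold / policy@window
  if (x == 0) return(0)
  p <- floor(log10(abs(x))) - (sigDigits - 1L)
  trunc(x / 10^p) * 10^p
}

#' Default humidity step schedule
#'
#' The standard stepwise schedule: desorption 85, 80, 70, 60, 50, 40, 30,
#' 20, 10, 5, 0\% r.h. followed by absorption 5, 10, 20, 30, 40, 50, 60,
#' 70, 80, 85, 90\% r.h. (22 steps).
#'
#' @return data.frame with columns \code{direction} and \code{rh}.
#' @export
defaultSchedule <- function() {
  data.frame(
    direction = rep(c("desorption", "absorption"), each = 11L),
    rh = c(85, 80, 70, 60, 50, 40, 30, 20, 10, 5, 0,
           5, 10, 20, 30, 40, 50, 60, 70, 80, 85, 90))
}

validateSchedule <- function(schedule) {
  if (!is.data.frame(schedule) ||
      !all(c("direction", "rh") %in% names(schedule)) ||
      nrow(schedule) < 1L)
    stop("schedule must be a data.frame with columns direction, rh",
         call. = FALSE)
  if (any(!schedule$direction %in% c("desorption", "absorption")))
    stop("schedule directions must be 'desorption' or 'absorption'",
         call. = FALSE)
  if (any(schedule$rh < 0 | schedule$rh > 100))
    stop("schedule setpoints must lie in [0, 100]", call. = FALSE)
  if (nrow(schedule) > 1L && any(diff(schedule$rh) == 0))
    stop("consecutive schedule setpoints must differ", call. = FALSE)
  invisible(schedule)
}

#' Segment a mass series into humidity steps
#'
#' Partitions the records into consecutive runs of constant r.h. setpoint
#' and matches the run sequence against a contiguous slice of the schedule
#' (a log may start mid-schedule). Each step is tagged with its direction
#' and tested for equilibrium at its end; EMC is filled in once the dry
#' mass is known (see \code{\link{assignEmc}}). A setpoint sequence that
#' cannot be aligned with the schedule is an error that reports the
#' divergence.
#'
#' @param series a \code{\link{MassSeries}}.
#' @param schedule step schedule data.frame (\code{\link{defaultSchedule}}).
#' @param policy an \code{\link{EquilibriumPolicy}}.
#' @return list of \code{\linkS4class{SorptionStep}} objects.
#' @export
segmentSteps <- function(series, schedule = defaultSchedule(),
                         policy = EquilibriumPolicy()) {
  stopifnot(is(series, "MassSeries"))
  validateSchedule(schedule)
  r <- series@records
  if (nrow(r) == 0L) stop("mass series has no records", call. = FALSE)
  runs <- rle(r$rh_set)
  nRuns <- length(runs$values)
  starts <- which(schedule$rh == runs$values[1])
  startAt <- NA_integer_
  for (s in starts) {
    if (s + nRuns - 1L <= nrow(schedule) &&
        all(schedule$rh[s:(s + nRuns - 1L)] == runs$values)) {
      startAt <- s
      break
    }
  }
  if (is.na(startAt)) {
    sched <- paste(schedule$rh, collapse = ", ")
    seen <- paste(runs$values, collapse = ", ")
    stop(sprintf(
      "observed setpoint sequence [%s] does not match any contiguous slice of the schedule [%s]",
      seen, sched), call. = FALSE)
  }
  ends <- cumsum(runs$lengths)
  begins <- c(1L, utils::head(ends, -1L) + 1L)
  steps <- vector("list", nRuns)
  for (k in seq_len(nRuns)) {
    slice <- r[begins[k]:ends[k], , drop = FALSE]
    eq <- FALSE
    if (nrow(slice) >= policy@minPoints) {
      tail <- slice[(nrow(slice) - policy@minPoints + 1L):nrow(slice), ]
      if (diff(range(tail$t)) >= policy@window * (1 - 1e-9))
        eq <- isEquilibrium(tail, policy)
    }
    steps[[k]] <- new("SorptionStep",
      direction = schedule$direction[startAt + k - 1L],
      rhSet = runs$values[k], records = slice, reachedEquilibrium = eq,
      emc = NA_real_, tStart = slice$t[1], tEnd = slice$t[nrow(slice)])
  }
  steps
}

#' Dry mass from an equilibrated 0% r.h. step
#'
#' The dry reference mass m0 is the final mass of the first 0\% r.h. step
#' that reached equilibrium (when several 0\% steps equilibrated, the first
#' is used).
#'
#' @param steps list of \code{\linkS4class{SorptionStep}} objects.
#' @return dry mass in mg.
#' @export
estimateDryMass <- function(steps) {
  for (s in steps) {
    if (s@rhSet == 0 && s@reachedEquilibrium)
      return(s@records$mass[nrow(s@records)])
  }
  if (!any(vapply(steps, function(s) s@rhSet == 0, logical(1))))
    stop("no 0% r.h. step in the log: dry mass m0 undefined, moisture contents cannot be computed",
         call. = FALSE)
  stop("no 0% r.h. step reached equilibrium: dry mass m0 undefined",
       call. = FALSE)
}

#' Fill in equilibrium moisture contents
#'
#' Sets \code{emc} on every equilibrated step to the moisture content of
#' its last record (the value closest to the asymptote), leaving
#' non-equilibrated steps at NA.
#'
#' @param steps list of \code{\linkS4class{SorptionStep}} objects.
#' @param m0 dry mass in mg.
#' @return the annotated step list.
#' @export
assignEmc <- function(steps, m0) {
  lapply(steps, function(s) {
    if (s@reachedEquilibrium && nrow(s@records) > 0L)
      s@emc <- suppressWarnings(
        moistureContent(s@records$mass[nrow(s@records)], m0))
    s
  })
}

#' Segment, find the dry mass and annotate EMCs in one call
#'
#' @inheritParams segmentSteps
#' @return list with elements \code{series} (dry mass attached),
#'   \code{steps} (annotated list) and \code{table}
#'   (\code{\link{stepTable}} summary).
#' @export
analyzeMassSeries <- function(series, schedule = defaultSchedule(),
                              policy = EquilibriumPolicy()) {
  steps <- segmentSteps(series, schedule, policy)
  m0 <- estimateDryMass(steps)
  dryMass(series) <- m0
  steps <- assignEmc(steps, m0)
  list(series = series, steps = steps,
       table = stepTable(steps, sampleId(series)))
}

#' Tabulate sorption steps
#'
#' @param steps list of \code{\linkS4class{SorptionStep}} objects.
#' @param sampleId specimen identifier for the output table.
#' @return data.frame with columns \code{sample_id}, \code{step_index},
#'   \code{direction}, \code{rh_set_pct}, \code{t_start_min},
#'   \code{t_end_min}, \code{equilibrated}, \code{emc_pct}.
#' @export
stepTable <- function(steps, sampleId = "sample") {
  data.frame(
    sample_id = sampleId,
    step_index = seq_along(steps),
    direction = vapply(steps, function(s) s@direction, character(1)),
    rh_set_pct = vapply(steps, function(s) s@rhSet, numeric(1)),
    t_start_min = vapply(steps, function(s) s@tStart, numeric(1)),
    t_end_min = vapply(steps, function(s) s@tEnd, numeric(1)),
    equilibrated = vapply(steps, function(s) s@reachedEquilibrium,
                          logical(1)),
    emc_pct = vapply(steps, function(s) s@emc, numeric(1)))
}
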