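#' Dose events and dosing regimens
#'
#' A dose event is one administration of the racemate; a regimen is an
#' ordered set of dose events. Per-enantiomer dose is always half the
#' racemic amount.
#'
#' @param time minutes since the first administration.
#' @param route `"iv"` (bolus) or `"oral"`.
#' @param amount_racemic racemic dose (mg/kg body weight).
#' @param fed logical, fed (vs fasted) state; metadata only.
#' @return `dose_event()`: a one-row data frame with class
#'   `c("dose_event", "data.frame")`.
#' @examples
#' dose_event(0, "iv", 5)
#' @export
dose_event <- function(time, route = c("iv", "oral"), amount_racemic, fed = FALSE) {
  route <- match.arg(route)
  stopifnot(is.numeric(time), length(time) == 1L, time >= 0)
  if (!is.numeric(amount_racemic) || amount_racemic <= 0) {
    stop("'amount_racemic' must be > 0", call. = FALSE)
  }
  out <- data.frame(time = time, route = route,
                    amount_racemic = amount_racemic, fed = fed)
  class(out) <- c("dose_event", class(out))
  out
}

#' @param ... dose events (from [dose_event()]) in any order of arguments;
#'   event times must be strictly increasing after sorting is checked.
#' @rdname dose_event
#' @return `regimen()`: a data frame of dose events with class
#'   `c("regimen", "data.frame")`.
#' @export
regimen <- function(...) {
  events <- list(...)
  if (length(events) == 1L && is.data.frame(events[[1L]]) &&
      !inherits(events[[1L]], "dose_event")) {
    out <- events[[1L]]
  } else {
    out <- do.call(rbind, lapply(events, as.data.frame))
  }
  need <- c("time", "route", "amount_racemic", "fed")
  if (!all(need %in% names(out))) {
    stop("a regimen needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(out) > 1L && any(diff(out$time) <= 0)) {
    stop("dose times must be strictly increasing", call. = FALSE)
  }
  if (any(out$amount_racemic <= 0)) stop("doses must be > 0", call. = FALSE)
  class(out) <- c("regimen", "data.frame")
  out
}

#' The study dosing regimen
#'
#' Convenience constructor for the study design: a single IV bolus of
#' 5 mg/kg racemate, or the multiple-oral regimen of 5 mg/kg three times a
#' day for five consecutive days. The three daily doses are 6 h apart
#' (within-day offsets 0, 360 and 720 min of a 1440-min day, leaving a 12-h
#' overnight gap), so the regimen has 15 oral doses and dose 13 -- the first
#' dose of day 5 -- falls 5760 min after dose 1.
#'
#' @param route `"oral"` (default, 15 doses) or `"iv"` (single bolus).
#' @param dose racemic dose per administration (mg/kg), default 5.
#' @param n_days number of oral dosing days, default 5.
#' @param offsets within-day dose offsets (min), default `c(0, 360, 720)`.
#' @param day_length minutes per day, default 1440.
#' @return a [regimen()].
#' @examples
#' r <- study_regimen("oral")
#' nrow(r)      # 15
#' r$time[13]   # 5760
#' @export
study_regimen <- function(route = c("oral", "iv"), dose = 5, n_days = 5,
                          offsets = c(0, 360, 720), day_length = 1440) {
  route <- match.arg(route)
  if (route == "iv") {
    return(regimen(dose_event(0, "iv", dose, fed = FALSE)))
  }
  times <- as.vector(outer(offsets, (seq_len(n_days) - 1) * day_length, `+`))
  times <- sort(times)
  evs <- data.frame(time = times, route = "oral", amount_racemic = dose,
                    fed = rep(TRUE, length(times)))
  evs$fed[1] <- FALSE # first oral dose given fasted
  regimen(evs)
}

#' Concentration-time curve container
#'
#' @param analyte one of `"R"`, `"S"`, `"total"`.
#' @param time sampling times (min).
#' @param conc concentrations (ug/mL), non-negative, same length as `time`.
#' @return object of class `conc_curve` (a list with `analyte`, `time`,
#'   `conc`).
#' @export
conc_curve <- function(analyte = c("R", "S", "total"), time, conc) {
  analyte <- match.arg(analyte)
  stopifnot(length(time) == length(conc))
  if (any(conc < -1e-12)) stop("concentrations must be >= 0", call. = FALSE)
  structure(list(analyte = analyte, time = as.numeric(time),
                 conc = pmax(as.numeric(conc), 0)),
            class = "conc_curve")
}

#' @export
print.conc_curve <- function(x, ...) {
  cat(sprintf("<conc_curve> analyte %s, %d samples, t %.4g..%.4g min, Cmax %.4g ug/mL\n",
              x$analyte, length(x$time), min(x$time), max(x$time), max(x$conc)))
  invisible(x)
}

#' @export
as.data.frame.conc_curve <- function(x, ...) {
  data.frame(analyte = x$analyte, time_min = x$time, conc_ug_per_ml = x$conc)
}

#' Pointwise total (R + S) concentration curve
#'
#' Total drug concentration is the sum of the two enantiomer
#' concentrations at matching times.
#'
#' @param curve_R,curve_S [conc_curve()] objects on the same time grid.
#' @return a `conc_curve` with analyte `"total"`.
#' @export
total_curve <- function(curve_R, curve_S) {
  stopifnot(inherits(curve_R, "conc_curve"), inherits(curve_S, "conc_curve"))
  if (length(curve_R$time) != length(curve_S$time) ||
      any(curve_R$time != curve_S$time)) {
    stop("curves must share the same time grid", call. = FALSE)
  }
  conc_curve("total", curve_R$time, curve_R$conc + curve_S$conc)
}
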