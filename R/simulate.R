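#' Simulate an IV bolus of the racemate
#'
#' Closed-form solution of the two-enantiomer model for an intravenous
#' bolus. With `kR = Cl_R/V_R`, `kS = Cl_S/V_S` and inversion rate
#' `kRS = Cl_RtoS/V_R`, the amounts per kg follow
#' `dA_R/dt = -kR*A_R` and `dA_S/dt = kRS*A_R - kS*A_S`, both started at
#' the per-enantiomer dose `D = amount_racemic/2`. The R curve is
#' mono-exponential; the S curve is bi-exponential (its own dose plus the
#' inversion input). The degenerate case `kR ~ kS` is handled by the
#' `t*exp(-k*t)` limiting form.
#'
#' @param params an [enantiomer_params()] object.
#' @param dose a [dose_event()] with route `"iv"`.
#' @param times sampling times in minutes, relative to the first
#'   administration (must be `>= dose$time`; the solution uses time since
#'   this dose).
#' @return a list with `conc_curve` elements `R` and `S`.
#' @examples
#' p <- enantiomer_params(329.9, 10.6, 9.3, 248.5, 1.9)
#' cv <- simulate_iv_bolus(p, dose_event(0, "iv", 5), times = c(0, 5, 30, 120))
#' cv$R$conc[1]  # C0 = 2500/329.9 ~ 7.58 ug/mL
#' @export
simulate_iv_bolus <- function(params, dose, times) {
  validate_enantiomer_params(params)
  if (!inherits(dose, "dose_event") || dose$route != "iv") {
    stop("'dose' must be an IV dose_event", call. = FALSE)
  }
  t <- as.numeric(times) - dose$time
  if (any(t < -1e-9)) stop("times must not precede the dose", call. = FALSE)
  t <- pmax(t, 0)
  D <- 1000 * dose$amount_racemic / 2  # ug/kg per enantiomer
  kR <- params$Cl_R / params$V_R
  kS <- params$Cl_S / params$V_S
  kRS <- params$Cl_RtoS / params$V_R
  cR <- D / params$V_R * exp(-kR * t)
  cS <- D / params$V_S * exp(-kS * t) + kRS * D / params$V_S * conv_exp(kR, kS, t)
  list(R = conc_curve("R", times, cR), S = conc_curve("S", times, cS))
}

#' Simulate a single oral dose of the racemate
#'
#' Adds per-enantiomer first-order absorption depots to the
#' chiral-inversion model. The absorbed input to the R compartment is
#' `ka_R * F_R * D * exp(-ka_R*t)`; the S compartment receives its own
#' depot input plus the systemic inversion flux from R. The solution is a
#' closed tri-exponential form with robust fallbacks for (nearly) equal
#' rate constants.
#'
#' @inheritParams simulate_iv_bolus
#' @param dose a [dose_event()] with route `"oral"`.
#' @return a list with `conc_curve` elements `R` and `S`.
#' @export
simulate_oral <- function(params, dose, times) {
  validate_enantiomer_params(params, need_oral = TRUE)
  if (!inherits(dose, "dose_event") || dose$route != "oral") {
    stop("'dose' must be an oral dose_event", call. = FALSE)
  }
  t <- as.numeric(times) - dose$time
  if (any(t < -1e-9)) stop("times must not precede the dose", call. = FALSE)
  t <- pmax(t, 0)
  D <- 1000 * dose$amount_racemic / 2
  kR <- params$Cl_R / params$V_R
  kS <- params$Cl_S / params$V_S
  kRS <- params$Cl_RtoS / params$V_R
  aR <- params$F_R * D * params$ka_R * conv_exp(kR, params$ka_R, t)
  aS <- params$F_S * D * params$ka_S * conv_exp(kS, params$ka_S, t) +
    kRS * params$F_R * D * params$ka_R * conv3(kR, params$ka_R, kS, t)
  list(R = conc_curve("R", times, aR / params$V_R),
       S = conc_curve("S", times, aS / params$V_S))
}

# time-derivatives of the single-oral-dose curves (used for Tmax location)
oral_curve_deriv <- function(params, dose, times, enantiomer = c("R", "S")) {
  enantiomer <- match.arg(enantiomer)
  t <- pmax(as.numeric(times) - dose$time, 0)
  D <- 1000 * dose$amount_racemic / 2
  kR <- params$Cl_R / params$V_R
  kS <- params$Cl_S / params$V_S
  kRS <- params$Cl_RtoS / params$V_R
  if (enantiomer == "R") {
    params$F_R * D * params$ka_R * dconv_exp(kR, params$ka_R, t) / params$V_R
  } else {
    (params$F_S * D * params$ka_S * dconv_exp(kS, params$ka_S, t) +
       kRS * params$F_R * D * params$ka_R * dconv3(kR, params$ka_R, kS, t)) /
      params$V_S
  }
}

#' Simulate a multiple-dose regimen by superposition
#'
#' The model is linear, so the multi-dose solution is the superposition of
#' single-dose solutions, each on its own time-since-dose axis. Times
#' before the first dose return zero concentration.
#'
#' @inheritParams simulate_iv_bolus
#' @param regimen a [regimen()].
#' @param times sampling times in minutes since the first dose.
#' @return a list with `conc_curve` elements `R` and `S`.
#' @export
simulate_regimen <- function(params, regimen, times) {
  stopifnot(inherits(regimen, "regimen"))
  need_oral <- any(regimen$route == "oral")
  validate_enantiomer_params(params, need_oral = need_oral)
  times <- as.numeric(times)
  cR <- numeric(length(times))
  cS <- numeric(length(times))
  for (i in seq_len(nrow(regimen))) {
    ev <- regimen[i, , drop = FALSE]
    class(ev) <- c("dose_event", "data.frame")
    after <- times >= ev$time
    if (!any(after)) next
    sim <- if (ev$route == "iv") {
      simulate_iv_bolus(params, ev, times[after])
    } else {
      simulate_oral(params, ev, times[after])
    }
    cR[after] <- cR[after] + sim$R$conc
    cS[after] <- cS[after] + sim$S$conc
  }
  list(R = conc_curve("R", times, cR), S = conc_curve("S", times, cS))
}

#' Profile window after a given dose of a regimen
#'
#' Extracts the superposed concentrations at offsets after the `n`-th dose
#' of a regimen, e.g. the rich profiles after oral dose 1 and dose 13.
#'
#' @inheritParams simulate_regimen
#' @param n dose number (1-based).
#' @param offsets sampling offsets after that dose (min).
#' @return a list with `conc_curve` elements `R` and `S`; curve times are
#'   the offsets (time after dose `n`).
#' @export
regimen_window <- function(params, regimen, n, offsets) {
  stopifnot(inherits(regimen, "regimen"), n >= 1, n <= nrow(regimen))
  t0 <- regimen$time[n]
  sim <- simulate_regimen(params, regimen, t0 + offsets)
  list(R = conc_curve("R", offsets, sim$R$conc),
       S = conc_curve("S", offsets, sim$S$conc))
}
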