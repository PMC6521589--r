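# Per-subject nonlinear least-squares estimation.
#
# All fits use bounded Levenberg-Marquardt (minpack.lm::nls.lm) on
# log-transformed positive parameters, with proportional (1/yhat)
# weighting: residual_i = (obs_i - pred_i) / pred_i. Concentrations within
# a profile span orders of magnitude, so unweighted least squares would be
# dominated by the early samples.

.pred_floor <- 1e-8

.lm_control <- function() {
  minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15, gtol = 0,
                             maxiter = 1000, maxfev = 100000)
}

# run nls.lm from a base start and, if it fails to converge, from jittered
# starts; ties broken by lowest weighted RSS
.nlfit <- function(par0, lower, upper, resid_fn) {
  jitters <- list(rep(0, length(par0)))
  run1 <- function(shift) {
    p0 <- pmin(pmax(par0 + shift, lower), upper)
    fit <- try(minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                                  fn = resid_fn, control = .lm_control()),
               silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    fit
  }
  best <- run1(jitters[[1L]])
  converged <- !is.null(best) && best$info %in% 1:4
  if (!converged) {
    for (shift in list(rep(log(0.5), length(par0)), rep(log(2), length(par0)),
                       log(seq(0.6, 1.6, length.out = length(par0))))) {
      alt <- run1(shift)
      if (is.null(alt)) next
      if (is.null(best) || alt$deviance < best$deviance) best <- alt
    }
    converged <- !is.null(best) && best$info %in% 1:4
  }
  if (is.null(best)) stop("least-squares optimisation failed from all starts",
                          call. = FALSE)
  list(fit = best, converged = converged)
}

.check_profile <- function(time, conc, n_min, what) {
  if (length(time) != length(conc)) stop("length mismatch", call. = FALSE)
  if (length(conc) < n_min) {
    stop(sprintf("%s needs at least %d observations, got %d",
                 what, n_min, length(conc)), call. = FALSE)
  }
  if (all(conc <= 0)) stop(sprintf("%s: all concentrations are zero", what),
                           call. = FALSE)
}

# crude NCA-based initial V and Cl for one analyte (dose in ug/kg)
.init_v_cl <- function(time, conc, dose_ug) {
  ord <- order(time)
  time <- time[ord]; conc <- conc[ord]
  c_first <- conc[which(conc > 0)[1L]]
  V0 <- dose_ug / max(c_first, .pred_floor)
  lz <- terminal_lambda_z(time, conc)
  Cl0 <- if (!is.na(lz$auc_0_inf) && lz$auc_0_inf > 0) {
    dose_ug / lz$auc_0_inf
  } else {
    dose_ug / max(auc_lin_up_log_down(time, conc), .pred_floor)
  }
  c(V = V0, Cl = max(Cl0, 1e-4))
}

#' Fit the chiral-inversion model to IV enantiomer profiles
#'
#' Jointly estimates `V_R`, `Cl_R`, `Cl_RtoS`, `V_S` and `Cl_S` from the
#' R and S concentration profiles of one subject after an IV bolus of the
#' racemate, by bounded Levenberg-Marquardt least squares with
#' proportional (1/yhat) weighting. The inversion clearance is
#' parameterised as a fraction of total `Cl_R`, which enforces
#' `0 <= Cl_RtoS <= Cl_R` structurally. Initial values come from
#' non-compartmental quantities (`V ~ D/C_first`, `Cl ~ D/AUC_inf`), with
#' three deterministic jittered restarts on non-convergence. BLQ records
#' must be excluded beforehand (see [apply_loq_filter()]).
#'
#' @param data data frame with columns `analyte` (`"R"`/`"S"`), `time_min`
#'   (time after the IV dose) and `conc_ug_per_ml`.
#' @param dose_racemic racemic IV dose (mg/kg), default 5.
#' @return an object of class `pk_fit`: list with `params`
#'   ([enantiomer_params()]), weighted `rss`, `converged`, `n_obs`, and
#'   `start` (initial values).
#' @export
fit_iv_enantiomers <- function(data, dose_racemic = 5) {
  stopifnot(all(c("analyte", "time_min", "conc_ug_per_ml") %in% names(data)))
  dR <- data[data$analyte == "R", ]
  dS <- data[data$analyte == "S", ]
  .check_profile(dR$time_min, dR$conc_ug_per_ml, 6L, "IV fit (R)")
  .check_profile(dS$time_min, dS$conc_ug_per_ml, 6L, "IV fit (S)")
  D <- 1000 * dose_racemic / 2
  ev <- dose_event(0, "iv", dose_racemic)

  sR <- .init_v_cl(dR$time_min, dR$conc_ug_per_ml, D)
  sS <- .init_v_cl(dS$time_min, dS$conc_ug_per_ml, D)
  # par = (log V_R, log Cl_R, f = Cl_RtoS/Cl_R, log V_S, log Cl_S)
  par0 <- c(log(sR[["V"]]), log(sR[["Cl"]]), 0.5, log(sS[["V"]]), log(sS[["Cl"]]))
  lower <- c(-Inf, -Inf, 0, -Inf, -Inf)
  upper <- c(Inf, Inf, 1, Inf, Inf)

  unpack <- function(par) {
    enantiomer_params(V_R = exp(par[1L]), Cl_R = exp(par[2L]),
                      Cl_RtoS = par[3L] * exp(par[2L]),
                      V_S = exp(par[4L]), Cl_S = exp(par[5L]))
  }
  resid_fn <- function(par) {
    p <- unpack(par)
    predR <- simulate_iv_bolus(p, ev, dR$time_min)$R$conc
    predS <- simulate_iv_bolus(p, ev, dS$time_min)$S$conc
    c((dR$conc_ug_per_ml - predR) / pmax(predR, .pred_floor),
      (dS$conc_ug_per_ml - predS) / pmax(predS, .pred_floor))
  }

  res <- .nlfit(par0, lower, upper, resid_fn)
  structure(list(params = unpack(res$fit$par),
                 rss = res$fit$deviance,
                 converged = res$converged,
                 n_obs = nrow(dR) + nrow(dS),
                 start = unpack(par0)),
            class = "pk_fit")
}

#' Fit oral absorption parameters with the inversion clearance frozen
#'
#' Sequential second stage of the estimation scheme: the inversion
#' clearance estimated from IV data is fixed (never re-estimated; it is
#' carried into the result bit-identically) and the oral profiles are
#' fitted for `ka_R`, `ka_S`, `F_R` and `F_S`. Bioavailability is not
#' clipped at 1. By default the volumes and clearances are frozen at their
#' IV estimates as well, because re-estimating `V`/`Cl` jointly with `F`
#' from oral data alone is structurally unidentifiable (scaling `V`, `Cl`
#' and `F` of an enantiomer by a common factor leaves both predicted
#' curves unchanged); `refit_vcl = TRUE` is available but ill-conditioned.
#'
#' @param data data frame with columns `analyte`, `time_min` (time after
#'   the oral dose) and `conc_ug_per_ml`.
#' @param cl_rts inversion clearance (mL/(min*kg)) from the IV fit;
#'   required.
#' @param iv_params [enantiomer_params()] from [fit_iv_enantiomers()]
#'   supplying `V_R`, `Cl_R`, `V_S`, `Cl_S`.
#' @param dose_racemic racemic oral dose (mg/kg), default 5.
#' @param refit_vcl logical; re-estimate `V`/`Cl` starting from the IV
#'   values (default `FALSE`).
#' @return a `pk_fit` object whose `params` carry the frozen `Cl_RtoS`.
#' @export
fit_oral_enantiomers <- function(data, cl_rts, iv_params, dose_racemic = 5,
                                 refit_vcl = FALSE) {
  if (missing(cl_rts) || is.null(cl_rts) || is.na(cl_rts)) {
    stop("'cl_rts' (IV-estimated inversion clearance) is required for the sequential oral fit",
         call. = FALSE)
  }
  stopifnot(all(c("analyte", "time_min", "conc_ug_per_ml") %in% names(data)))
  dR <- data[data$analyte == "R", ]
  dS <- data[data$analyte == "S", ]
  .check_profile(dR$time_min, dR$conc_ug_per_ml, 4L, "oral fit (R)")
  .check_profile(dS$time_min, dS$conc_ug_per_ml, 4L, "oral fit (S)")
  D <- 1000 * dose_racemic / 2
  ev <- dose_event(0, "oral", dose_racemic)

  ka_start <- function(d) {
    tm <- cmax_tmax(d$time_min, d$conc_ug_per_ml)$tmax
    if (tm > 0) min(max(1.5 / tm, 1e-4), 2) else 0.05
  }
  f_start <- function(d, Cl) {
    auc <- auc_lin_up_log_down(d$time_min, d$conc_ug_per_ml)
    max(auc * Cl / D, 0.05)
  }
  par0 <- c(log(ka_start(dR)), log(ka_start(dS)),
            log(f_start(dR, iv_params$Cl_R)), log(f_start(dS, iv_params$Cl_S)))
  lower <- rep(-Inf, 4L); upper <- rep(Inf, 4L)
  if (refit_vcl) {
    par0 <- c(par0, log(iv_params$V_R), log(iv_params$Cl_R),
              log(iv_params$V_S), log(iv_params$Cl_S))
    lower <- c(lower, -Inf, log(cl_rts), -Inf, -Inf) # keep Cl_R >= Cl_RtoS
    upper <- c(upper, rep(Inf, 4L))
  }

  unpack <- function(par) {
    p <- list(V_R = iv_params$V_R, Cl_R = iv_params$Cl_R,
              V_S = iv_params$V_S, Cl_S = iv_params$Cl_S)
    if (refit_vcl) {
      p <- list(V_R = exp(par[5L]), Cl_R = exp(par[6L]),
                V_S = exp(par[7L]), Cl_S = exp(par[8L]))
    }
    out <- enantiomer_params(V_R = p$V_R, Cl_R = p$Cl_R, Cl_RtoS = cl_rts,
                             V_S = p$V_S, Cl_S = p$Cl_S,
                             ka_R = exp(par[1L]), ka_S = exp(par[2L]),
                             F_R = exp(par[3L]), F_S = exp(par[4L]))
    out$Cl_RtoS <- cl_rts # exact, bit-identical pass-through
    out
  }
  resid_fn <- function(par) {
    p <- unpack(par)
    predR <- simulate_oral(p, ev, dR$time_min)$R$conc
    predS <- simulate_oral(p, ev, dS$time_min)$S$conc
    c((dR$conc_ug_per_ml - predR) / pmax(predR, .pred_floor),
      (dS$conc_ug_per_ml - predS) / pmax(predS, .pred_floor))
  }

  res <- .nlfit(par0, lower, upper, resid_fn)
  structure(list(params = unpack(res$fit$par),
                 rss = res$fit$deviance,
                 converged = res$converged,
                 n_obs = nrow(dR) + nrow(dS),
                 start = unpack(par0)),
            class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("<pk_fit> %d observations, weighted RSS %.4g, %s\n",
              x$n_obs, x$rss,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  invisible(x)
}

#' Fit a one-compartment model to a total-drug profile
#'
#' Mono-exponential fit (IV bolus) of `V` and `Cl` to the summed-analyte
#' (total drug) curve, or a first-order-absorption fit of `ka` and `F`
#' for oral data with `V` and `Cl` frozen at their IV estimates. Uses the
#' same proportional weighting and NCA-based initialisation as the
#' enantiomer fits. The full racemic dose applies (the total curve is the
#' sum of both enantiomers).
#'
#' @param data data frame with columns `time_min` and `conc_ug_per_ml`.
#' @param dose_racemic racemic dose (mg/kg), default 5.
#' @param route `"iv"` or `"oral"`.
#' @param iv_values for `route = "oral"`: list/vector with `V` and `Cl`
#'   from the IV fit.
#' @return object of class `one_cpt_fit`: list with `V`, `Cl`, `ka`, `F`,
#'   `rss`, `converged`, `n_obs`.
#' @export
fit_total_one_compartment <- function(data, dose_racemic = 5,
                                      route = c("iv", "oral"),
                                      iv_values = NULL) {
  route <- match.arg(route)
  stopifnot(all(c("time_min", "conc_ug_per_ml") %in% names(data)))
  tt <- data$time_min; yy <- data$conc_ug_per_ml
  .check_profile(tt, yy, 3L, "one-compartment fit")
  D <- 1000 * dose_racemic

  if (route == "iv") {
    s <- .init_v_cl(tt, yy, D)
    par0 <- log(c(s[["V"]], s[["Cl"]]))
    pred_fn <- function(par) {
      V <- exp(par[1L]); Cl <- exp(par[2L])
      D / V * exp(-(Cl / V) * tt)
    }
  } else {
    if (is.null(iv_values)) {
      stop("oral one-compartment fit requires 'iv_values' (V and Cl from the IV fit)",
           call. = FALSE)
    }
    V <- iv_values[["V"]]; Cl <- iv_values[["Cl"]]
    tm <- cmax_tmax(tt, yy)$tmax
    ka0 <- if (tm > 0) min(max(1.5 / tm, 1e-4), 2) else 0.05
    F0 <- max(auc_lin_up_log_down(tt, yy) * Cl / D, 0.05)
    par0 <- log(c(ka0, F0))
    pred_fn <- function(par) {
      ka <- exp(par[1L]); FF <- exp(par[2L])
      ke <- Cl / V
      FF * D * ka / V * conv_exp(ke, ka, tt)
    }
  }
  resid_fn <- function(par) {
    pred <- pred_fn(par)
    (yy - pred) / pmax(pred, .pred_floor)
  }
  res <- .nlfit(par0, rep(-Inf, length(par0)), rep(Inf, length(par0)), resid_fn)
  par <- res$fit$par
  out <- if (route == "iv") {
    list(V = exp(par[1L]), Cl = exp(par[2L]), ka = NA_real_, F = NA_real_)
  } else {
    list(V = iv_values[["V"]], Cl = iv_values[["Cl"]],
         ka = exp(par[1L]), F = exp(par[2L]))
  }
  structure(c(out, list(rss = res$fit$deviance, converged = res$converged,
                        n_obs = length(tt))),
            class = "one_cpt_fit")
}

#' @export
print.one_cpt_fit <- function(x, ...) {
  cat(sprintf("<one_cpt_fit> V = %.4g mL/kg, Cl = %.4g mL/(min*kg)", x$V, x$Cl))
  if (!is.na(x$ka)) cat(sprintf(", ka = %.4g 1/min, F = %.4g", x$ka, x$F))
  cat(sprintf(" (%d obs, %s)\n", x$n_obs,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Secondary pharmacokinetic parameters from fitted model parameters
#'
#' For each enantiomer: `C0 = (D/2)/V` (IV) or model-predicted `Cmax`
#' (oral, located by bracketed maximisation of the fitted curve via
#' root-finding on its analytic time-derivative), `Tmax`,
#' `t1/2 = log(2)*V/Cl`, and `AUC_0_inf = (D/2)/Cl` (IV) or
#' `F*(D/2)/Cl` (oral).
#'
#' @param params an [enantiomer_params()] object (oral fields required for
#'   `route = "oral"`).
#' @param dose_racemic racemic dose (mg/kg), default 5.
#' @param route `"iv"` or `"oral"`.
#' @return data frame with one row per enantiomer: `analyte`,
#'   `c0_or_cmax`, `tmax`, `t_half`, `auc_0_inf`.
#' @export
secondary_parameters <- function(params, dose_racemic = 5,
                                 route = c("iv", "oral")) {
  route <- match.arg(route)
  validate_enantiomer_params(params, need_oral = route == "oral")
  D <- 1000 * dose_racemic / 2
  ev <- dose_event(0, route, dose_racemic)
  out <- lapply(c("R", "S"), function(en) {
    V <- if (en == "R") params$V_R else params$V_S
    Cl <- if (en == "R") params$Cl_R else params$Cl_S
    FF <- if (en == "R") params$F_R else params$F_S
    if (route == "iv") {
      data.frame(analyte = en, c0_or_cmax = D / V, tmax = 0,
                 t_half = half_life(V, Cl), auc_0_inf = D / Cl)
    } else {
      tm <- .tmax_bracketed(params, ev, en)
      cm <- if (en == "R") simulate_oral(params, ev, tm)$R$conc
            else simulate_oral(params, ev, tm)$S$conc
      data.frame(analyte = en, c0_or_cmax = cm, tmax = tm,
                 t_half = half_life(V, Cl), auc_0_inf = FF * D / Cl)
    }
  })
  do.call(rbind, out)
}

# locate oral Tmax by root-finding on the analytic curve derivative,
# bracketing the sign change by doubling
.tmax_bracketed <- function(params, ev, enantiomer) {
  dfun <- function(t) oral_curve_deriv(params, ev, t, enantiomer)
  hi <- 10
  while (dfun(hi) > 0 && hi < 1e7) hi <- hi * 2
  if (dfun(hi) > 0) stop("could not bracket Tmax", call. = FALSE)
  lo <- 1e-8
  if (dfun(lo) <= 0) return(0)
  stats::uniroot(dfun, c(lo, hi), tol = 1e-12)$root
}

#' Group summary of per-subject parameter estimates
#'
#' Mean, SD, median and n of each parameter column within each group
#' (the study reports "mean (SD)" per age group). SD is 0 for a single
#' subject.
#'
#' @param data data frame of per-subject results.
#' @param value_cols character vector of numeric columns to summarise.
#' @param by character vector of grouping columns (e.g. `"age_group"`, or
#'   `c("age_group", "sex")`).
#' @return long data frame: grouping columns, `parameter`, `mean`, `sd`,
#'   `median`, `n`.
#' @export
summarize_group <- function(data, value_cols, by = "age_group") {
  stopifnot(all(value_cols %in% names(data)), all(by %in% names(data)))
  if (nrow(data) < 1L) stop("empty input", call. = FALSE)
  key <- interaction(data[by], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(seq_len(nrow(data)), key), function(idx) {
    g <- data[idx, , drop = FALSE]
    do.call(rbind, lapply(value_cols, function(vc) {
      v <- g[[vc]][!is.na(g[[vc]])]
      cbind(g[1L, by, drop = FALSE],
            data.frame(parameter = vc,
                       mean = mean(v),
                       sd = if (length(v) > 1L) stats::sd(v) else 0,
                       median = stats::median(v),
                       n = length(v)))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
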