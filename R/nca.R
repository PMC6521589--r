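#' Linear-up/log-down trapezoidal AUC
#'
#' Area under the concentration-time curve by the linear-up/log-down
#' trapezoidal rule: a segment uses the linear trapezoid when the
#' concentration is non-decreasing or either endpoint is zero, and the
#' logarithmic trapezoid `(C_i - C_{i+1}) * dt / log(C_i / C_{i+1})` when
#' it is strictly decreasing with both endpoints positive. When `t_end`
#' falls inside a segment, the partial area is computed by interpolating
#' within that segment with the segment's own rule.
#'
#' @param time strictly increasing sampling times (min).
#' @param conc non-negative concentrations (ug/mL).
#' @param t_end end of integration (min); defaults to the last sample. No
#'   extrapolation beyond the last sample is performed: `t_end` past the
#'   last time returns the AUC to the last sample (with a warning).
#' @return AUC in ug*min/mL.
#' @examples
#' auc_lin_up_log_down(c(0, 60, 120), c(10, 20, 10))  # 1765.62
#' @export
auc_lin_up_log_down <- function(time, conc, t_end = NULL) {
  time <- as.numeric(time); conc <- as.numeric(conc)
  if (length(time) < 2L) stop("need at least 2 points", call. = FALSE)
  if (length(time) != length(conc)) stop("length mismatch", call. = FALSE)
  if (any(diff(time) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (is.null(t_end)) t_end <- time[length(time)]
  if (t_end < time[1L]) stop("'t_end' precedes the first sample", call. = FALSE)
  if (t_end > time[length(time)] + 1e-9) {
    warning("'t_end' is beyond the last observation; AUC computed to the last sample (no extrapolation)")
    t_end <- time[length(time)]
  }
  auc <- 0
  for (i in seq_len(length(time) - 1L)) {
    t1 <- time[i]; t2 <- time[i + 1L]
    if (t1 >= t_end) break
    c1 <- conc[i]; c2 <- conc[i + 1L]
    partial <- t2 > t_end
    log_seg <- (c2 < c1) && c1 > 0 && c2 > 0
    if (partial) {
      # interpolate the segment's concentration at t_end with its own rule
      frac <- (t_end - t1) / (t2 - t1)
      c2 <- if (log_seg) c1 * (c2 / c1)^frac else c1 + frac * (c2 - c1)
      t2 <- t_end
    }
    auc <- auc + if (log_seg) {
      (c1 - c2) * (t2 - t1) / log(c1 / c2)
    } else {
      0.5 * (c1 + c2) * (t2 - t1)
    }
  }
  auc
}

#' Maximum concentration and its time
#'
#' Ties are broken toward the earliest time.
#'
#' @inheritParams auc_lin_up_log_down
#' @return list with `cmax` (ug/mL) and `tmax` (min, an observed time).
#' @export
cmax_tmax <- function(time, conc) {
  stopifnot(length(time) == length(conc), length(time) >= 1L)
  i <- which.max(conc) # which.max returns the first maximum
  list(cmax = conc[i], tmax = time[i])
}

#' Terminal slope, half-life and extrapolated AUC
#'
#' Log-linear regression over terminal samples. The regression window is
#' chosen among the last 3 to 6 strictly positive samples (the sample at
#' Tmax is never included) by best adjusted R-squared. `lambda_z` is the
#' negative slope; `t_half = log(2)/lambda_z`;
#' `AUC_0_inf = AUC_0_tlast + C_last/lambda_z` with the
#' linear-up/log-down rule for the observed part.
#'
#' @inheritParams auc_lin_up_log_down
#' @return list with `lambda_z` (1/min), `t_half` (min), `auc_0_tlast`,
#'   `auc_0_inf` (ug*min/mL), `n_points_lambda_z`, `adj_r2`. When fewer
#'   than 3 usable terminal points exist or the fitted slope is
#'   non-negative, the lambda-z-dependent outputs are `NA` (flagged
#'   missing, not an error).
#' @export
terminal_lambda_z <- function(time, conc) {
  time <- as.numeric(time); conc <- as.numeric(conc)
  stopifnot(length(time) == length(conc))
  missing_out <- list(lambda_z = NA_real_, t_half = NA_real_,
                      auc_0_tlast = NA_real_, auc_0_inf = NA_real_,
                      n_points_lambda_z = NA_integer_, adj_r2 = NA_real_)
  pos <- conc > 0
  if (sum(pos) < 3L) return(missing_out)
  tmax_i <- which.max(conc)
  usable <- which(pos & seq_along(conc) != tmax_i & time > time[tmax_i])
  if (tmax_i == 1L) usable <- which(pos & seq_along(conc) != tmax_i)
  if (length(usable) < 3L) return(missing_out)
  best <- NULL
  for (n in 3:min(6L, length(usable))) {
    idx <- utils::tail(usable, n)
    fit <- stats::lm(log(conc[idx]) ~ time[idx])
    # summary.lm warns on numerically perfect fits; harmless here
    ar2 <- suppressWarnings(summary(fit)$adj.r.squared)
    if (is.null(best) || (is.finite(ar2) && ar2 > best$ar2 + 1e-12)) {
      best <- list(idx = idx, fit = fit, ar2 = ar2)
    }
  }
  lambda <- -unname(stats::coef(best$fit)[2L])
  if (!is.finite(lambda) || lambda <= 0) return(missing_out)
  last_pos <- max(which(pos))
  auc_last <- auc_lin_up_log_down(time[seq_len(last_pos)], conc[seq_len(last_pos)])
  list(lambda_z = lambda,
       t_half = log(2) / lambda,
       auc_0_tlast = auc_last,
       auc_0_inf = auc_last + conc[last_pos] / lambda,
       n_points_lambda_z = length(best$idx),
       adj_r2 = best$ar2)
}

#' Full non-compartmental summary of one profile
#'
#' @inheritParams auc_lin_up_log_down
#' @param t_auc time (min) for the truncated AUC (default 180 = 3 h).
#' @return one-row data frame: `cmax`, `tmax`, `auc_0_t`, `auc_0_tlast`,
#'   `auc_0_inf`, `lambda_z`, `t_half`, `n_points_lambda_z`.
#' @export
nca_profile <- function(time, conc, t_auc = 180) {
  ct <- cmax_tmax(time, conc)
  lz <- terminal_lambda_z(time, conc)
  data.frame(cmax = ct$cmax, tmax = ct$tmax,
             auc_0_t = auc_lin_up_log_down(time, conc, t_end = min(t_auc, max(time))),
             auc_0_tlast = if (is.na(lz$auc_0_tlast))
               auc_lin_up_log_down(time, conc) else lz$auc_0_tlast,
             auc_0_inf = lz$auc_0_inf,
             lambda_z = lz$lambda_z, t_half = lz$t_half,
             n_points_lambda_z = lz$n_points_lambda_z)
}

#' Absolute oral bioavailability from truncated AUC ratio
#'
#' Per-subject `F = (AUC_0-3h,PO / dose_PO) / (AUC_0-3h,IV / dose_IV)`,
#' with both AUCs by the linear-up/log-down rule interpolated to exactly
#' `t_end` (default 180 min). Not clipped at 1.
#'
#' @param time_po,conc_po oral profile (time after the oral dose).
#' @param time_iv,conc_iv IV profile (time after the IV dose).
#' @param dose_po,dose_iv administered doses (same units, default equal).
#' @param t_end truncation time (min), default 180.
#' @return list with `F` (fraction), `auc_po`, `auc_iv`.
#' @export
absolute_bioavailability <- function(time_po, conc_po, time_iv, conc_iv,
                                     dose_po = 1, dose_iv = dose_po,
                                     t_end = 180) {
  if (max(time_po) < t_end || max(time_iv) < t_end) {
    stop(sprintf("both profiles must cover at least %g min", t_end), call. = FALSE)
  }
  auc_po <- auc_lin_up_log_down(time_po, conc_po, t_end = t_end)
  auc_iv <- auc_lin_up_log_down(time_iv, conc_iv, t_end = t_end)
  if (auc_iv <= 0) stop("IV AUC is zero; bioavailability undefined", call. = FALSE)
  list(F = (auc_po / dose_po) / (auc_iv / dose_iv),
       auc_po = auc_po, auc_iv = auc_iv)
}

#' Accumulation ratio over one dosing interval
#'
#' Ratio of the AUC over one 6-h dosing interval (0-360 min) after a late
#' dose (dose 13 in the study regimen) to that after the first dose, both
#' by the linear-up/log-down rule. A ratio near 1 indicates no
#' accumulation.
#'
#' @param time_1,conc_1 profile after dose 1 (time after that dose).
#' @param time_n,conc_n profile after the later dose (time after that dose).
#' @param interval dosing interval (min), default 360.
#' @return list with `ratio`, `auc_dose_n`, `auc_dose_1`.
#' @export
accumulation_ratio <- function(time_1, conc_1, time_n, conc_n, interval = 360) {
  auc1 <- auc_lin_up_log_down(time_1, conc_1, t_end = interval)
  aucn <- auc_lin_up_log_down(time_n, conc_n, t_end = interval)
  if (auc1 <= 0) stop("dose-1 AUC is zero; ratio undefined", call. = FALSE)
  list(ratio = aucn / auc1, auc_dose_n = aucn, auc_dose_1 = auc1)
}

#' Exclude records below the limit of quantification
#'
#' Removes records with concentration strictly below the LOQ (values equal
#' to the LOQ are retained) or flagged BLQ, and counts the removals.
#'
#' @param records a data frame with a `conc_ug_per_ml` column and
#'   optionally a logical `blq` column (honored if present).
#' @param loq limit of quantification (ug/mL), default 0.25.
#' @return list with `records` (filtered data frame) and `n_removed`.
#' @export
apply_loq_filter <- function(records, loq = 0.25) {
  stopifnot(is.data.frame(records), "conc_ug_per_ml" %in% names(records))
  below <- records$conc_ug_per_ml < loq
  if ("blq" %in% names(records)) below <- below | isTRUE_vec(records$blq)
  list(records = records[!below, , drop = FALSE], n_removed = sum(below))
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
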