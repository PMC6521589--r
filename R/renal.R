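# Renal marker clearance models.
#
# Glomerular filtration rate (GFR) is the plasma clearance of iohexol,
# estimated with a two-compartment (bi-exponential) bolus model; estimated
# renal plasma flow (eRPF) is the plasma clearance of p-aminohippuric acid
# (PAH), estimated with a one-compartment model. In both cases the
# reported marker clearance is the fitted elimination clearance.

#' Bi-exponential bolus disposition curve
#'
#' `C(t) = A*exp(-alpha*t) + B*exp(-beta*t)`, the macro-constant form of a
#' two-compartment IV bolus model.
#'
#' @param A,B macro intercepts (ug/mL); `alpha`,`beta` macro rates
#'   (1/min), `alpha > beta`.
#' @param alpha,beta macro rate constants (1/min).
#' @param t times (min).
#' @return concentrations (ug/mL).
#' @export
biexp_curve <- function(A, alpha, B, beta, t) {
  A * exp(-alpha * t) + B * exp(-beta * t)
}

#' Clearance from bi-exponential macro constants
#'
#' `Cl = D / AUC_0_inf = D / (A/alpha + B/beta)`. With `B = 0` this
#' reduces to the one-compartment `D*alpha/A`.
#'
#' @inheritParams biexp_curve
#' @param dose_ug dose (ug/kg) matching the concentration units.
#' @return clearance in mL/(min*kg).
#' @export
two_cpt_clearance <- function(A, alpha, B, beta, dose_ug) {
  auc <- A / alpha + if (B > 0) B / beta else 0
  dose_ug / auc
}

# micro-constant parameterisation -> macro constants, per unit BW
.micro_to_macro <- function(V1, Cl, Cld, V2, dose_ug) {
  k10 <- Cl / V1; k12 <- Cld / V1; k21 <- Cld / V2
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  A <- dose_ug * (alpha - k21) / (V1 * (alpha - beta))
  B <- dose_ug * (k21 - beta) / (V1 * (alpha - beta))
  list(A = A, alpha = alpha, B = B, beta = beta)
}

#' Simulate marker disposition curves
#'
#' `simulate_two_cpt()` simulates an IV bolus in a two-compartment model
#' given micro constants (central volume `V1`, elimination clearance `Cl`,
#' inter-compartmental clearance `Cld`, peripheral volume `V2`);
#' `simulate_one_cpt()` the mono-exponential analogue.
#'
#' @param V1,Cl,Cld,V2 micro constants (mL/kg and mL/(min*kg)); all
#'   positive.
#' @param dose_mg_kg marker dose (mg/kg).
#' @param t times (min).
#' @return concentrations (ug/mL).
#' @export
simulate_two_cpt <- function(V1, Cl, Cld, V2, dose_mg_kg, t) {
  stopifnot(V1 > 0, Cl > 0, Cld > 0, V2 > 0)
  m <- .micro_to_macro(V1, Cl, Cld, V2, 1000 * dose_mg_kg)
  biexp_curve(m$A, m$alpha, m$B, m$beta, t)
}

#' @param V one-compartment volume (mL/kg).
#' @rdname simulate_two_cpt
#' @export
simulate_one_cpt <- function(V, Cl, dose_mg_kg, t) {
  stopifnot(V > 0, Cl > 0)
  1000 * dose_mg_kg / V * exp(-(Cl / V) * t)
}

#' Fit the iohexol two-compartment model; clearance reported as GFR
#'
#' Fits `C(t) = A*exp(-alpha*t) + B*exp(-beta*t)` by bounded
#' Levenberg-Marquardt with proportional weighting. The rates are
#' parameterised as `beta` and `delta = alpha - beta > 0`, so the fitted
#' phases can never come back inverted. Clearance
#' `Cl = D/(A/alpha + B/beta)` is reported as the glomerular filtration
#' rate.
#'
#' @param time,conc marker profile (min, ug/mL), time after the marker
#'   bolus.
#' @param dose_mg_kg iohexol dose (mg/kg), study default 64.7.
#' @return object of class `two_cpt_fit`: macro constants `A`, `alpha`,
#'   `B`, `beta`; micro constants `V1`, `Cl`, `Cld`, `V2`; `GFR` (= `Cl`,
#'   mL/(min*kg)); `rss`, `converged`, `n_obs`.
#' @export
fit_iohexol_gfr <- function(time, conc, dose_mg_kg = 64.7) {
  .check_profile(time, conc, 5L, "iohexol fit")
  D <- 1000 * dose_mg_kg
  ord <- order(time)
  tt <- time[ord]; yy <- conc[ord]

  # curve-stripping starts: terminal log-linear fit for (B, beta), then
  # peel the early residuals for (A, alpha)
  nterm <- min(4L, max(3L, length(tt) - 2L))
  iterm <- utils::tail(which(yy > 0), nterm)
  ft <- stats::lm(log(yy[iterm]) ~ tt[iterm])
  beta0 <- max(-unname(stats::coef(ft)[2L]), 1e-6)
  B0 <- max(exp(unname(stats::coef(ft)[1L])), 1e-6)
  resid0 <- yy - B0 * exp(-beta0 * tt)
  iearly <- which(resid0 > 0 & seq_along(tt) <= max(3L, length(tt) - nterm))
  if (length(iearly) >= 2L) {
    fe <- stats::lm(log(resid0[iearly]) ~ tt[iearly])
    alpha0 <- max(-unname(stats::coef(fe)[2L]), 2 * beta0)
    A0 <- max(exp(unname(stats::coef(fe)[1L])), 1e-6)
  } else {
    alpha0 <- 10 * beta0
    A0 <- max(max(yy) - B0, 0.1 * B0)
  }

  par0 <- c(log(A0), log(B0), log(beta0), log(max(alpha0 - beta0, 1e-6)))
  pred_fn <- function(par) {
    A <- exp(par[1L]); B <- exp(par[2L])
    beta <- exp(par[3L]); alpha <- beta + exp(par[4L])
    biexp_curve(A, alpha, B, beta, tt)
  }
  resid_fn <- function(par) {
    pred <- pred_fn(par)
    (yy - pred) / pmax(pred, .pred_floor)
  }
  # physiologic bounds: C0 = A + B cannot exceed dose over a minimal
  # plasma volume (20 mL/kg), and the fast phase cannot be faster than
  # the sampling can support; without these a noisy profile can absorb
  # unbounded area into an unobserved ultra-fast phase and drive Cl to 0
  c0_cap <- log(D / 20)
  upper <- c(c0_cap, c0_cap, log(1), log(5))
  par0 <- pmin(par0, upper - 1e-6)
  res <- .nlfit(par0, rep(-Inf, 4L), upper, resid_fn)
  par <- res$fit$par
  A <- exp(par[1L]); B <- exp(par[2L])
  beta <- exp(par[3L]); alpha <- beta + exp(par[4L])

  V1 <- D / (A + B)
  k21 <- (A * beta + B * alpha) / (A + B)
  k10 <- alpha * beta / k21
  k12 <- alpha + beta - k10 - k21
  Cl <- k10 * V1
  structure(list(A = A, alpha = alpha, B = B, beta = beta,
                 V1 = V1, Cl = Cl, Cld = k12 * V1, V2 = k12 * V1 / k21,
                 GFR = Cl,
                 rss = res$fit$deviance, converged = res$converged,
                 n_obs = length(tt)),
            class = "two_cpt_fit")
}

#' @export
print.two_cpt_fit <- function(x, ...) {
  cat(sprintf("<two_cpt_fit> GFR (Cl) = %.4g mL/(min*kg); V1 = %.4g, V2 = %.4g mL/kg; alpha = %.4g, beta = %.4g 1/min (%d obs, %s)\n",
              x$GFR, x$V1, x$V2, x$alpha, x$beta, x$n_obs,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit the PAH one-compartment model; clearance reported as eRPF
#'
#' Mono-exponential bolus fit with proportional weighting; the clearance
#' is reported as the estimated renal plasma flow (in pigs PAH is also
#' acetylated, hence "estimated").
#'
#' @inheritParams fit_iohexol_gfr
#' @param dose_mg_kg PAH dose (mg/kg), study default 10.
#' @return object of class `one_cpt_fit` with additional element `eRPF`
#'   (= `Cl`, mL/(min*kg)).
#' @export
fit_pah_erpf <- function(time, conc, dose_mg_kg = 10) {
  .check_profile(time, conc, 3L, "PAH fit")
  D <- 1000 * dose_mg_kg
  tt <- time; yy <- conc
  s <- .init_v_cl(tt, yy, D)
  par0 <- log(c(s[["V"]], s[["Cl"]]))
  resid_fn <- function(par) {
    V <- exp(par[1L]); Cl <- exp(par[2L])
    pred <- D / V * exp(-(Cl / V) * tt)
    (yy - pred) / pmax(pred, .pred_floor)
  }
  res <- .nlfit(par0, c(-Inf, -Inf), c(Inf, Inf), resid_fn)
  par <- res$fit$par
  structure(list(V = exp(par[1L]), Cl = exp(par[2L]),
                 ka = NA_real_, F = NA_real_, eRPF = exp(par[2L]),
                 rss = res$fit$deviance, converged = res$converged,
                 n_obs = length(tt)),
            class = "one_cpt_fit")
}
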