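#' Structural parameters of the two-enantiomer one-compartment model
#'
#' Builds the parameter set of the chiral-inversion model: each enantiomer
#' (R and S) distributes in its own apparent one-compartment volume, and the
#' R enantiomer is converted systemically and unidirectionally to S with
#' inversion clearance `Cl_RtoS`.
#'
#' Units are fixed package-wide: volumes in mL/kg, clearances in
#' mL/(min*kg), first-order absorption rate constants in 1/min,
#' bioavailability fractions dimensionless (1 = 100%; values above 1 are
#' allowed because per-subject estimates can exceed 100%). Doses are given
#' in mg/kg of the racemate and converted internally to ug/kg so that
#' concentrations come out in ug/mL.
#'
#' @param V_R,V_S apparent distribution volumes (mL/kg).
#' @param Cl_R total clearance of the R enantiomer (mL/(min*kg)). By
#'   default this is *inclusive* of the inversion route, so clearance to
#'   other routes is `Cl_R - Cl_RtoS`; see `convention`.
#' @param Cl_RtoS systemic inversion clearance R -> S (mL/(min*kg)).
#' @param Cl_S total clearance of the S enantiomer (mL/(min*kg)).
#' @param ka_R,ka_S first-order absorption rate constants (1/min); may be
#'   `NA` when only IV dosing is simulated.
#' @param F_R,F_S absolute oral bioavailability fractions; may be `NA` for
#'   IV-only use. Not clipped at 1.
#' @param convention `"total"` (default): `Cl_R` is total R clearance and
#'   must satisfy `Cl_RtoS <= Cl_R`. `"additive"`: the supplied `Cl_R` is
#'   exclusive of inversion and total R clearance is `Cl_R + Cl_RtoS`
#'   (provided for sensitivity analysis; the object always stores the
#'   total-clearance convention).
#'
#' @return An object of class `enantiomer_params`: a named list with
#'   elements `V_R`, `Cl_R`, `Cl_RtoS`, `V_S`, `Cl_S`, `ka_R`, `ka_S`,
#'   `F_R`, `F_S` (total-clearance convention).
#'
#' @examples
#' # one-week-old piglet group means
#' p <- enantiomer_params(V_R = 329.9, Cl_R = 10.6, Cl_RtoS = 9.3,
#'                        V_S = 248.5, Cl_S = 1.9)
#' half_life(p$V_R, p$Cl_R) # ~21.6 min
#' @export
enantiomer_params <- function(V_R, Cl_R, Cl_RtoS, V_S, Cl_S,
                              ka_R = NA_real_, ka_S = NA_real_,
                              F_R = NA_real_, F_S = NA_real_,
                              convention = c("total", "additive")) {
  convention <- match.arg(convention)
  if (convention == "additive") {
    Cl_R <- Cl_R + Cl_RtoS
  }
  p <- list(V_R = V_R, Cl_R = Cl_R, Cl_RtoS = Cl_RtoS,
            V_S = V_S, Cl_S = Cl_S,
            ka_R = ka_R, ka_S = ka_S, F_R = F_R, F_S = F_S)
  class(p) <- "enantiomer_params"
  validate_enantiomer_params(p)
  p
}

validate_enantiomer_params <- function(p, need_oral = FALSE) {
  for (nm in c("V_R", "Cl_R", "V_S", "Cl_S")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
    }
  }
  if (!is.numeric(p$Cl_RtoS) || is.na(p$Cl_RtoS) || p$Cl_RtoS < 0) {
    stop("'Cl_RtoS' must be non-negative", call. = FALSE)
  }
  if (p$Cl_RtoS > p$Cl_R + 1e-12) {
    stop("'Cl_RtoS' must not exceed total 'Cl_R' (inversion is a component of total R clearance)",
         call. = FALSE)
  }
  for (nm in c("ka_R", "ka_S", "F_R", "F_S")) {
    v <- p[[nm]]
    if (!is.na(v) && v < 0) stop(sprintf("'%s' must be >= 0", nm), call. = FALSE)
  }
  if (need_oral) {
    for (nm in c("ka_R", "ka_S", "F_R", "F_S")) {
      if (is.na(p[[nm]])) {
        stop(sprintf("oral simulation requires '%s'", nm), call. = FALSE)
      }
    }
    if (p$ka_R <= 0 || p$ka_S <= 0) stop("'ka' must be > 0 for oral simulation",
                                         call. = FALSE)
  }
  invisible(p)
}

#' @export
print.enantiomer_params <- function(x, ...) {
  cat("Two-enantiomer one-compartment model parameters (per kg)\n")
  cat(sprintf("  R: V = %.4g mL/kg, Cl = %.4g mL/(min*kg), Cl_RtoS = %.4g mL/(min*kg)\n",
              x$V_R, x$Cl_R, x$Cl_RtoS))
  cat(sprintf("  S: V = %.4g mL/kg, Cl = %.4g mL/(min*kg)\n", x$V_S, x$Cl_S))
  if (!is.na(x$ka_R) || !is.na(x$ka_S)) {
    cat(sprintf("  oral: ka_R = %.4g, ka_S = %.4g 1/min; F_R = %.4g, F_S = %.4g\n",
                x$ka_R, x$ka_S, x$F_R, x$F_S))
  }
  invisible(x)
}

#' Elimination half-life from volume and clearance
#'
#' `t1/2 = ln(2) * V / Cl`, in minutes for the package units.
#'
#' @param V apparent volume (mL/kg).
#' @param Cl clearance (mL/(min*kg)).
#' @return half-life in minutes.
#' @export
half_life <- function(V, Cl) log(2) * V / Cl
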