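# Synthetic cohort generator.
#
# Emulates the four-age-group growing-piglet study of racemic ibuprofen:
# 8 treated pigs per group (4 males / 4 females), a single 5 mg/kg IV
# bolus, then 5 mg/kg orally three times a day for five days, with rich
# sampling on the IV day and after oral doses 1 and 13, marker (iohexol /
# PAH) profiles on two occasions, log-normal between-subject variability
# around published group means, combined proportional + additive residual
# error, and censoring at the 0.25 ug/mL LOQ.

#' Reference per-group generating parameters
#'
#' Group means and between-subject SDs of the enantiomer model parameters
#' for the four age groups (1 week, 4 weeks, 8 weeks, 6-7 months), taken
#' from the published study summaries: IV disposition (`V`, `Cl`,
#' `Cl_RtoS`), first-oral-dose absorption (`ka`, `F`, as fractions), the
#' total-drug one-compartment values, and body weight. The 6-7-month body
#' weight is 138 kg, the midpoint of the reported male (134 kg) and
#' female (142 kg) sub-cohorts. Renal-marker generating values (GFR,
#' eRPF and marker volumes) are synthetic defaults chosen to be
#' physiologically plausible for growing pigs, since no marker parameter
#' table was published.
#'
#' @return data frame with one row per age group and paired
#'   `<param>`/`<param>_sd` columns.
#' @export
pig_reference_params <- function() {
  data.frame(
    age_group = c("1wk", "4wk", "8wk", "6-7mo"),
    bw = c(3.0, 7.0, 20.1, 138), bw_sd = c(0.4, 0.8, 3.4, 8),
    # R enantiomer
    V_R = c(329.9, 259.5, 296.0, 139.5), V_R_sd = c(58.8, 41.4, 64.7, 33.1),
    Cl_R = c(10.6, 5.3, 7.5, 3.2), Cl_R_sd = c(2.7, 1.8, 1.0, 2.2),
    Cl_RtoS = c(9.3, 4.6, 3.9, 1.6), Cl_RtoS_sd = c(2.1, 1.5, 0.7, 0.6),
    ka_R = c(0.1, 0.08, 0.03, 0.1), ka_R_sd = c(0.1, 0.1, 0.02, 0.1),
    F_R = c(1.262, 0.679, 1.104, 1.022), F_R_sd = c(0.468, 0.338, 0.552, 0.461),
    # S enantiomer
    V_S = c(248.5, 233.6, 275.4, 137.3), V_S_sd = c(26.2, 90.6, 64.4, 36.0),
    Cl_S = c(1.9, 2.6, 4.9, 2.1), Cl_S_sd = c(0.6, 0.7, 1.6, 0.5),
    ka_S = c(0.07, 0.06, 0.01, 0.01), ka_S_sd = c(0.07, 0.08, 0.009, 0.009),
    F_S = c(0.869, 0.835, 0.866, 0.793), F_S_sd = c(0.226, 0.389, 0.258, 0.437),
    # total drug, one-compartment
    V_tot = c(308.9, 196.0, 293.4, 140.7), V_tot_sd = c(20.9, 58.0, 54.2, 32.6),
    Cl_tot = c(2.3, 3.6, 5.6, 2.2), Cl_tot_sd = c(0.7, 1.1, 1.4, 0.7),
    # renal markers (synthetic defaults, mL/kg and mL/(min*kg))
    gfr = c(2.0, 3.5, 4.5, 2.0), gfr_sd = c(0.4, 0.7, 0.9, 0.4),
    erpf = c(8, 14, 18, 7), erpf_sd = c(1.6, 2.8, 3.6, 1.4),
    iohexol_V1 = c(250, 250, 250, 220), iohexol_V1_sd = c(40, 40, 40, 35),
    iohexol_Cld = c(4, 5, 6, 4), iohexol_Cld_sd = c(0.8, 1, 1.2, 0.8),
    iohexol_V2 = c(150, 150, 150, 130), iohexol_V2_sd = c(30, 30, 30, 26),
    pah_V = c(400, 400, 400, 350), pah_V_sd = c(60, 60, 60, 55),
    stringsAsFactors = FALSE
  )
}

#' Named sampling schedules of the study design
#'
#' Minute grids relative to the relevant dose: the IV day (pre-dose then
#' 5 min to 24 h), the rich oral profiles after doses 1 and 13 (0-6 h),
#' the sparse oral occasions (pre-dose and 30 min), and the renal-marker
#' days (pre-dose to 8 h).
#'
#' @return named list of numeric vectors: `iv`, `oral_rich`,
#'   `oral_sparse`, `marker`.
#' @export
sampling_schedules <- function() {
  list(
    iv = c(0, 5, 10, 20, 30, 45, 60, 90, 120, 150, 180, 240, 360, 480, 1440),
    oral_rich = c(0, 5, 10, 20, 30, 45, 60, 75, 90, 105, 120, 150, 180, 240, 360),
    oral_sparse = c(0, 30),
    marker = c(0, 5, 10, 30, 60, 120, 180, 360, 480)
  )
}

#' Cohort specification
#'
#' Bundles everything the generator needs: per-group generating means and
#' SDs, group sizes, dosing regimen, sampling schedules, and the residual
#' error model.
#'
#' @param groups reference parameter table, default
#'   [pig_reference_params()].
#' @param n_per_group treated pigs per age group (default 8: 4 males,
#'   4 females).
#' @param error_model list with `prop` (proportional residual SD,
#'   fraction, default 0.10), `add` (additive residual SD, ug/mL, default
#'   0.05), `loq` (ug/mL, default 0.25), and metadata `lod_R`/`lod_S`.
#' @param dose racemic dose per administration (mg/kg), default 5.
#' @param schedules named schedule list, default [sampling_schedules()].
#' @param cor_cl_inversion correlation of `log(Cl_R)` and `log(Cl_RtoS)`
#'  between-subject draws (default 0.98, reflecting that inversion is the
#'  dominant component of R clearance in piglets); draws violating
#'   `Cl_RtoS < Cl_R` are rejected and redrawn.
#' @return object of class `cohort_spec` (a list).
#' @export
cohort_spec <- function(groups = pig_reference_params(),
                        n_per_group = 8,
                        error_model = list(prop = 0.10, add = 0.05, loq = 0.25,
                                           lod_R = 0.128, lod_S = 0.165),
                        dose = 5,
                        schedules = sampling_schedules(),
                        cor_cl_inversion = 0.98) {
  stopifnot(n_per_group >= 1, error_model$prop >= 0, error_model$add >= 0)
  structure(list(groups = groups, n_per_group = n_per_group,
                 error_model = error_model, dose = dose,
                 schedules = schedules,
                 cor_cl_inversion = cor_cl_inversion),
            class = "cohort_spec")
}

# moment-matched log-normal draw: arithmetic mean m, arithmetic SD s
.rlnorm_mm <- function(n, m, s, z = NULL) {
  if (s <= 0) return(rep(m, n))
  sigma2 <- log(1 + (s / m)^2)
  mu <- log(m) - sigma2 / 2
  if (is.null(z)) z <- stats::rnorm(n)
  exp(mu + sqrt(sigma2) * z)
}

#' Draw virtual subjects with individual parameters
#'
#' Between-subject variability is log-normal with moment-matched mean and
#' SD per parameter. `log(Cl_R)` and `log(Cl_RtoS)` are drawn with
#' correlation `cor_cl_inversion` and any draw violating the structural
#' constraint `Cl_RtoS < Cl_R` is rejected and redrawn (independent draws
#' would violate it frequently in the youngest group, where inversion
#' dominates total R clearance). Deterministic under a fixed seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return data frame, one row per subject: `subject_id`, `age_group`,
#'   `sex`, `bw_kg` and the individual model parameters.
#' @export
draw_subjects <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed))
  g <- spec$groups
  n <- spec$n_per_group
  rho <- spec$cor_cl_inversion
  rows <- lapply(seq_len(nrow(g)), function(i) {
    gr <- g[i, ]
    # correlated Cl_R / Cl_RtoS draws with rejection of constraint violations
    clR <- numeric(n); clRS <- numeric(n)
    for (j in seq_len(n)) {
      for (try in seq_len(200L)) {
        z1 <- stats::rnorm(1)
        z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(1)
        a <- .rlnorm_mm(1, gr$Cl_R, gr$Cl_R_sd, z = z1)
        b <- .rlnorm_mm(1, gr$Cl_RtoS, gr$Cl_RtoS_sd, z = z2)
        if (b < a) break
      }
      if (b >= a) b <- 0.99 * a
      clR[j] <- a; clRS[j] <- b
    }
    data.frame(
      subject_id = sprintf("%s_%02d", gr$age_group, seq_len(n)),
      age_group = gr$age_group,
      sex = rep(c("M", "F"), length.out = n),
      bw_kg = .rlnorm_mm(n, gr$bw, gr$bw_sd),
      V_R = .rlnorm_mm(n, gr$V_R, gr$V_R_sd),
      Cl_R = clR,
      Cl_RtoS = clRS,
      V_S = .rlnorm_mm(n, gr$V_S, gr$V_S_sd),
      Cl_S = .rlnorm_mm(n, gr$Cl_S, gr$Cl_S_sd),
      ka_R = .rlnorm_mm(n, gr$ka_R, gr$ka_R_sd),
      ka_S = .rlnorm_mm(n, gr$ka_S, gr$ka_S_sd),
      F_R = .rlnorm_mm(n, gr$F_R, gr$F_R_sd),
      F_S = .rlnorm_mm(n, gr$F_S, gr$F_S_sd),
      gfr = .rlnorm_mm(n, gr$gfr, gr$gfr_sd),
      erpf = .rlnorm_mm(n, gr$erpf, gr$erpf_sd),
      iohexol_V1 = .rlnorm_mm(n, gr$iohexol_V1, gr$iohexol_V1_sd),
      iohexol_Cld = .rlnorm_mm(n, gr$iohexol_Cld, gr$iohexol_Cld_sd),
      iohexol_V2 = .rlnorm_mm(n, gr$iohexol_V2, gr$iohexol_V2_sd),
      pah_V = .rlnorm_mm(n, gr$pah_V, gr$pah_V_sd),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

.subject_params <- function(row) {
  enantiomer_params(V_R = row$V_R, Cl_R = row$Cl_R, Cl_RtoS = row$Cl_RtoS,
                    V_S = row$V_S, Cl_S = row$Cl_S,
                    ka_R = row$ka_R, ka_S = row$ka_S,
                    F_R = row$F_R, F_S = row$F_S)
}

.add_error <- function(pred, em) {
  n <- length(pred)
  obs <- pred * (1 + stats::rnorm(n, 0, em$prop)) + stats::rnorm(n, 0, em$add)
  pmax(obs, 0)
}

#' Simulate observed study data for a cohort
#'
#' Generates the long-format concentration table of the study: noiseless
#' curves from the chiral-inversion model (and the marker models) at the
#' study sampling schedules, observation error
#' `y = pred*(1 + eps_prop) + eps_add` floored at 0, and BLQ flagging
#' below the LOQ. Pre-dose samples of the IV and first-oral occasions are
#' true zeros (flagged BLQ); the pre-dose sample of the dose-13 occasion
#' is the superposed trough. The marker occasions (start and end of the
#' dosing week) share each subject's marker parameters, i.e. the
#' generated GFR is unchanged between occasions.
#'
#' @param subjects output of [draw_subjects()].
#' @param spec the [cohort_spec()] used to draw them.
#' @param seed integer seed for the residual-error draws.
#' @param occasions subset of
#'   `c("iv", "po_dose1", "po_dose13", "marker_day1", "marker_day2")`.
#' @return a study table (data frame) with columns `subject_id`,
#'   `age_group`, `sex`, `bw_kg`, `occasion`, `analyte`
#'   (`R-IBU`, `S-IBU`, `iohexol`, `PAH`), `time_min` (time after the
#'   occasion's own dose), `conc_ug_per_ml`, `blq`.
#' @export
simulate_cohort <- function(subjects, spec, seed = 1L,
                            occasions = c("iv", "po_dose1", "po_dose13",
                                          "marker_day1", "marker_day2")) {
  stopifnot(inherits(spec, "cohort_spec"))
  occasions <- match.arg(occasions, several.ok = TRUE)
  set.seed(as.integer(seed) + 1L)
  em <- spec$error_model
  sch <- spec$schedules
  oral_reg <- study_regimen("oral", dose = spec$dose)
  out <- list()

  emit <- function(subj, occ, analyte, time, pred) {
    obs <- .add_error(pred, em)
    data.frame(subject_id = subj$subject_id, age_group = subj$age_group,
               sex = subj$sex, bw_kg = subj$bw_kg, occasion = occ,
               analyte = analyte, time_min = time,
               conc_ug_per_ml = obs, blq = obs < em$loq,
               stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(subjects))) {
    subj <- subjects[i, ]
    p <- .subject_params(subj)
    if ("iv" %in% occasions) {
      tg <- sch$iv
      sim <- simulate_iv_bolus(p, dose_event(0, "iv", spec$dose), tg)
      predR <- sim$R$conc; predS <- sim$S$conc
      predR[tg == 0] <- 0; predS[tg == 0] <- 0 # pre-dose sample
      out[[length(out) + 1L]] <- emit(subj, "iv", "R-IBU", tg, predR)
      out[[length(out) + 1L]] <- emit(subj, "iv", "S-IBU", tg, predS)
    }
    if ("po_dose1" %in% occasions) {
      tg <- sch$oral_rich
      sim <- simulate_oral(p, dose_event(0, "oral", spec$dose), tg)
      predR <- sim$R$conc; predS <- sim$S$conc
      predR[tg == 0] <- 0; predS[tg == 0] <- 0
      out[[length(out) + 1L]] <- emit(subj, "po_dose1", "R-IBU", tg, predR)
      out[[length(out) + 1L]] <- emit(subj, "po_dose1", "S-IBU", tg, predS)
    }
    if ("po_dose13" %in% occasions) {
      tg <- sch$oral_rich
      sim <- regimen_window(p, oral_reg, 13, tg)
      out[[length(out) + 1L]] <- emit(subj, "po_dose13", "R-IBU", tg, sim$R$conc)
      out[[length(out) + 1L]] <- emit(subj, "po_dose13", "S-IBU", tg, sim$S$conc)
    }
    for (md in c("marker_day1", "marker_day2")) {
      if (!(md %in% occasions)) next
      tg <- sch$marker
      gi <- simulate_two_cpt(subj$iohexol_V1, subj$gfr, subj$iohexol_Cld,
                             subj$iohexol_V2, 64.7, tg)
      pa <- simulate_one_cpt(subj$pah_V, subj$erpf, 10, tg)
      gi[tg == 0] <- 0; pa[tg == 0] <- 0
      out[[length(out) + 1L]] <- emit(subj, md, "iohexol", tg, gi)
      out[[length(out) + 1L]] <- emit(subj, md, "PAH", tg, pa)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default study design configuration
#'
#' Emits the full study design as a plain list (optionally written to a
#' YAML file): doses and routes, the t.i.d.-for-5-days oral regimen
#' (within-day offsets 0/360/720 min, 15 doses, dose 13 at 5760 min),
#' marker doses, sampling schedules, and the LOQ.
#'
#' @param path optional path; when given the configuration is written as
#'   YAML.
#' @return the configuration list, invisibly when written to file.
#' @examples
#' cfg <- make_study_config()
#' length(cfg$oral_dose_times_min)  # 15
#' cfg$oral_dose_times_min[13]      # 5760
#' @export
make_study_config <- function(path = NULL) {
  reg <- study_regimen("oral")
  cfg <- list(
    dose_racemic_mg_kg = 5,
    dose_per_enantiomer_mg_kg = 2.5,
    iv = list(route = "iv", time_min = 0),
    oral = list(route = "oral", n_days = 5, per_day = 3, interval_min = 360,
                day_length_min = 1440),
    oral_dose_times_min = reg$time,
    marker = list(iohexol_dose_mg_kg = 64.7, pah_dose_mg_kg = 10),
    loq_ug_per_ml = 0.25,
    age_groups = pig_reference_params()$age_group,
    n_per_group = 8,
    schedules = sampling_schedules()
  )
  if (!is.null(path)) {
    yaml::write_yaml(cfg, path)
    return(invisible(cfg))
  }
  cfg
}

#' Read a study design configuration
#'
#' @param path YAML file written by [make_study_config()].
#' @return the configuration list.
#' @export
read_study_config <- function(path) {
  yaml::read_yaml(path)
}
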