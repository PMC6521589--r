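# shared fixtures: published group-mean parameter sets and small builders

ref_group_params <- function(age = "1wk") {
  g <- pig_reference_params()
  r <- g[g$age_group == age, ]
  enantiomer_params(V_R = r$V_R, Cl_R = r$Cl_R, Cl_RtoS = r$Cl_RtoS,
                    V_S = r$V_S, Cl_S = r$Cl_S,
                    ka_R = r$ka_R, ka_S = r$ka_S, F_R = r$F_R, F_S = r$F_S)
}

age_groups <- function() pig_reference_params()$age_group

# long-format noiseless profile data for fitting (times > 0)
noiseless_profiles <- function(params, route = "iv", dose = 5, times = NULL) {
  sch <- sampling_schedules()
  if (is.null(times)) {
    times <- if (route == "iv") sch$iv else sch$oral_rich
  }
  times <- times[times > 0]
  sim <- if (route == "iv") {
    simulate_iv_bolus(params, dose_event(0, "iv", dose), times)
  } else {
    simulate_oral(params, dose_event(0, "oral", dose), times)
  }
  rbind(data.frame(analyte = "R", time_min = times, conc_ug_per_ml = sim$R$conc),
        data.frame(analyte = "S", time_min = times, conc_ug_per_ml = sim$S$conc))
}

# random parameter draws spanning the published range (used by the
# closed-form vs ODE property tests)
random_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    Cl_R <- runif(1, 1.5, 12)
    enantiomer_params(
      V_R = runif(1, 120, 350), Cl_R = Cl_R,
      Cl_RtoS = runif(1, 0.2, 0.95) * Cl_R,
      V_S = runif(1, 120, 300), Cl_S = runif(1, 1.5, 6),
      ka_R = runif(1, 0.01, 0.2), ka_S = runif(1, 0.01, 0.2),
      F_R = runif(1, 0.5, 1.3), F_S = runif(1, 0.5, 1.3))
  })
}

rel_err <- function(est, tru) abs(est - tru) / abs(tru)
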