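test_that("noiseless IV profiles return the generating parameters", {
  p <- ref_group_params("4wk")
  fit <- fit_iv_enantiomers(noiseless_profiles(p, "iv"))
  for (nm in c("V_R", "Cl_R", "Cl_RtoS", "V_S", "Cl_S")) {
    expect_lt(rel_err(fit$params[[nm]], p[[nm]]), 1e-6)
  }
  expect_true(fit$converged)
  expect_equal(fit$n_obs, 28)
})

test_that("absent inversion is estimated at its lower bound", {
  p <- enantiomer_params(300, 6, 0, 250, 2)
  fit <- fit_iv_enantiomers(noiseless_profiles(p, "iv"))
  expect_lt(fit$params$Cl_RtoS, 1e-6)
})

test_that("IV fit enforces its preconditions", {
  p <- ref_group_params("1wk")
  d <- noiseless_profiles(p, "iv")
  expect_error(fit_iv_enantiomers(d[d$time_min <= 30 | d$analyte == "S", ]),
               "at least 6")
})

test_that("sequential oral fit recovers ka and F and never touches the frozen inversion", {
  p <- ref_group_params("8wk")
  ivp <- fit_iv_enantiomers(noiseless_profiles(p, "iv"))$params
  d <- noiseless_profiles(p, "oral")
  fit <- fit_oral_enantiomers(d, cl_rts = ivp$Cl_RtoS, iv_params = ivp)
  for (nm in c("ka_R", "ka_S", "F_R", "F_S")) {
    expect_lt(rel_err(fit$params[[nm]], p[[nm]]), 1e-5)
  }
  expect_identical(fit$params$Cl_RtoS, ivp$Cl_RtoS) # bit-identical pass-through
  expect_error(fit_oral_enantiomers(d, cl_rts = NULL, iv_params = ivp),
               "required")
})

test_that("bioavailability above 100% is returned unclipped and scales linearly", {
  p <- ref_group_params("1wk") # published F_R is 126.2%
  ivp <- fit_iv_enantiomers(noiseless_profiles(p, "iv"))$params
  d <- noiseless_profiles(p, "oral")
  fit <- fit_oral_enantiomers(d, cl_rts = ivp$Cl_RtoS, iv_params = ivp)
  expect_gt(fit$params$F_R, 1)
  expect_lt(rel_err(fit$params$F_R, 1.262), 1e-5)
  # halving all concentrations halves F and leaves ka unchanged
  d2 <- d; d2$conc_ug_per_ml <- 0.5 * d2$conc_ug_per_ml
  fit2 <- fit_oral_enantiomers(d2, cl_rts = ivp$Cl_RtoS, iv_params = ivp)
  expect_equal(fit2$params$F_R, fit$params$F_R / 2, tolerance = 1e-6)
  expect_equal(fit2$params$ka_R, fit$params$ka_R, tolerance = 1e-6)
})

test_that("total-drug one-compartment fit recovers mono-exponential truth", {
  t <- sampling_schedules()$iv[-1]
  d <- data.frame(time_min = t, conc_ug_per_ml = 5000 / 200 * exp(-(4 / 200) * t))
  fit <- fit_total_one_compartment(d, route = "iv")
  expect_lt(rel_err(fit$V, 200), 1e-8)
  expect_lt(rel_err(fit$Cl, 4), 1e-8)
  expect_error(fit_total_one_compartment(
    data.frame(time_min = t, conc_ug_per_ml = 0 * t), route = "iv"), "zero")
  # sum of a symmetric decoupled R/S pair is one compartment with the same V, Cl
  p <- enantiomer_params(200, 4, 0, 200, 4)
  sim <- simulate_iv_bolus(p, dose_event(0, "iv", 5), t)
  dsum <- data.frame(time_min = t, conc_ug_per_ml = sim$R$conc + sim$S$conc)
  fsum <- fit_total_one_compartment(dsum, route = "iv")
  expect_lt(rel_err(fsum$V, 200), 1e-6)
  expect_lt(rel_err(fsum$Cl, 4), 1e-6)
  # oral stage needs the IV values
  expect_error(fit_total_one_compartment(d, route = "oral"), "iv_values")
})

test_that("secondary parameters follow their closed forms", {
  # published one-week R values: t1/2 = ln2*329.9/10.6 = 21.6 min, within
  # one SD of the reported 22.6 (5.5) min
  expect_lt(abs(half_life(329.9, 10.6) - 22.6), 5.5)
  expect_equal(half_life(7, 7), log(2))
  p <- ref_group_params("1wk")
  iv <- secondary_parameters(p, 5, "iv")
  expect_equal(iv$c0_or_cmax, c(2500 / p$V_R, 2500 / p$V_S))
  expect_equal(iv$auc_0_inf, c(2500 / p$Cl_R, 2500 / p$Cl_S))
  # symmetric oral case: bracketed Tmax equals ln(ka/ke)/(ka - ke)
  ps <- enantiomer_params(300, 6, 0, 300, 6, ka_R = 0.05, ka_S = 0.05,
                          F_R = 0.8, F_S = 0.8)
  po <- secondary_parameters(ps, 5, "oral")
  ke <- 6 / 300
  expect_equal(po$tmax, rep(log(0.05 / ke) / (0.05 - ke), 2), tolerance = 1e-8)
  expect_equal(po$auc_0_inf, rep(0.8 * 2500 / 6, 2))
})

test_that("group summaries match their definitions and a streaming oracle", {
  one <- data.frame(age_group = "1wk", x = 3.5)
  s1 <- summarize_group(one, "x")
  expect_equal(s1$mean, 3.5)
  expect_equal(s1$sd, 0)
  expect_equal(s1$n, 1)
  two <- data.frame(age_group = "g", x = c(10 - 2, 10 + 2))
  expect_equal(summarize_group(two, "x")$sd, 2 * sqrt(2))
  # streaming-moment oracle on random grouped data
  set.seed(5)
  d <- data.frame(age_group = sample(c("a", "b"), 60, TRUE),
                  sex = sample(c("M", "F"), 60, TRUE),
                  v = rnorm(60))
  s <- summarize_group(d, "v", by = c("age_group", "sex"))
  for (i in seq_len(nrow(s))) {
    g <- d[d$age_group == s$age_group[i] & d$sex == s$sex[i], "v"]
    n <- 0; m <- 0; m2 <- 0
    for (x in g) { # Welford recursion
      n <- n + 1; delta <- x - m; m <- m + delta / n
      m2 <- m2 + delta * (x - m)
    }
    expect_equal(s$mean[i], m)
    expect_equal(s$sd[i], sqrt(m2 / (n - 1)))
    expect_equal(s$n[i], n)
  }
  expect_error(summarize_group(d[0, ], "v"), "empty")
})

test_that("self-consistency holds across all four age-group parameter sets", {
  for (age in age_groups()) {
    p <- ref_group_params(age)
    fit <- fit_iv_enantiomers(noiseless_profiles(p, "iv"))
    for (nm in c("V_R", "Cl_R", "Cl_RtoS", "V_S", "Cl_S")) {
      expect_lt(rel_err(fit$params[[nm]], p[[nm]]), 1e-6)
    }
  }
})
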