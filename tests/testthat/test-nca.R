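test_that("linear-up/log-down AUC reproduces the hand-computed two-segment value", {
  # rising segment: linear trapezoid 15*60 = 900;
  # falling segment: (20-10)*60/log(2) = 865.617
  auc <- auc_lin_up_log_down(c(0, 60, 120), c(10, 20, 10))
  expect_equal(auc, 900 + 10 * 60 / log(2), tolerance = 1e-12)
  expect_equal(auc, 1765.62, tolerance = 0.01)
})

test_that("AUC rule degenerates correctly on flat and truncated segments", {
  # constant curve: log rule never triggers, area is c*T exactly
  expect_identical(auc_lin_up_log_down(c(0, 50, 130), c(4, 4, 4)), 4 * 130)
  # interpolated truncation inside a log-down segment uses the log rule
  t <- c(0, 60, 120); c <- c(10, 20, 10)
  a90 <- auc_lin_up_log_down(t, c, t_end = 90)
  c90 <- 20 * (10 / 20)^((90 - 60) / 60) # log interpolation at 90 min
  expect_equal(a90, 900 + (20 - c90) * 30 / log(20 / c90), tolerance = 1e-12)
  # t_end beyond the data: warn and integrate to the last sample
  expect_warning(afull <- auc_lin_up_log_down(t, c, t_end = 500), "beyond")
  expect_equal(afull, auc_lin_up_log_down(t, c))
  expect_error(auc_lin_up_log_down(t, c, t_end = -5), "precedes")
  expect_error(auc_lin_up_log_down(c(0, 0, 10), c(1, 1, 1)), "increasing")
})

test_that("AUC is additive over a shared sampling point and dose-proportional", {
  set.seed(42)
  for (i in 1:20) {
    t <- sort(runif(8, 0, 400)); t[1] <- 0
    c <- rlnorm(8, 0, 1)
    mid <- t[5]
    expect_equal(auc_lin_up_log_down(t, c, t_end = mid) +
                   auc_lin_up_log_down(t[5:8], c[5:8]),
                 auc_lin_up_log_down(t, c), tolerance = 1e-10)
    expect_equal(auc_lin_up_log_down(t, 3.7 * c), 3.7 * auc_lin_up_log_down(t, c),
                 tolerance = 1e-10)
  }
})

test_that("log-down trapezoid is bounded by the linear trapezoid and the exact integral", {
  ke <- 0.015
  t <- c(0, 15, 45, 90, 180, 300)
  c <- 12 * exp(-ke * t)
  lin <- sum(diff(t) * (head(c, -1) + tail(c, -1)) / 2)
  exact <- 12 / ke * (1 - exp(-ke * max(t)))
  a <- auc_lin_up_log_down(t, c)
  expect_lt(a, lin)
  expect_gte(a, exact - 1e-9)
  # equality with the linear rule iff the segment is flat
  expect_identical(auc_lin_up_log_down(c(0, 60), c(5, 5)), 5 * 60)
})

test_that("terminal slope is exact on mono-exponential data and flags sparse input", {
  t <- c(0, 10, 30, 60, 120, 240, 360, 480)
  c <- 20 * exp(-0.02 * t)
  lz <- terminal_lambda_z(t, c)
  expect_equal(lz$lambda_z, 0.02, tolerance = 1e-10)
  expect_equal(lz$t_half, log(2) / 0.02, tolerance = 1e-10)
  expect_equal(lz$auc_0_inf, 20 / 0.02, tolerance = 1e-3)
  # appended censored zeros never enter the regression
  lz2 <- terminal_lambda_z(c(t, 600, 720), c(c, 0, 0))
  expect_equal(lz2$lambda_z, lz$lambda_z)
  # two positive points are not enough: flagged missing, not an error
  expect_true(is.na(terminal_lambda_z(c(0, 60), c(5, 2))$lambda_z))
  # rising tail gives a non-positive slope: flagged missing
  expect_true(is.na(terminal_lambda_z(c(0, 30, 60, 90, 120),
                                      c(5, 1, 2, 3, 4))$lambda_z))
})

test_that("Cmax/Tmax report the earliest maximum", {
  expect_equal(cmax_tmax(c(0, 5, 30), c(9, 7, 2)),
               list(cmax = 9, tmax = 0))
  expect_equal(cmax_tmax(c(15, 30, 45, 60), c(1, 8, 8, 3))$tmax, 30)
  # on the study oral grid, observed Tmax is the grid point nearest the
  # analytic ln(ka/ke)/(ka - ke)
  ka <- 0.05; ke <- 0.02
  tg <- sampling_schedules()$oral_rich
  conc <- ka / (ka - ke) * (exp(-ke * tg) - exp(-ka * tg))
  t_true <- log(ka / ke) / (ka - ke)
  expect_equal(cmax_tmax(tg, conc)$tmax, tg[which.min(abs(tg - t_true))])
})

test_that("absolute bioavailability is the dose-normalised 0-3 h AUC ratio", {
  t <- c(0, 15, 30, 60, 120, 180, 240)
  civ <- 10 * exp(-0.01 * t)
  expect_equal(absolute_bioavailability(t, civ, t, civ)$F, 1)
  expect_equal(absolute_bioavailability(t, 0.5 * civ, t, civ)$F, 0.5,
               tolerance = 1e-12)
  expect_error(absolute_bioavailability(t[t <= 120], civ[t <= 120], t, civ),
               "180")
  expect_error(absolute_bioavailability(t, 0 * civ, t, 0 * civ), "zero")
  # simulated subject with true F = 0.8 on rich grids recovers F within 3%
  p <- enantiomer_params(300, 6, 1.5, 250, 2, ka_R = 0.06, ka_S = 0.05,
                         F_R = 0.8, F_S = 0.8)
  tg <- seq(0, 240, by = 5)
  po <- simulate_oral(p, dose_event(0, "oral", 5), tg)
  iv <- simulate_iv_bolus(p, dose_event(0, "iv", 5), tg)
  fb <- absolute_bioavailability(tg, po$R$conc, tg, iv$R$conc)
  expect_lt(abs(fb$F - 0.8) / 0.8, 0.03)
})

test_that("accumulation ratio is one for identical interval profiles", {
  t <- c(0, 30, 60, 120, 240, 360)
  c <- 8 * exp(-0.01 * t)
  expect_equal(accumulation_ratio(t, c, t, c)$ratio, 1)
  expect_error(accumulation_ratio(t, 0 * c, t, c), "zero")
})

test_that("LOQ filtering excludes strictly-below values and counts them", {
  toy <- data.frame(conc_ug_per_ml = c(0.1, 0.25, 0.3))
  out <- apply_loq_filter(toy)
  expect_equal(out$n_removed, 1) # 0.25 itself is retained
  expect_equal(out$records$conc_ug_per_ml, c(0.25, 0.3))
  # count matches an independent recount on a random censored set
  set.seed(7)
  rc <- data.frame(conc_ug_per_ml = rlnorm(500, -1, 1),
                   blq = rep(FALSE, 500))
  expect_equal(apply_loq_filter(rc, loq = 0.25)$n_removed,
               sum(rc$conc_ug_per_ml < 0.25))
  # a pre-set BLQ flag is honored even above the LOQ
  fl <- data.frame(conc_ug_per_ml = c(1, 2), blq = c(TRUE, FALSE))
  expect_equal(apply_loq_filter(fl)$n_removed, 1)
})

test_that("NCA clearance matches compartmental clearance on the study IV grid", {
  V <- 300; Cl <- 6
  tg <- sampling_schedules()$iv
  conc <- 5000 / V * exp(-(Cl / V) * tg)
  lz <- terminal_lambda_z(tg, conc)
  cl_nca <- 5000 / lz$auc_0_inf
  expect_lt(abs(cl_nca - Cl) / Cl, 0.005)
})
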