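test_that("elastance is periodic, bounded and hits its extremes", {
  p <- circulation_params()
  t <- seq(0, 2 * p$T_hb, by = 1e-3)
  E <- elastance(t, p)
  expect_true(all(E >= p$E_min - 1e-9 & E <= p$E_max + 1e-9))
  expect_equal(elastance(t, p), elastance(t + p$T_hb, p), tolerance = 1e-12)
  # fully relaxed diastole -> minimal elastance
  expect_equal(elastance(0, p), p$E_min, tolerance = 1e-6)
  expect_equal(elastance(0.99 * p$T_hb, p), p$E_min, tolerance = 1e-3)
  # activation peak -> maximal elastance
  expect_equal(max(E), p$E_max, tolerance = 1e-6)
})

test_that("activation integral agrees between coarse and fine quadrature", {
  p <- circulation_params()
  act <- function(t) (elastance(t, p) - p$E_min) / (p$E_max - p$E_min)
  trapz <- function(n) {
    t <- seq(0, p$T_hb, length.out = n + 1)
    sum((act(t[-1]) + act(t[-(n + 1)])) / 2) * p$T_hb / n
  }
  coarse <- trapz(2048)
  fine <- stats::integrate(act, 0, p$T_hb, rel.tol = 1e-10,
                           subdivisions = 2000L)$value
  expect_lt(abs(coarse - fine) / fine, 1e-6)
})

test_that("a pressure-equilibrated state does not move", {
  p0 <- mmHg_to_Pa(10)
  p <- circulation_params(p_pv = p0, p_ven = p0)
  st <- list(time = 0.99 * p$T_hb,        # relaxed diastole, E ~ E_min
             V_LA = p$V0_LA + p0 / p$E_LA,
             V_LV = p$V0_LV + p0 / elastance(0.99 * p$T_hb, p),
             p_ar = p0, V_res = 100)
  st2 <- step_circulation(st, 1e-3, p)
  expect_equal(st2$V_LA, st$V_LA, tolerance = 1e-10)
  expect_equal(st2$V_LV, st$V_LV, tolerance = 1e-7)
  expect_equal(st2$p_ar, st$p_ar, tolerance = 1e-10)
  expect_equal(st2$time, st$time + 1e-3)
  expect_false(st2$ao_open)
})

test_that("chamber pressure is elastance times distended volume", {
  p <- circulation_params()
  st <- initial_circulation_state(p)
  st$V_LV <- 120
  out <- step_circulation(st, 1e-3, p)
  expect_equal(out$p_LV, elastance(st$time, p) * (120 - p$V0_LV))
})

test_that("the closed loop conserves blood volume without a coronary sink", {
  p <- circulation_params()
  nsteps <- as.integer(round(p$beats * p$T_hb / p$dt))
  st <- initial_circulation_state(p)
  total0 <- st$V_LA + st$V_LV + p$C_art * st$p_ar + st$V_res
  drift <- 0
  for (i in seq_len(nsteps)) {
    st <- step_circulation(st, p$dt, p)
    total <- st$V_LA + st$V_LV + p$C_art * st$p_ar + st$V_res
    drift <- max(drift, abs(total - total0))
  }
  expect_lt(drift / total0, 1e-12)
})

test_that("calibrated defaults reproduce resting left-heart biomarkers", {
  b <- extract_biomarkers(run_circulation(circulation_params()))
  expect_equal(b$SV_mL, 83.0, tolerance = 0.10)
  expect_equal(b$EF_pct, 54.2, tolerance = 0.10)
  expect_equal(b$p_LV_max_mmHg, 125.4, tolerance = 0.10)
  expect_equal(b$Q_ao_max_mL_s, 562.0, tolerance = 0.10)
  expect_equal(b$Q_pv_max_mL_s, 267.2, tolerance = 0.15)
  expect_equal(b$p_ar_sys_mmHg, 103.3, tolerance = 0.10)
  expect_equal(b$p_ar_dia_mmHg, 80.3, tolerance = 0.10)
  # residual diode leakage only (closed-valve resistance 1e9 Pa s/mL)
  expect_lt(b$regurgitant_volume_mL, 1e-3)
})

test_that("stroke volume settles between the first and second beat", {
  tr <- run_circulation(circulation_params())
  b1 <- extract_biomarkers(tr, beat = 1)
  b2 <- extract_biomarkers(tr, beat = 2)
  expect_gt(b2$SV_mL, 0)
  expect_lt(abs(b2$SV_mL - b1$SV_mL) / b2$SV_mL, 0.2)
})

test_that("aortic regurgitation scenario modifies only the leak and scaling", {
  p <- circulation_params()
  expect_identical(apply_ar_scenario(p, 0), p)
  ar <- apply_ar_scenario(p, 0.045)
  expect_equal(ar$leak_area, 0.045 * p$annulus_area)
  expect_equal(ar$sys_scale, 1.2)
  expect_equal(ar$dia_scale, 0.8)
})

test_that("diastolic aortic flow is retrograde with a leak, zero without", {
  p <- circulation_params()
  tr_ph <- run_circulation(p)
  closed <- tr_ph$ao_open == 0
  expect_true(all(abs(tr_ph$Q_av_mL_s[closed]) < 1e-3))

  ar <- apply_ar_scenario(p, 0.045)
  tr_ar <- run_circulation(ar)
  expect_lt(min(tr_ar$Q_av_mL_s[tr_ar$ao_open == 0]), 0)
  b_ar <- extract_biomarkers(tr_ar)
  expect_gt(b_ar$regurgitant_volume_mL, 0)

  # doubling the leak conductance strictly increases the regurgitant volume
  ar2 <- ar; ar2$leak_coef <- 2 * ar$leak_coef
  b_ar2 <- extract_biomarkers(run_circulation(ar2))
  expect_gt(b_ar2$regurgitant_volume_mL, b_ar$regurgitant_volume_mL)
})

test_that("biomarkers of synthetic transients match analytic extrema", {
  p <- circulation_params()
  t <- seq(p$dt, 2 * p$T_hb, by = p$dt)
  flat <- data.frame(time_s = t, V_LV_mL = 100, p_LV_Pa = 0,
                     Q_av_mL_s = 0, Q_pv_mL_s = 0, p_ar_eff_Pa = 0)
  b <- extract_biomarkers(flat, p)
  expect_equal(b$SV_mL, 0)
  expect_equal(b$EF_pct, 0)
  sine <- flat
  sine$V_LV_mL <- 110 + 40 * sin(2 * pi * t / p$T_hb)
  b2 <- extract_biomarkers(sine, p)
  expect_equal(b2$SV_mL, 80, tolerance = 1e-4)
})
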