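test_that("zero driving pressures give the zero-flux fixed point immediately", {
  m <- fx_tiny_mesh()
  r <- fx_tiny_regions()
  net <- coronary_network(r, side = c("LCA", "RCA", "LCA", "LCA"))
  sys <- assemble_darcy(m, darcy_params(), regions = r)
  out <- couple_step(sys, r, net, p_root = 0, p_bed = 0,
                     Q_init = rep(0, 4), full_state = FALSE)
  expect_equal(out$Q, rep(0, 4))
  expect_equal(out$iterations, 1L)
})

test_that("iterative splitting matches the monolithic interface solve", {
  m <- fx_tiny_mesh()
  r <- fx_tiny_regions()
  net <- coronary_network(r, side = c("LCA", "RCA", "LCA", "LCA"))
  sys <- assemble_darcy(m, darcy_params(), regions = r, seed = 3)
  resp <- perfusim:::.interface_response(sys, r)
  cfg <- coupling_config(tol = 1e-13, max_subiter = 2000L)
  Rb <- perfusim:::.branch_resistances(net, FALSE)
  p_root <- mmHg_to_Pa(95); p_bed <- 2100
  mono <- perfusim:::.monolithic_fluxes(p_root, p_bed, Rb, resp)
  split <- perfusim:::.couple_fluxes(rep(0.1, 4), p_root, p_bed, Rb, resp, cfg)
  expect_lt(max(abs(split$Q - mono)) / max(abs(mono)), 1e-8)

  # the converged fluxes reproduce the network law at the solved pressures
  st <- solve_darcy(resp$sys, compute_g1(split$Q, r), p_bed)
  p1c <- (st$p1[m$tetrahedra[, 1]] + st$p1[m$tetrahedra[, 2]] +
          st$p1[m$tetrahedra[, 3]] + st$p1[m$tetrahedra[, 4]]) / 4
  means <- vapply(1:4, function(j) {
    s <- r$labels == j
    sum(p1c[s] * m$cell_volumes[s]) / sum(m$cell_volumes[s])
  }, numeric(1))
  Qlaw <- total_flows(net, p_root, means, FALSE)$Q
  expect_equal(split$Q, Qlaw, tolerance = 1e-7)
})

test_that("tightening the tolerance moves the fluxes by less than it", {
  m <- fx_tiny_mesh()
  r <- fx_tiny_regions()
  net <- coronary_network(r, side = c("LCA", "RCA", "LCA", "LCA"))
  sys <- assemble_darcy(m, darcy_params(), regions = r)
  resp <- perfusim:::.interface_response(sys, r)
  Rb <- perfusim:::.branch_resistances(net, FALSE)
  q0 <- rep(0.2, 4)
  a <- perfusim:::.couple_fluxes(q0, 1e4, 2000, Rb, resp,
                                 coupling_config(tol = 1e-6,
                                                 max_subiter = 2000L))
  b <- perfusim:::.couple_fluxes(q0, 1e4, 2000, Rb, resp,
                                 coupling_config(tol = 5e-7,
                                                 max_subiter = 2000L))
  expect_lt(max(abs(a$Q - b$Q)) / max(abs(b$Q)), 1e-6)
})

test_that("the physiological run is diastolic-dominant and LCA-dominant", {
  ph <- fx_tiny_ph()
  tr <- ph$transients
  ipk <- ph$peak$index
  # peak total coronary inflow falls in the filling phase, not ejection
  expect_true(tr$mv_open[ipk] == 1)
  expect_true(tr$ao_open[ipk] == 0)
  expect_gt(ph$peak$Q_total_mL_s, ph$peak$Q_systolic_peak_mL_s)
  expect_gt(ph$peak$Q_LCA_mL_s, ph$peak$Q_RCA_mL_s)
})

test_that("every accepted step is converged and mass-closed", {
  ph <- fx_tiny_ph()
  expect_true(all(ph$convergence$residual <= ph$config$coupling$tol))
  expect_true(all(ph$convergence$iterations <=
                  ph$config$coupling$max_subiter))
  expect_lt(max(ph$convergence$mass_rel_err), 1e-8)
  # transient sampling equals dt
  expect_equal(unique(round(diff(ph$transients$time_s), 12)),
               ph$config$coupling$dt)
})

test_that("compartment pressures decrease along the exchange chain", {
  ph <- fx_tiny_ph()
  st <- ph$state_peak
  w <- node_volume_weights(ph$mesh)
  mean_p <- function(p) sum(w * p) / sum(w)
  expect_gte(mean_p(st$p1), mean_p(st$p2))
  expect_gte(mean_p(st$p2), mean_p(st$p3))
})

test_that("aortic regurgitation steals diastolic coronary flow", {
  ph <- fx_tiny_ph()
  ar <- fx_tiny_ar()
  cmp <- compare_scenarios(ph, ar)
  expect_gt(cmp$flow_reduction_pct, 0)
  expect_lt(ar$mbf$mean, ph$mbf$mean)
  # slight systolic increase driven by the raised systolic aortic pressure
  expect_gte(ar$peak$Q_systolic_peak_mL_s, ph$peak$Q_systolic_peak_mL_s)
  # retrograde diastolic aortic flow only in AR
  expect_lt(min(ar$transients$Q_av_mL_s), 0)
  expect_gte(min(ph$transients$Q_av_mL_s), -1e-3)
})

test_that("comparison arithmetic is exact on constructed peaks", {
  ph <- fx_tiny_ph()
  self <- compare_scenarios(ph, ph)
  expect_equal(self$flow_reduction_pct, 0)
  expect_equal(self$mbf_delta, 0)
  expect_true(all(self$mbf_region_delta == 0))
  fake <- fx_tiny_ar()
  fake$peak$Q_total_mL_s <- 3
  ph2 <- ph; ph2$peak$Q_total_mL_s <- 4
  expect_equal(compare_scenarios(ph2, fake)$flow_reduction_pct, 25)
})

test_that("runs are deterministic given the config and seed", {
  ph1 <- fx_tiny_ph()
  ph2 <- run_scenario(default_config(level = "tiny"), "ph")
  expect_identical(ph1$transients, ph2$transients)
  expect_identical(ph1$Q_branches, ph2$Q_branches)
  expect_identical(ph1$mbf$mbf, ph2$mbf$mbf)
})
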