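test_that("coronary-bed pressure reproduces the printed bounds", {
  # peak LV pressure 125.4 mmHg -> upper bound 61.4 mmHg
  p_bed <- coronary_bed_pressure(mmHg_to_Pa(125.4), a1 = 0.4, a2 = 1500)
  expect_equal(round(Pa_to_mmHg(p_bed), 1), 61.4)
  expect_equal(coronary_bed_pressure(0), 1500)
  # inverting the linear law at the printed lower bound and re-evaluating
  p_lv_low <- (mmHg_to_Pa(14.2) - 1500) / 0.4
  expect_equal(Pa_to_mmHg(p_lv_low), 7.4, tolerance = 0.01)
  expect_equal(Pa_to_mmHg(coronary_bed_pressure(p_lv_low)), 14.2,
               tolerance = 1e-10)
})

test_that("regional inflow source integrates exactly to the total flux", {
  r <- fx_tiny_regions()
  m <- fx_tiny_mesh()
  Q <- c(2, 5, 1, 3)
  g1 <- compute_g1(Q, r)
  # piecewise constant per territory: Q_j / |Omega_j|
  for (j in 1:4) {
    expect_equal(unique(g1[r$labels == j]),
                 1000 * Q[j] / r$region_volumes[j])
  }
  expect_equal(sum(g1 * m$cell_volumes) / 1000, sum(Q), tolerance = 1e-14)
  # single region, Q numerically equal to |Omega| in mL -> g1 = 1/s
  r1 <- partition_regions(m, matrix(0, 1, 3))
  g <- compute_g1(sum(m$cell_volumes) / 1000, r1)
  expect_equal(unique(g), 1)
})

test_that("two-region arithmetic example", {
  # volumes 2 and 4 mL with Q = (6, 8) mL/s -> g1 = 3 and 2 1/s
  regions <- structure(list(labels = c(1L, 2L),
                            seeds = matrix(0, 2, 3),
                            region_volumes = c(2000, 4000)),
                       class = "perfusion_regions")
  expect_equal(compute_g1(c(6, 8), regions), c(3, 2))
})

test_that("assembled system is symmetric positive definite", {
  b <- mesh_box(c(10, 10, 10), 3)
  sys <- assemble_darcy(b, darcy_params(beta23_sigma = 0))
  A <- as.matrix(sys$A)
  expect_lt(max(abs(A - t(A))), 1e-12 * max(abs(A)))
  expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), 0)
  dp0 <- darcy_params(beta23_sigma = 0)
  dp0$gamma <- 0                      # pure Neumann: refuse, system singular
  expect_error(assemble_darcy(b, dp0), "singular")
})

test_that("uniform forcing reproduces the closed-form pressure chain", {
  b <- mesh_box(c(10, 10, 10), 4)
  dp <- darcy_params(beta23_sigma = 0)
  sys <- assemble_darcy(b, dp)
  # zero sources: equilibrium at the bed pressure
  st0 <- solve_darcy(sys, 0, 5000)
  expect_lt(max(abs(c(st0$p1, st0$p2, st0$p3) - 5000)), 1e-6)
  # uniform g1 = c: gradients vanish, algebraic balance gives the chain
  cc <- 0.01
  st <- solve_darcy(sys, cc, 2000)
  p3e <- 2000 + cc / dp$gamma
  p2e <- p3e + cc / dp$beta23
  p1e <- p2e + cc / dp$beta12
  expect_lt(max(abs(st$p1 - p1e)) / p1e, 1e-8)
  expect_lt(max(abs(st$p2 - p2e)) / p2e, 1e-8)
  expect_lt(max(abs(st$p3 - p3e)) / p3e, 1e-8)
  expect_lt(st$residual, 1e-10)
  # velocities vanish for the spatially constant solution
  expect_lt(max(abs(st$u1)), 1e-10)
})

test_that("manufactured solution converges at second order", {
  dp <- darcy_params(beta23_sigma = 0)
  L <- 10
  A <- c(3000, 2000, 1000); C <- c(3000, 2500, 2000); pbed <- 2000
  lap <- 3 * pi^2 / L^2
  errs <- vapply(c(4L, 8L, 16L), function(n) {
    b <- mesh_box(c(L, L, L), n)
    cen <- cell_centroids(b)
    cosm <- cos(pi * cen[, 1] / L) * cos(pi * cen[, 2] / L) *
            cos(pi * cen[, 3] / L)
    p <- sapply(1:3, function(i) A[i] * cosm + C[i])
    f1 <- dp$K[1] * lap * A[1] * cosm + dp$beta12 * (p[, 1] - p[, 2])
    f2 <- dp$K[2] * lap * A[2] * cosm + dp$beta12 * (p[, 2] - p[, 1]) +
          dp$beta23 * (p[, 2] - p[, 3])
    f3 <- dp$K[3] * lap * A[3] * cosm + dp$beta23 * (p[, 3] - p[, 2]) +
          dp$gamma * (p[, 3] - pbed)
    sys <- assemble_darcy(b, dp, extra_g = list(f1, f2, f3))
    st <- solve_darcy(sys, 0, pbed)
    pex <- A[1] * cos(pi * b$vertices[, 1] / L) *
           cos(pi * b$vertices[, 2] / L) * cos(pi * b$vertices[, 3] / L) + C[1]
    w <- node_volume_weights(b)
    sqrt(sum(w * (st$p1 - pex)^2) / sum(w))
  }, numeric(1))
  rates <- log2(errs[-3] / errs[-1])
  expect_gt(min(rates), 1.7)
})

test_that("solution is invariant under vertex renumbering", {
  m <- mesh_box(c(8, 6, 10), c(3, 3, 3))
  dp <- darcy_params(beta23_sigma = 0)
  g1 <- sin(seq_len(nrow(m$tetrahedra)))^2 * 0.01
  st <- solve_darcy(assemble_darcy(m, dp), g1, 3000)
  perm <- withr::with_seed(42, sample.int(nrow(m$vertices)))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  m2 <- m
  m2$vertices <- m$vertices[perm, ]
  m2$tetrahedra <- matrix(inv[m$tetrahedra], ncol = 4)
  m2$boundary_faces <- matrix(inv[m$boundary_faces], ncol = 3)
  st2 <- solve_darcy(assemble_darcy(m2, dp), g1, 3000)
  expect_lt(max(abs(st2$p1[inv] - st$p1)), 1e-10 * max(abs(st$p1)))
  expect_lt(max(abs(st2$p3[inv] - st$p3)), 1e-10 * max(abs(st$p3)))
})

test_that("solution is linear in the sources (superposition)", {
  m <- fx_tiny_mesh()
  r <- fx_tiny_regions()
  dp <- darcy_params(beta23_sigma = 0)
  sys <- assemble_darcy(m, dp)
  ga <- compute_g1(c(1, 2, 0.5, 1.5), r)
  gb <- compute_g1(c(0.3, 0.1, 2, 0.7), r)
  sa <- solve_darcy(sys, ga, 1000)
  sb <- solve_darcy(sys, gb, 2500)
  sab <- solve_darcy(sys, ga + gb, 3500)
  expect_equal(sab$p1, sa$p1 + sb$p1, tolerance = 1e-9)
  expect_equal(sab$p3, sa$p3 + sb$p3, tolerance = 1e-9)
})

test_that("global mass balance and compartment ordering hold", {
  m <- fx_tiny_mesh()
  r <- fx_tiny_regions()
  sys <- assemble_darcy(m, darcy_params(), regions = r, seed = 7)
  Q <- c(0.6, 0.5, 0.4, 0.7)
  pbed <- 2000
  st <- solve_darcy(sys, compute_g1(Q, r), pbed)
  p3c <- (st$p3[m$tetrahedra[, 1]] + st$p3[m$tetrahedra[, 2]] +
          st$p3[m$tetrahedra[, 3]] + st$p3[m$tetrahedra[, 4]]) / 4
  sink <- 1e-4 * sum((p3c - pbed) * m$cell_volumes) / 1000
  expect_lt(abs(sink - sum(Q)) / sum(Q), 1e-8)
  w <- node_volume_weights(m)
  mean_p <- function(p) sum(w * p) / sum(w)
  expect_gte(mean_p(st$p1), mean_p(st$p2))
  expect_gte(mean_p(st$p2), mean_p(st$p3))
})

test_that("MBF map follows the exchange law and its units", {
  m <- fx_tiny_mesh()
  st <- list(p1 = rep(0, nrow(m$vertices)),
             p2 = rep(3458.3, nrow(m$vertices)),
             p3 = rep(2000, nrow(m$vertices)),
             b23_cell = rep(1e-5, nrow(m$tetrahedra)))
  mb <- compute_mbf(st, m)
  # beta23 = 1e-5 g/(s Pa mL), p2 - p3 = 1458.3 Pa -> 87.5 mL/min/100mL
  expect_equal(mb$mean, 87.498, tolerance = 1e-5)
  st$p3 <- st$p2
  expect_equal(compute_mbf(st, m)$mean, 0)
  st$p3 <- rep(2000, nrow(m$vertices))
  st$b23_cell <- rep(0, nrow(m$tetrahedra))
  expect_equal(compute_mbf(st, m)$mean, 0)
})
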