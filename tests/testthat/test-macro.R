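test_that("uniform density with flat coefficients is stationary for the local part", {
  cfg <- macro_config(D0 = 2, delta = 0, chi0 = 0.5, theta = 1, T = 1)
  du <- rhs_parabolic(rep(5, 601), numeric(601), cfg)
  expect_equal(du, numeric(601))
  # a = d = 1: diffusion prefactor c1 = 1/9, overall division by a + 1 = 2
  expect_equal(cfg$c1, 1 / 9)
})

test_that("discrete right-hand side matches the analytic operator on a smooth field", {
  a <- 1
  for (h in c(0.02, 0.01)) {
    cfg <- macro_config(D0 = 1, delta = 0, chi0 = 0, theta = 1, h = h, T = 1)
    x <- seq(0, 6, by = h)
    u <- 2 + cos(pi * x / 6)
    exact <- -cfg$c1 / (a + 1) * (pi / 6)^2 * cos(pi * x / 6)
    err <- max(abs(rhs_parabolic(u, numeric(length(x)), cfg) - exact))
    # no-flux is exact here (u' = 0 at both ends); expect O(h^2)
    if (h == 0.02) err_coarse <- err else
      expect_lt(err, err_coarse / 3)
  }
  # negative diffusion moments are rejected at configuration time
  expect_error(macro_config(D0 = 1, delta = -1, chi0 = 0, T = 1),
               "negative")
})

test_that("outer step conserves mass and only boundaries feel the stencil bias", {
  cfg <- macro_config(D0 = 0.15, delta = 0, chi0 = 0.5, theta = 1, T = 1)
  u0 <- cfg$u0
  u1 <- step_outer(u0, cfg)
  # the conserved functional of the scheme is the trapezoid mass (half
  # cells at the boundary)
  trap <- function(u) u$h * (sum(u$values) - (u$values[1] +
                                              u$values[601]) / 2)
  expect_equal(trap(u1), trap(u0), tolerance = 1e-10)
  expect_equal(total_mass(u1), total_mass(u0), tolerance = 1e-4)
  # constant density: the frozen adhesion velocity is constant in the
  # interior, so transport acts only within reach of the boundaries
  # (plus a few nodes of diffusive spill-over per window)
  interior <- abs(u0$x - 3) <= 2 - 0.1
  expect_lt(max(abs(u1$values[interior] - 5)), 1e-9)
  expect_gt(max(abs(u1$values[!interior] - 5)), 1e-4)
})

test_that("free diffusion of a narrow bump follows the heat kernel", {
  s0 <- 0.15
  cfg <- macro_config(D0 = 1, delta = 0, chi0 = 0, theta = 1, T = 0.5,
                      u0 = make_ic("gaussian_bumps", centers = 3,
                                   widths = s0, masses = 2))
  kymo <- solve_ibvp(cfg)
  Deff <- cfg$c1 * 1 / (cfg$a + 1)    # effective diffusivity 1/18
  s2 <- s0^2 + 2 * Deff * 0.5
  exact <- 2 * stats::dnorm(kymo$x, 3, sqrt(s2))
  uT <- kymo$density[nrow(kymo$density), ]
  expect_lt(max(abs(uT - exact)) / max(exact), 0.01)
})

test_that("splitting solver agrees with a dense Crank-Nicolson oracle when chi0 = 0", {
  u0 <- make_ic("gaussian_bumps", centers = c(2.5, 4), widths = c(0.3, 0.5),
                masses = c(3, 2), h = 0.02)
  cfg <- macro_config(D0 = 3, delta = 0, chi0 = 0, theta = 1, T = 0.5,
                      h = 0.02, u0 = u0)
  kymo <- solve_ibvp(cfg)
  oracle <- crank_nicolson_diffusion(u0$values, h = 0.02, D0 = 3, a = 1,
                                     T = 0.5, dt = 1e-3)
  uT <- kymo$density[nrow(kymo$density), ]
  expect_lt(max(abs(uT - oracle)) / max(abs(oracle)), 1e-6)
})

test_that("symmetric data under x-independent coefficients stay symmetric", {
  # exact mirror symmetry holds for the local operator (chi0 = 0); the
  # right-endpoint Riemann stencil of the non-local term carries an O(h)
  # directional bias, so adhesion runs are only symmetric in their peak
  # positions (checked on the reference run elsewhere)
  u0 <- make_ic("gaussian_bumps", centers = 3, widths = 0.4, masses = 6)
  cfg <- macro_config(D0 = 0.5, delta = 0, chi0 = 0, theta = 1, T = 1,
                      u0 = u0, snapshot_stride = 25L)
  kymo <- solve_ibvp(cfg)
  for (i in seq_len(nrow(kymo$density))) {
    row <- kymo$density[i, ]
    expect_lt(max(abs(row - rev(row))), 1e-8)
  }
})

test_that("reference-run aggregates sit mirror-symmetrically", {
  agg <- detect_aggregates(final_field(reference_run("chi05")), 5)
  expect_equal(agg$peak_positions, 6 - rev(agg$peak_positions),
               tolerance = 0.011)
})

test_that("snapshots remain non-negative and conserve mass over long runs", {
  kymo <- reference_run("chi05")
  expect_gt(min(kymo$density), -1e-6 * max(kymo$density))
  expect_lt(max(abs(kymo$mass - kymo$mass[1])) / kymo$mass[1], 1e-3)
})

test_that("CAM coupling reduces to known limits of the plain solver", {
  base <- macro_config(D0 = 0.5, delta = 0, chi0 = 0.5, theta = 1, T = 0.2,
                       h = 0.02)
  plain <- solve_ibvp(base)
  Sfun <- function(t, x) rep(1, length(x))
  # K- = 0: every CAM bound, identical dynamics
  kin_all <- binding_kinetics(function(S, rho) rep(2, length(rho)),
                              function(S, rho) rep(0, length(rho)), r = 1)
  cam_all <- solve_ibvp_cam(macro_config(D0 = 0.5, delta = 0, chi0 = 0.5,
                                         theta = 1, T = 0.2, h = 0.02,
                                         mode = "parabolic_cam",
                                         kinetics = kin_all, S = Sfun))
  expect_lt(max(abs(cam_all$u$density - plain$density)), 1e-8)
  expect_equal(cam_all$mu1$density[1, ], cam_all$u$density[1, ],
               tolerance = 1e-8)
  # K+ = 0: no bonds, pure diffusion
  kin_none <- binding_kinetics(function(S, rho) rep(0, length(rho)),
                               function(S, rho) rep(2, length(rho)), r = 1)
  diff_only <- solve_ibvp(macro_config(D0 = 0.5, delta = 0, chi0 = 0,
                                       theta = 1, T = 0.2, h = 0.02))
  cam_none <- solve_ibvp_cam(macro_config(D0 = 0.5, delta = 0, chi0 = 0.5,
                                          theta = 1, T = 0.2, h = 0.02,
                                          mode = "parabolic_cam",
                                          kinetics = kin_none, S = Sfun))
  expect_lt(max(abs(cam_none$u$density - diff_only$density)), 1e-8)
  expect_lt(max(abs(cam_none$mu1$density)), 1e-9)
  # identical binding and unbinding kernels: exactly half bound (by
  # linearity of the binding operator), so the evolution matches the
  # plain solver with halved sensitivity
  keq <- function(S, rho) 2 * pmax(1 - rho, 0)
  kin_eq <- binding_kinetics(keq, keq, r = 1)
  halved <- solve_ibvp(macro_config(D0 = 0.5, delta = 0, chi0 = 0.25,
                                    theta = 1, T = 0.2, h = 0.02))
  cam_eq <- solve_ibvp_cam(macro_config(D0 = 0.5, delta = 0, chi0 = 0.5,
                                        theta = 1, T = 0.2, h = 0.02,
                                        mode = "parabolic_cam",
                                        kinetics = kin_eq, S = Sfun))
  expect_lt(max(abs(cam_eq$u$density - halved$density)), 1e-7)
})

test_that("conservative transport translates a bump at the characteristic speed", {
  e0 <- 0.5
  u0 <- make_ic("gaussian_bumps", centers = 2, widths = 0.25, masses = 2,
                h = 0.02)
  cfg <- macro_config(D0 = 0, delta = 0, chi0 = 0, theta = 0, T = 4,
                      h = 0.02, dt_outer = 0.005, mode = "cte",
                      E_field = e0, u0 = u0, snapshot_stride = 100L)
  kymo <- solve_hyperbolic(cfg)
  uT <- kymo$density[nrow(kymo$density), ]
  center <- sum(kymo$x * uT) / sum(uT)
  # speed (d/(d+1)) e0 / (a+1) = e0/4; first-order upwinding diffuses the
  # bump but transports its mass at the right speed
  expect_lt(abs(center - (2 + e0 / 4 * 4)), 0.04)
  expect_equal(kymo$mass[length(kymo$mass)], kymo$mass[1], tolerance = 1e-9)
  # zero mean direction: nothing moves
  cfg0 <- macro_config(D0 = 0, delta = 0, chi0 = 0, theta = 0, T = 1,
                       h = 0.02, dt_outer = 0.005, mode = "cte",
                       E_field = 0, u0 = u0)
  k0 <- solve_hyperbolic(cfg0)
  expect_equal(k0$density[nrow(k0$density), ], u0$values)
  cfg_cfl <- macro_config(D0 = 0, delta = 0, chi0 = 0, theta = 0, T = 1,
                          h = 0.001, dt_outer = 0.05, mode = "cte",
                          E_field = 5, u0 = make_ic("uniform", h = 0.001))
  expect_error(solve_hyperbolic(cfg_cfl), "CFL violation")
})

test_that("hyperbolic corrections with no mean direction reduce to the parabolic operator", {
  u0 <- make_ic("gaussian_bumps", centers = 3, widths = 0.4, masses = 4,
                h = 0.05)
  cfg <- macro_config(D0 = 0.2, delta = 0, chi0 = 0.5, theta = 1, T = 0.01,
                      h = 0.05, dt_outer = 0.01, mode = "hyperbolic",
                      E_field = 0, epsilon = 1, u0 = u0)
  kymo <- solve_hyperbolic(cfg)
  # one explicit Euler step of the frozen-adhesion parabolic right-hand side
  frozen <- 0.5 * adhesion_grid_1d(u0, cfg$law)
  manual <- u0$values + 0.01 * rhs_parabolic(u0$values, frozen, cfg)
  expect_lt(max(abs(kymo$density[nrow(kymo$density), ] - manual)), 1e-10)
})

test_that("halving the mesh moves the aggregates by at most a node", {
  # the sharp final aggregates of the D0 = 3 run keep count, position and
  # local mass under simultaneous h and dt refinement
  coarse <- reference_run("D3")
  cfg_f <- macro_config(D0 = 3, delta = 0, chi0 = 0.5, theta = 1,
                        h = 0.005, dt_outer = 0.005, snapshot_stride = 500L)
  fine <- solve_ibvp(cfg_f)
  ac <- detect_aggregates(final_field(coarse), 5)
  af <- detect_aggregates(final_field(fine), 5)
  expect_equal(af$count, ac$count)
  expect_lt(max(abs(af$peak_positions - ac$peak_positions)), 0.011)
  uc <- final_field(coarse); uf <- final_field(fine)
  for (p in ac$peak_positions) {
    mass_c <- sum(uc$values[abs(uc$x - p) < 0.3]) * uc$h
    mass_f <- sum(uf$values[abs(uf$x - p) < 0.3]) * uf$h
    expect_lt(abs(mass_f - mass_c) / mass_c, 0.02)
  }
})
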