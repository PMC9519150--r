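# Frequency- and time-domain solver validation on small meshes. The deeper
# (slower) oracle suite lives in test-acceptance.R; these tests exercise the
# same physics at reduced sizes.

test_that("conical-product quadrature integrates barycentric monomials exactly", {
  # closed form: int lam1^a lam2^b lam3^c lam4^d dV = a!b!c!d!/(a+b+c+d+3)! * 6V
  q <- resonear:::tet_quadrature(3)
  lam <- cbind(1 - rowSums(q$points), q$points)
  cases <- list(c(2, 1, 0, 0), c(1, 1, 1, 0), c(2, 2, 0, 0), c(4, 0, 0, 0))
  for (e in cases) {
    got <- sum(q$weights * lam[, 1]^e[1] * lam[, 2]^e[2] * lam[, 3]^e[3] * lam[, 4]^e[4])
    want <- prod(factorial(e)) / factorial(sum(e) + 3)
    expect_equal(got, want, tolerance = 1e-13)
  }
  qt <- resonear:::tri_quadrature(3)
  lam2 <- cbind(1 - rowSums(qt$points), qt$points)
  for (e in list(c(2, 1, 0), c(1, 1, 1), c(3, 0, 1))) {
    got <- sum(qt$weights * lam2[, 1]^e[1] * lam2[, 2]^e[2] * lam2[, 3]^e[3])
    want <- prod(factorial(e)) / factorial(sum(e) + 2)
    expect_equal(got, want, tolerance = 1e-13)
  }
})

test_that("mass and stiffness matrices have the right integrals and kernels", {
  m <- build_ball_mesh(radius = 1e-3, target_h = 4e-4)
  for (ord in c(1, 2)) {
    dofs <- resonear:::fem_dofs(m, ord)
    asm <- resonear:::assemble_volume(m, dofs)
    one <- rep(1, dofs$n)
    # sum(M) = domain volume; K annihilates constants
    expect_equal(sum(asm$M %*% one * one),
                 sum(resonear:::tet_volumes(m$nodes, m$tets)), tolerance = 1e-10)
    expect_lt(max(abs(asm$K %*% one)), 1e-10)
    # K reproduces the Dirichlet energy of a linear field exactly
    u <- dofs$coords[, 1] + 2 * dofs$coords[, 3]
    energy <- sum(u * as.numeric(asm$K %*% u))
    expect_equal(energy, 5 * sum(resonear:::tet_volumes(m$nodes, m$tets)),
                 tolerance = 1e-9)
  }
})

test_that("radiation boundary is transparent to the incident plane wave", {
  # small ball, quadratic elements, mesh at the six-per-wavelength rule
  m <- build_ball_mesh(radius = 1.2e-3, target_h = hmax_rule(343, 150e3) / 1.75)
  expect_lte(m$h_max, hmax_rule(343, 150e3))
  sw <- solve_frequency_domain(m, frequencies = c(20e3, 150e3), order = 2)
  pts <- rbind(c(0, 0, 0), c(4e-4, 2e-4, -3e-4))
  for (s in sw) {
    k <- 2 * pi * s$frequency / 343
    for (i in seq_len(nrow(pts))) {
      p_exact <- exp(-1i * k * sum(pts[i, ] * s$wave$direction))
      p_fem <- probe_pressure(s, pts[i, ])
      expect_lt(Mod(p_fem - p_exact) / Mod(p_exact), 0.02)
    }
  }
})

test_that("rigid-sphere scattering matches the partial-wave series at ka = 1", {
  a <- 6e-4; c0 <- 343
  k <- 1 / a; f <- k * c0 / (2 * pi)
  m <- build_annulus_mesh(a, radius = 1.6e-3, target_h = 3.4e-4)
  sw <- solve_frequency_domain(m, wave = plane_wave(direction = c(0, 0, 1)),
                               frequencies = f, order = 2,
                               check_resolution = "none")
  s <- sw[[1]]
  pts <- rbind(c(0, 0, 9e-4), c(0, 0, -9e-4), c(9e-4, 0, 0), c(5e-4, 5e-4, 5e-4))
  for (i in seq_len(nrow(pts))) {
    r <- sqrt(sum(pts[i, ]^2)); costh <- pts[i, 3] / r
    p_exact <- rigid_sphere_total_field(a, k, r, costh)
    p_fem <- probe_pressure(s, pts[i, ])
    expect_lt(Mod(p_fem - p_exact) / Mod(p_exact), 0.05)
  }
})

test_that("scattering transfer is reciprocal under direction reversal", {
  a <- 6e-4; f <- 60e3
  m <- build_annulus_mesh(a, radius = 1.6e-3, target_h = 3.4e-4)
  s1 <- solve_frequency_domain(m, wave = plane_wave(direction = c(0, 0, 1)),
                               frequencies = f, order = 2,
                               check_resolution = "none")[[1]]
  s2 <- solve_frequency_domain(m, wave = plane_wave(direction = c(0, 0, -1)),
                               frequencies = f, order = 2,
                               check_resolution = "none")[[1]]
  pt <- c(3e-4, 2e-4, 1.1e-3)
  p1 <- probe_pressure(s1, pt)
  p2 <- probe_pressure(s2, -pt)
  expect_lt(abs(Mod(p1) - Mod(p2)) / Mod(p1), 0.01)
})

test_that("probe interpolation reproduces nodal and in-element values", {
  m <- build_ball_mesh(radius = 1e-3, target_h = 4e-4)
  dofs <- resonear:::fem_dofs(m, 2)
  # synthetic linear field is reproduced exactly by the interpolant
  s <- structure(list(frequency = 1, pressure = complex(real = dofs$coords[, 1],
                                                        imaginary = 0),
                      mesh = m, order = 2, wave = plane_wave(), air = air_medium()),
                 class = "harmonic_solution")
  pt <- c(2.3e-4, -1.1e-4, 3e-4)
  expect_equal(Re(probe_pressure(s, pt)), pt[1], tolerance = 1e-12)
  node <- m$nodes[10, ]
  expect_equal(Re(probe_pressure(s, node)), node[1], tolerance = 1e-12)
  expect_error(probe_pressure(s, c(5e-3, 0, 0)), "outside")
})

test_that("cavity gain is the dB ratio with an exact sign flip", {
  expect_equal(cavity_gain_db(1, 1), 0)
  expect_equal(cavity_gain_db(10, 1), 20)
  expect_equal(cavity_gain_db(0.5, 1), -6.0206, tolerance = 1e-4)
  expect_equal(cavity_gain_db(2.7, 0.9), -cavity_gain_db(0.9, 2.7))
  expect_error(cavity_gain_db(1, 0), "non-zero")
})

test_that("time stepping is quiescent without forcing and transmits plane waves", {
  m <- build_ball_mesh(radius = 1.2e-3, target_h = 3.5e-4)
  z <- solve_time_domain(m, wave = plane_wave(amplitude = 0), f0 = 60e3,
                         duration = 2e-5, probe_points = c(0, 0, 0))
  expect_true(all(z$probe_pressure == 0))
  ts <- solve_time_domain(m, f0 = 60e3, duration = 1.4e-4,
                          probe_points = c(0, 0, 0))
  expect_equal(steady_state_amplitude(ts), 1, tolerance = 0.03)
})

test_that("elastic shells recover the rigid solution in the stiff limit", {
  mesh <- build_parametric_ear(slit_area = 0.16e-6, cavity_volume = 0.14e-9,
                               sphere_radius = 1.5e-3, target_h = 4.5e-4,
                               n_theta = 12, n_phi = 22)
  f <- 80e3
  rigid <- solve_frequency_domain(mesh, frequencies = f, order = 1,
                                  check_resolution = "none")[[1]]
  stiff <- shell_material(thickness = 175e-6, stiffness_override = 1e15)
  near_rigid <- solve_frequency_domain(mesh, shells = stiff, frequencies = f,
                                       order = 1, check_resolution = "none")[[1]]
  p1 <- probe_pressure(rigid, c(0, 0, 0))
  p2 <- probe_pressure(near_rigid, c(0, 0, 0))
  expect_lt(Mod(p1 - p2) / Mod(p1), 1e-3)
  # a compliant shell changes the interior field and reports displacements
  soft <- shell_material(thickness = 5e-6)
  el <- solve_frequency_domain(mesh, shells = soft, frequencies = f,
                               order = 1, check_resolution = "none")[[1]]
  expect_true(all(is.finite(Mod(el$shell_displacement))))
  expect_gt(max(Mod(el$shell_displacement)), 0)
})
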