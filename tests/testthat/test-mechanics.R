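mech <- mechanics_params()

test_that("softcore potential has depth -epsilon at the contact separation", {
  ## use a cutoff far enough out that the energy shift is negligible
  ff <- mechanics_params(rcut_factor = 1e3)
  sij <- 2 * ff$sigma0
  r_min <- ff$zeta * sij
  expect_equal(softcore_lj_energy(r_min, sij, ff), -ff$epsilon,
               tolerance = 1e-10)
  ## zero slope at the minimum
  expect_equal(pair_force(c(r_min, 0, 0), sij, ff), c(0, 0, 0),
               tolerance = 1e-20)
  ## finite at zero separation (softcore): U_raw(0) = 4 eps (c^-2 - c^-1)
  u0 <- softcore_lj_energy(0, sij, ff)
  expect_true(is.finite(u0))
  expect_equal(u0, 4 * ff$epsilon * (ff$c_soft^-2 - ff$c_soft^-1),
               tolerance = 1e-8)
})

test_that("potential is truncated and shifted to zero at the cutoff", {
  sij <- 2 * mech$sigma0
  rcut <- mech$rcut_factor * mech$zeta * sij
  expect_identical(softcore_lj_energy(rcut, sij, mech), 0)
  expect_identical(softcore_lj_energy(rcut * 2, sij, mech), 0)
  ## continuity just inside the cutoff
  expect_lt(abs(softcore_lj_energy(rcut * (1 - 1e-8), sij, mech)),
            1e-8 * mech$epsilon)
  expect_error(softcore_lj_energy(1, -1, mech), "positive")
})

test_that("pair force is the negative gradient of the pair energy", {
  sij <- 2 * mech$sigma0
  rcut <- mech$rcut_factor * mech$zeta * sij
  h <- 1e-5
  for (r in seq(0.3 * sij, 0.99 * rcut, length.out = 40)) {
    f <- pair_force(c(r, 0, 0), sij, mech)[1]
    fd <- -(softcore_lj_energy(r + h, sij, mech) -
              softcore_lj_energy(r - h, sij, mech)) / (2 * h)
    expect_equal(f, fd, tolerance = 1e-6)
  }
  ## repulsive inside the minimum, attractive outside (up to the cutoff)
  r_min <- mech$zeta * sij
  expect_gt(pair_force(c(0.8 * r_min, 0, 0), sij, mech)[1], 0)
  expect_lt(pair_force(c(1.2 * r_min, 0, 0), sij, mech)[1], 0)
})

test_that("coincident centers yield a zero force with a warning", {
  expect_warning(f <- pair_force(c(0, 0, 0), 2 * mech$sigma0, mech),
                 "coincident")
  expect_identical(f, c(0, 0, 0))
})

test_that("population forces obey action-reaction and translation invariance", {
  pop <- random_population(80, side = 30)
  ff <- total_forces(pop, mech)
  ## pairwise antisymmetry implies zero net momentum change from pair forces
  expect_equal(colSums(ff$pair), c(0, 0, 0), tolerance = 1e-12)
  shifted <- pop
  shifted$pos <- sweep(pop$pos, 2, c(17.3, -4.2, 8.8), `+`)
  expect_equal(total_forces(shifted, mech)$pair, ff$pair, tolerance = 1e-9)
  ## Newton's third law on an isolated pair
  pair <- two_cell_pop(1.8 * mech$zeta * mech$sigma0)
  fp <- total_forces(pair, mech)$pair
  expect_equal(fp[1, ], -fp[2, ], tolerance = 1e-18)
})

test_that("a single moving cell feels only friction", {
  pop <- two_cell_pop(1e6, mech,
                      vel = rbind(c(1e-3, -2e-3, 5e-4), c(0, 0, 0)))
  ff <- total_forces(pop, mech)
  expect_equal(ff$total[1, ], -mech$mu_fric * pop$vel[1, ], tolerance = 1e-18)
  expect_equal(unname(ff$pair), matrix(0, 2, 3))
})

test_that("two cells at the equilibrium separation at rest feel no force", {
  pop <- two_cell_pop(2 * mech$zeta * mech$sigma0, mech)
  ff <- total_forces(pop, mech)
  expect_equal(max(abs(ff$total)), 0, tolerance = 1e-18)
})

test_that("free flight is exact without forces and friction", {
  ff <- mechanics_params(mu_fric = 0)
  pop <- two_cell_pop(1e6, ff, vel = rbind(c(1, 0, 0), c(0, 0, 0)))
  out <- verlet_step(pop, ff, dt = 3.75, n_sub = 5L)
  expect_identical(out$pos[1, ], c(1e6 * 0 + 3.75, 0, 0) + pop$pos[1, ])
  expect_identical(out$vel, pop$vel)
})

test_that("friction reproduces the exponential velocity decay", {
  v0 <- 2e-3
  pop <- two_cell_pop(1e6, mech, vel = rbind(c(v0, 0, 0), c(0, 0, 0)))
  t_end <- 120
  h <- 0.1
  for (k in seq_len(t_end / h))
    pop <- verlet_step(pop, mech, dt = h, n_sub = 1L)
  v_exact <- v0 * exp(-mech$mu_fric * t_end / mech$m0)
  ## second-order accurate in the substep size
  expect_equal(pop$vel[1, 1], v_exact, tolerance = 1e-5)
})

test_that("energy drift without friction stays small over 1e4 substeps", {
  ff <- mechanics_params(mu_fric = 0)
  ## bound pair oscillating about the potential minimum
  pop <- two_cell_pop(0.95 * 2 * ff$zeta * ff$sigma0, ff)
  e0 <- mechanical_energy(pop, ff)$total
  for (k in 1:100) pop <- verlet_step(pop, ff, dt = 375, n_sub = 100L)
  e1 <- mechanical_energy(pop, ff)$total
  expect_lt(abs(e1 - e0) / abs(e0), 1e-4)
})

test_that("kinetic energy is non-increasing under friction alone", {
  pop <- two_cell_pop(1e6, mech,
                      vel = rbind(c(1e-3, 2e-3, -1e-3), c(5e-4, 0, 0)))
  ek <- numeric(50)
  for (k in 1:50) {
    pop <- verlet_step(pop, mech, dt = 3.75, n_sub = 1L)
    ek[k] <- sum(pop$vel^2)
  }
  expect_true(all(diff(ek) < 0))
})

test_that("a perturbed bound pair relaxes monotonically to equilibrium", {
  skip_if_not_installed("deSolve")
  r_eq <- 2 * mech$zeta * mech$sigma0
  pop <- two_cell_pop(0.9 * r_eq, mech)
  seps <- numeric(960)
  for (k in seq_along(seps)) {
    pop <- verlet_step(pop, mech, dt = 3.75, n_sub = 1L)
    seps[k] <- pop$pos[2, 1] - pop$pos[1, 1]
  }
  expect_true(all(diff(seps) > 0))       # overdamped: monotone approach
  expect_true(all(seps < r_eq))
  ## against a reference ODE integration of the 1-D two-body problem
  deriv <- function(t, y, parms) {
    f <- pair_force(c(y[1], 0, 0), 2 * mech$sigma0, mech)[1]
    list(c(y[2], (2 * f - mech$mu_fric * y[2]) / mech$m0))
  }
  ref <- deSolve::ode(y = c(0.9 * r_eq, 0), times = seq(0, 3600, by = 375),
                      func = deriv, parms = NULL, method = "ode45",
                      rtol = 1e-10, atol = 1e-12)
  expect_equal(seps[seq(100, 960, by = 100)], ref[2:10, 2], tolerance = 1e-3)
})

test_that("the stability guard aborts on oversized substep displacements", {
  pop <- two_cell_pop(20, mech, vel = rbind(c(10, 0, 0), c(0, 0, 0)))
  expect_error(verlet_step(pop, mech, dt = 3.75, n_sub = 1L), "n_sub")
})

test_that("cell-linked list forces equal the brute-force oracle", {
  pop <- random_population(400, side = 70)
  fb <- hipposim:::cpp_pair_forces(pop$pos, pop$sigma, mech$c_soft, mech$zeta,
                                   mech$epsilon, mech$rcut_factor, 1L)
  fc <- hipposim:::cpp_pair_forces(pop$pos, pop$sigma, mech$c_soft, mech$zeta,
                                   mech$epsilon, mech$rcut_factor, 2L)
  expect_equal(fb, fc, tolerance = 1e-13)
})
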