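p_tab <- reaction_params()
mech <- mechanics_params()
cyc <- cycle_params(dt = mech$dt, sigma0 = mech$sigma0, gamma = mech$gamma)

test_that("growth/arrest and phase discrimination assigns the four colors", {
  ## growing, mitosis -> orange
  d <- classify(X2 = 0.2, age = 0.5 * 3600, p_tab, cyc)
  expect_true(d$growing)
  expect_identical(d$phase, "M")
  expect_identical(d$color, 1L)
  ## arrested, G1 -> blue
  d <- classify(X2 = 0.010, age = 5 * 3600, p_tab, cyc)
  expect_false(d$growing)
  expect_identical(d$color, 2L)
  ## remaining quadrants
  expect_identical(classify(0.010, 0, p_tab, cyc)$color, 0L)   # cyan
  expect_identical(classify(0.2, 2 * 3600, p_tab, cyc)$color, 3L)  # red
  ## growth requires X2 strictly above threshold: the tie arrests
  expect_false(classify(p_tab$X_th, 0, p_tab, cyc)$growing)
  ## age exactly T_M is G1
  expect_identical(classify(0.2, cyc$T_M, p_tab, cyc)$phase, "G1")
})

make_single <- function(X2, sigma = mech$sigma0, age = 0) {
  new_population(id = 1L, pos = matrix(0, 1, 3), vel = matrix(0, 1, 3),
                 sigma = sigma, age = age, color = 1L,
                 X = matrix(c(0.05, X2, 0), 1, 3), rho = 0)
}

test_that("growing cells age and grow by one increment per step", {
  pop <- make_single(X2 = 0.2)
  out <- grow_step(pop, p_tab, cyc, mech)
  expect_equal(out$sigma, mech$sigma0 * (1 + mech$gamma * mech$dt / cyc$T_CC),
               tolerance = 1e-14)
  expect_equal(out$age, mech$dt)
  expect_identical(out$color, 1L)
})

test_that("arrest freezes age and size bit-exactly", {
  pop <- make_single(X2 = 0.005, sigma = 4.8, age = 1234)
  for (k in 1:100) pop <- grow_step(pop, p_tab, cyc, mech)
  expect_identical(pop$sigma, 4.8)
  expect_identical(pop$age, 1234)
  expect_identical(pop$color, 0L)  # cyan: arrested in M
})

test_that("uninterrupted growth reaches the division size in exactly T_CC", {
  pop <- make_single(X2 = 0.2)
  n_steps <- ceiling(cyc$T_CC / mech$dt)
  for (k in seq_len(n_steps)) pop <- grow_step(pop, p_tab, cyc, mech)
  expect_equal(pop$sigma, 2^(1 / 3) * mech$sigma0, tolerance = 1e-9)
  expect_equal(pop$age, cyc$T_CC)
})

test_that("division creates two daughters with the published kinematics", {
  sig_div <- 2^(1 / 3) * mech$sigma0
  pop <- make_single(X2 = 0.2, sigma = sig_div, age = cyc$T_CC)
  pop$X[1, ] <- c(0.031, 0.173, 0.046)
  X_mother <- pop$X[1, ]
  rng <- make_rng(4)
  out <- divide_ready(pop, rng, mech, cyc)
  expect_identical(n_cells(out), 2L)
  ## daughter separation 2 gamma sigma0' ~ 2.5992 um
  sep <- sqrt(sum((out$pos[2, ] - out$pos[1, ])^2))
  expect_equal(sep, 2 * mech$gamma * mech$sigma0_prime, tolerance = 1e-12)
  expect_equal(sep, 2.59921, tolerance = 1e-5)
  ## daughter speed (1 - gamma) sigma0' / T_M ~ 1.0281e-3 um/s
  speeds <- sqrt(rowSums(out$vel^2))
  expect_equal(speeds, rep((1 - mech$gamma) * mech$sigma0_prime / cyc$T_M, 2),
               tolerance = 1e-12)
  expect_equal(speeds[1], 1.02789e-3, tolerance = 1e-5)
  ## daughters separate in opposite directions along a unit vector
  expect_equal(out$vel[1, ], -out$vel[2, ], tolerance = 1e-18)
  ## volume audit: mother radius at division is zeta * 2^(1/3) sigma0 =
  ## 2^(1/3) sigma0', whose cube equals the two daughters' sigma0'^3 + sigma0'^3
  vol_mother <- (mech$zeta * sig_div)^3
  expect_equal(vol_mother, 2 * mech$sigma0_prime^3, tolerance = 1e-12)
  ## concentrations inherited bit-exactly; fresh state otherwise
  expect_identical(out$X[1, ], X_mother)
  expect_identical(out$X[2, ], X_mother)
  expect_identical(out$sigma, rep(mech$sigma0, 2))
  expect_identical(out$age, c(0, 0))
  expect_identical(out$color, c(1L, 1L))
  expect_identical(out$id, c(1L, 2L))
})

test_that("cells below the division size are left untouched", {
  pop <- make_single(X2 = 0.2, sigma = 0.99 * 2^(1 / 3) * mech$sigma0)
  out <- divide_ready(pop, make_rng(1), mech, cyc)
  expect_identical(out, pop)
})

test_that("simultaneous divisions process in id order with fresh ids", {
  sig_div <- 2^(1 / 3) * mech$sigma0
  pop <- new_population(id = c(5L, 2L), pos = rbind(c(0, 0, 0), c(30, 0, 0)),
                        vel = matrix(0, 2, 3), sigma = rep(sig_div, 2),
                        age = rep(cyc$T_CC, 2), color = c(3L, 3L),
                        X = matrix(0.1, 2, 3), rho = c(0, 0))
  rng1 <- make_rng(9)
  out <- divide_ready(pop, rng1, mech, cyc)
  expect_identical(n_cells(out), 4L)
  expect_identical(sort(out$id), c(2L, 5L, 6L, 7L))
  ## the lower id divides first: it consumes the first direction draw
  rng2 <- make_rng(9)
  d1 <- draw_direction(rng2)
  i2 <- which(out$id == 2L)
  expect_equal(out$pos[i2, ], c(30, 0, 0) - mech$gamma * mech$sigma0_prime *
                 d1$e_r, tolerance = 1e-14)
})

test_that("a permanently growing cell divides every ceiling(T_CC/dt) steps", {
  ## short cycle keeps the loop cheap: T_CC = 30 min, T_M = 6 min
  cyc2 <- cycle_params(T_CC = 0.5, T_M = 0.1, dt = mech$dt,
                       sigma0 = mech$sigma0, gamma = mech$gamma)
  period <- as.integer(ceiling(cyc2$T_CC / mech$dt))  # 480 steps
  pop <- make_single(X2 = 0.2)
  division_steps <- integer(0)
  for (k in 1:(2 * period + 2)) {
    pop <- grow_step(pop, p_tab, cyc2, mech)
    n_before <- n_cells(pop)
    pop <- divide_ready(pop, make_rng(k), mech, cyc2)
    if (n_cells(pop) > n_before) division_steps <- c(division_steps, k)
  }
  expect_identical(division_steps, c(period, 2L * period))
  expect_identical(n_cells(pop), 4L)
})
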