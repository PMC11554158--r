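## Shared fixtures: all built in code at test time.

## Independent adaptive Runge-Kutta oracle for the reaction system.
rk_propagate <- function(X, rho, dt, p, tol = 1e-12) {
  deriv <- function(t, y, parms) list(hipposim::reaction_rhs(y, rho, p))
  out <- deSolve::ode(y = X, times = c(0, dt), func = deriv, parms = NULL,
                      method = "ode45", rtol = tol, atol = tol * 1e-2)
  unname(out[2, 2:4])
}

## 12 nearest-neighbor directions of a face-centered-cubic lattice.
fcc_directions <- function() {
  dirs <- rbind(
    c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0),
    c(1, 0, 1), c(1, 0, -1), c(-1, 0, 1), c(-1, 0, -1),
    c(0, 1, 1), c(0, 1, -1), c(0, -1, 1), c(0, -1, -1))
  dirs / sqrt(2)
}

## A population with one center cell and `k` equal neighbors at separation
## `scale` times the contact distance.
contact_cluster <- function(k, mech = mechanics_params(), scale = 1) {
  stopifnot(k <= 12)
  contact <- 2 * mech$zeta * mech$sigma0
  dirs <- fcc_directions()[seq_len(k), , drop = FALSE]
  pos <- rbind(c(0, 0, 0), dirs * contact * scale)
  n <- k + 1L
  new_population(id = seq_len(n), pos = pos, vel = matrix(0, n, 3),
                 sigma = rep(mech$sigma0, n), age = rep(0, n),
                 color = rep(1L, n),
                 X = matrix(rep(c(0.05, 0.2, 0), each = n), n, 3),
                 rho = rep(0, n))
}

## A reproducible random cloud of n cells in a box of the given side (um).
random_population <- function(n, side = 40, seed = 42,
                              mech = mechanics_params()) {
  set.seed(seed)
  new_population(
    id = seq_len(n),
    pos = matrix(runif(3 * n, -side / 2, side / 2), n, 3),
    vel = matrix(rnorm(3 * n, sd = 1e-3), n, 3),
    sigma = runif(n, mech$sigma0, 2^(1 / 3) * mech$sigma0),
    age = runif(n, 0, 7.2e4), color = sample(0:3, n, replace = TRUE),
    X = matrix(runif(3 * n, 0, 0.3), n, 3), rho = rep(0, n))
}

## Two birth-size cells on the x axis at the given separation, at rest.
two_cell_pop <- function(sep, mech = mechanics_params(), vel = matrix(0, 2, 3)) {
  new_population(id = 1:2,
                 pos = rbind(c(0, 0, 0), c(sep, 0, 0)), vel = vel,
                 sigma = rep(mech$sigma0, 2), age = c(0, 0), color = c(1L, 1L),
                 X = matrix(rep(c(0.05, 0.2, 0), each = 2), 2, 3),
                 rho = c(0, 0))
}
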