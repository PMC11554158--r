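## R surface of the mechanics module. Scalar reference forms of the softcore
## pair potential, population-level forces, and the Verlet driver over the
## compiled kernels.

#' Softcore Lennard-Jones pair energy
#'
#' Truncated-and-shifted softcore 12-6 potential
#' `U(r) = 4 eps (S^-2 - S^-1) - U_raw(r_cut)` below the cutoff, zero beyond,
#' with `S(r) = alpha_LJ (1-lambda)^2 + (r / sigma_ij)^6`. The softcore
#' constant keeps the energy finite at zero separation, so each cell keeps an
#' exclusive domain without numerical blow-up; the minimum (depth `-eps`
#' before shifting) sits at separation `zeta * sigma_ij`, the sum of the two cell
#' radii.
#'
#' @param r Separation(s) (um), >= 0; vectorized.
#' @param sigma_ij Pair length scale `sigma_i + sigma_j` (um).
#' @param ff A [mechanics_params()] object (used for `c_soft`, `zeta`,
#'   `epsilon`, `rcut_factor`).
#' @return Energy (ng um^2/s^2), zero at and beyond the cutoff.
#' @export
softcore_lj_energy <- function(r, sigma_ij, ff) {
  if (sigma_ij <= 0) stop("sigma_ij must be positive")
  if (any(r < 0)) stop("separation r must be >= 0")
  rcut <- ff$rcut_factor * ff$zeta * sigma_ij
  u_raw <- function(d) {
    S <- ff$c_soft + (d / sigma_ij)^6
    4 * ff$epsilon * (S^-2 - S^-1)
  }
  ifelse(r < rcut, u_raw(r) - u_raw(rcut), 0)
}

#' Softcore Lennard-Jones pair force
#'
#' Force `F = -grad U` exerted on the cell at displacement `r_vec` from its
#' neighbor: repulsive below the equilibrium separation `zeta * sigma_ij`,
#' attractive between there and the cutoff.
#'
#' @param r_vec Displacement 3-vector from neighbor to cell (um).
#' @param sigma_ij Pair length scale `sigma_i + sigma_j` (um).
#' @param ff A [mechanics_params()] object.
#' @return Force 3-vector (ng um/s^2). Coincident centers give a zero force
#'   with a warning (the direction is undefined; the softcore energy stays
#'   finite).
#' @export
pair_force <- function(r_vec, sigma_ij, ff) {
  if (sigma_ij <= 0) stop("sigma_ij must be positive")
  d <- sqrt(sum(r_vec^2))
  if (d == 0) {
    warning("coincident cell centers: pair force direction undefined, using 0")
    return(c(0, 0, 0))
  }
  rcut <- ff$rcut_factor * ff$zeta * sigma_ij
  if (d >= rcut) return(c(0, 0, 0))
  S <- ff$c_soft + (d / sigma_ij)^6
  dUdS <- 4 * ff$epsilon * (-2 * S^-3 + S^-2)
  dUdr <- dUdS * 6 * d^5 / sigma_ij^6
  -dUdr * r_vec / d
}

#' Total forces on every cell of a population
#'
#' Sum of softcore pair forces over all neighbors within the cutoff plus
#' Stokes friction `-mu_fric * v`. The pair part obeys Newton's third law, so
#' it sums to zero over the population.
#'
#' @param pop A `cell_population`.
#' @param ff A [mechanics_params()] object.
#' @param method Neighbor search: `"auto"` (brute force for N <= 200, else
#'   cell-linked lists), `"brute"`, or `"cell"`.
#' @return A list with N x 3 matrices `pair` and `friction`, and their sum
#'   `total`.
#' @export
total_forces <- function(pop, ff, method = c("auto", "brute", "cell")) {
  method <- .neighbor_code(match.arg(method))
  pair <- cpp_pair_forces(pop$pos, pop$sigma, ff$c_soft, ff$zeta, ff$epsilon,
                          ff$rcut_factor, method)
  friction <- -ff$mu_fric * pop$vel
  list(pair = pair, friction = friction, total = pair + friction)
}

.neighbor_code <- function(method) {
  switch(method, auto = 0L, brute = 1L, cell = 2L,
         stop("unknown neighbor method: ", method))
}

#' Advance cell positions and velocities by one global step
#'
#' Velocity-Verlet integration of `m0 dv/dt = F_pair - mu_fric v` over
#' `n_sub` substeps of `dt / n_sub`, with the friction term treated
#' semi-implicitly at the half-step velocity. With zero friction and no
#' forces the motion is exactly uniform; identical inputs give bit-identical
#' output.
#'
#' @param pop A `cell_population`.
#' @param ff A [mechanics_params()] object.
#' @param dt Global time step (s).
#' @param n_sub Number of substeps (default from `ff`).
#' @param method Neighbor search method, see [total_forces()].
#' @return The population with updated `pos` and `vel`.
#' @export
verlet_step <- function(pop, ff, dt = ff$dt, n_sub = ff$n_sub,
                        method = c("auto", "brute", "cell")) {
  if (dt <= 0) stop("dt must be positive")
  method <- .neighbor_code(match.arg(method))
  out <- cpp_verlet(pop$pos, pop$vel, pop$sigma, ff$m0, ff$mu_fric, dt,
                    as.integer(n_sub), ff$c_soft, ff$zeta, ff$epsilon,
                    ff$rcut_factor, method)
  if (!out$ok)
    stop("mechanics instability: a substep displacement of ",
         format(out$max_disp, digits = 4), " um exceeded half the smallest ",
         "cell radius (", format(out$disp_limit, digits = 4),
         " um); increase n_sub (currently ", n_sub, ") or reduce dt",
         call. = FALSE)
  pop$pos <- out$pos
  pop$vel <- out$vel
  pop
}

#' Total mechanical energy of a population
#'
#' Kinetic plus truncated-shifted pair potential energy; used by the
#' integrator drift diagnostics.
#'
#' @inheritParams total_forces
#' @return A list with `kinetic`, `potential` and `total` (ng um^2/s^2).
#' @export
mechanical_energy <- function(pop, ff, method = c("auto", "brute", "cell")) {
  method <- .neighbor_code(match.arg(method))
  pot <- cpp_total_potential(pop$pos, pop$sigma, ff$c_soft, ff$zeta,
                             ff$epsilon, ff$rcut_factor, method)
  kin <- 0.5 * ff$m0 * sum(pop$vel^2)
  list(kinetic = kin, potential = pot, total = kin + pot)
}

#' Calibrate the pair-potential well depth
#'
#' Finds the well depth `epsilon` for which two birth-size cells released at
#' rest from 0.9 times their equilibrium separation settle (and stay) within
#' `settle_frac` of equilibrium in exactly `target_time` under the default
#' friction. Weaker adhesion settles too slowly; the returned value is the
#' slowest-settling admissible well depth, which also keeps the relaxation
#' overdamped (monotone in separation).
#'
#' @param ff A [mechanics_params()] template; `epsilon` is ignored.
#' @param target_time Required settling time (s); default one mitosis phase
#'   (3600 s).
#' @param settle_frac Relative distance from equilibrium that counts as
#'   settled (default 0.01).
#' @param dt Integration substep (s).
#' @param lower,upper Bisection bracket for epsilon (ng um^2/s^2).
#' @return The calibrated epsilon.
#' @export
calibrate_epsilon <- function(ff = mechanics_params(), target_time = 3600,
                              settle_frac = 0.01, dt = 3.75,
                              lower = 1e-7, upper = 1e-2) {
  settle_time <- function(eps) {
    f <- ff
    f$epsilon <- eps
    r_eq <- f$zeta * 2 * f$sigma0
    pop <- list(pos = rbind(c(0, 0, 0), c(0.9 * r_eq, 0, 0)),
                vel = matrix(0, 2, 3), sigma = rep(f$sigma0, 2))
    nstep <- ceiling(2 * target_time / dt)
    for (k in seq_len(nstep)) {
      pop <- verlet_step(pop, f, dt = dt, n_sub = 1L, method = "brute")
      sep <- sqrt(sum((pop$pos[2, ] - pop$pos[1, ])^2))
      if (abs(sep - r_eq) <= settle_frac * r_eq) return(k * dt)
    }
    Inf
  }
  if (!is.finite(settle_time(upper)) || is.finite(settle_time(lower)))
    stop("bisection bracket does not straddle the settling target")
  for (it in 1:60) {
    mid <- sqrt(lower * upper)
    if (settle_time(mid) <= target_time) upper <- mid else lower <- mid
    if (upper / lower < 1 + 1e-6) break
  }
  upper
}
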