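## Growth-vs-arrest discrimination, the four-color phase labels, and
## volume-conserving division.
##
## A cell is growing iff its nuclear YAP/TAZ strictly exceeds X_th (the
## boundary case X2 == X_th counts as arrest); it is in the M phase while its
## age is below T_M, in G1 afterwards. Colors: 0 cyan (arrest, M), 1 orange
## (growing, M), 2 blue (arrest, G1), 3 red (growing, G1). Both
## discriminations are re-evaluated every step, so growing and arrested
## states alternate freely as the density signal changes.

#' Growth/arrest and phase classification
#'
#' @param X2 Nuclear YAP/TAZ concentration(s) (uM); vectorized.
#' @param age Cell age(s) since last division (s).
#' @param p A [reaction_params()] object (threshold `X_th`).
#' @param cyc A [cycle_params()] object (mitosis duration `T_M`).
#' @return A list with logical `growing`, factor-free `phase` ("M" or "G1")
#'   and integer `color` in 0..3.
#' @export
#' @examples
#' classify(X2 = 0.2, age = 0.5 * 3600, reaction_params(), cycle_params())
classify <- function(X2, age, p, cyc) {
  growing <- X2 > p$X_th
  m_phase <- age < cyc$T_M
  color <- ifelse(growing, ifelse(m_phase, 1L, 3L),
                  ifelse(m_phase, 0L, 2L))
  list(growing = growing, phase = ifelse(m_phase, "M", "G1"),
       color = as.integer(color))
}

## division readiness uses a tiny relative tolerance so that T_CC/dt exact
## float increments trigger on the intended step
.division_ready <- function(sigma, sigma0) {
  sigma >= 2^(1 / 3) * sigma0 * (1 - 1e-12)
}

#' Apply one step of classification and growth to a population
#'
#' Growing cells age by `dt` and grow by `d_sigma = gamma dt sigma0 / T_CC`
#' (clipped at the division size `2^(1/3) sigma0`); arrested cells keep age
#' and size frozen. Colors are refreshed from the classification.
#'
#' @param pop A `cell_population`.
#' @param p A [reaction_params()] object.
#' @param cyc A [cycle_params()] object.
#' @param mech A [mechanics_params()] object (`sigma0`, `dt`).
#' @return The updated population.
#' @export
grow_step <- function(pop, p, cyc, mech) {
  cls <- classify(pop$X[, 2], pop$age, p, cyc)
  pop$color <- cls$color
  g <- cls$growing
  sig_max <- 2^(1 / 3) * mech$sigma0
  pop$age[g] <- pop$age[g] + mech$dt
  pop$sigma[g] <- pmin(pop$sigma[g] + cyc$d_sigma, sig_max)
  pop
}

#' Divide every division-ready cell
#'
#' A cell whose size parameter has reached `2^(1/3) sigma0` splits into two
#' daughters of size `sigma0` and age 0, placed at `r_mother -/+ gamma
#' sigma0' e_r` with velocities `-/+ (1 - gamma) sigma0' e_r / T_M` along a
#' random unit direction `e_r` (azimuth uniform on `[0, 2 pi)`, polar angle
#' uniform on `[0, pi)`). Since the mother radius at division is
#' `2^(1/3) sigma0'` and each daughter radius is `sigma0'`, the mother volume
#' equals the summed daughter volumes, and both daughters fit inside the
#' mother's footprint. Daughters inherit the mother's concentrations
#' unchanged and are colored orange (growing, M). Simultaneously ready cells
#' divide in ascending id order; new daughters are not re-checked until the
#' next step.
#'
#' @param pop A `cell_population`.
#' @param rng A `sim_rng` stream from [make_rng()].
#' @param mech A [mechanics_params()] object.
#' @param cyc A [cycle_params()] object.
#' @param sphere_uniform Use area-uniform division directions (default off,
#'   matching the stated uniform-polar-angle convention).
#' @return The population, with one extra cell per division.
#' @export
divide_ready <- function(pop, rng, mech, cyc, sphere_uniform = FALSE) {
  ready <- which(.division_ready(pop$sigma, mech$sigma0))
  if (length(ready) == 0L) return(pop)
  ready <- ready[order(pop$id[ready])]
  for (i in ready) {
    dir <- draw_direction(rng, sphere_uniform)
    offset <- mech$gamma * mech$sigma0_prime * dir$e_r
    vsep <- (1 - mech$gamma) * mech$sigma0_prime * dir$e_r / cyc$T_M
    r_mother <- pop$pos[i, ]
    X_mother <- pop$X[i, ]
    pop$pos[i, ] <- r_mother - offset
    pop$vel[i, ] <- -vsep
    pop$sigma[i] <- mech$sigma0
    pop$age[i] <- 0
    pop$color[i] <- 1L
    pop$id <- c(pop$id, pop$next_id)
    pop$next_id <- pop$next_id + 1L
    pop$pos <- rbind(pop$pos, matrix(r_mother + offset, 1, 3))
    pop$vel <- rbind(pop$vel, matrix(vsep, 1, 3))
    pop$sigma <- c(pop$sigma, mech$sigma0)
    pop$age <- c(pop$age, 0)
    pop$color <- c(pop$color, 1L)
    pop$X <- rbind(pop$X, matrix(X_mother, 1, 3))
    pop$rho <- c(pop$rho, pop$rho[i])  # recomputed in the density stage
  }
  pop
}
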