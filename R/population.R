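## The population container: one agent per cell, stored column-wise in plain
## matrices/vectors for fast per-step updates.

#' Construct a cell population
#'
#' @param id Integer cell ids (unique).
#' @param pos N x 3 matrix of center positions (um).
#' @param vel N x 3 matrix of velocities (um/s).
#' @param sigma Size parameters (um), in `[sigma0, 2^(1/3) sigma0]`; the cell
#'   radius is `zeta * sigma`.
#' @param age Time since last division (s).
#' @param color Phase/state color index: 0 cyan (arrest, M), 1 orange
#'   (growing, M), 2 blue (arrest, G1), 3 red (growing, G1).
#' @param X N x 3 matrix of concentrations (uM): cytoplasmic, nuclear and
#'   phosphorylated YAP/TAZ.
#' @param rho Local packing fractions (dimensionless).
#' @param t Simulation time (s).
#' @param step Step counter.
#' @return An object of class `cell_population`.
#' @export
new_population <- function(id, pos, vel, sigma, age, color, X, rho,
                           t = 0, step = 0L) {
  n <- length(id)
  pos <- matrix(as.numeric(pos), n, 3)
  vel <- matrix(as.numeric(vel), n, 3)
  X <- matrix(as.numeric(X), n, 3)
  if (anyDuplicated(id)) stop("cell ids must be unique")
  if (any(X < 0)) stop("concentrations must be non-negative")
  if (any(rho < 0)) stop("packing fractions must be non-negative")
  structure(list(id = as.integer(id), pos = pos, vel = vel,
                 sigma = as.numeric(sigma), age = as.numeric(age),
                 color = as.integer(color), X = X, rho = as.numeric(rho),
                 t = t, step = as.integer(step),
                 next_id = max(as.integer(id)) + 1L),
            class = "cell_population")
}

#' Number of cells in a population
#' @param pop A `cell_population`.
#' @return Integer cell count.
#' @export
n_cells <- function(pop) length(pop$id)

#' Cell radii of a population
#' @param pop A `cell_population`.
#' @param mech A [mechanics_params()] object supplying `zeta`.
#' @return Radii (um), `zeta * sigma`.
#' @export
cell_radii <- function(pop, mech) mech$zeta * pop$sigma

.color_names <- c("cyan", "orange", "blue", "red")

#' @export
print.cell_population <- function(x, ...) {
  counts <- tabulate(x$color + 1L, nbins = 4L)
  cat("<cell_population> N =", n_cells(x), " t =",
      format(x$t / 3600, digits = 4), "h  step =", x$step, "\n")
  cat("  colors:", paste(sprintf("%s=%d", .color_names, counts),
                         collapse = " "), "\n")
  cat("  X2 range: [", format(min(x$X[, 2]), digits = 4), ",",
      format(max(x$X[, 2]), digits = 4), "] uM\n")
  invisible(x)
}

#' Convert a population to a data frame
#'
#' One row per cell with the full per-cell state; the layout used by
#' [write_snapshot()].
#'
#' @param x A `cell_population`.
#' @param mech A [mechanics_params()] object (for the radius column); if
#'   omitted the default parameters are used.
#' @param ... Unused.
#' @return A `data.frame` with one row per cell.
#' @export
as.data.frame.cell_population <- function(x, mech = mechanics_params(), ...) {
  data.frame(id = x$id, t = x$t,
             x = x$pos[, 1], y = x$pos[, 2], z = x$pos[, 3],
             vx = x$vel[, 1], vy = x$vel[, 2], vz = x$vel[, 3],
             sigma = x$sigma, radius = mech$zeta * x$sigma, age = x$age,
             color = x$color, X1 = x$X[, 1], X2 = x$X[, 2], X3 = x$X[, 3],
             rho = x$rho)
}

#' Per-cell packing fractions
#'
#' Local density signal of every cell: a size-normalized sum of exponential
#' kernels over neighbors,
#' \deqn{\rho_i = \frac{1}{12} \sum_{j \ne i}
#'       e^{-(s_{ij} - 1)/\delta_\rho},\quad
#'       s_{ij} = \frac{|r_i - r_j|}{radius_i + radius_j},}
#' truncated at the mechanical cutoff. The 1/12 normalization calibrates
#' rho = 1 for a cell touched by 12 close-packed neighbors; an isolated cell
#' has rho = 0. Coincident centers contribute the finite value
#' `exp(1/delta_rho)/12`.
#'
#' @param pop A `cell_population`.
#' @param mech A [mechanics_params()] object.
#' @param delta_rho Kernel decay width (dimensionless, default 0.25).
#' @param method Neighbor search method, see [total_forces()].
#' @return Numeric vector of packing fractions (>= 0).
#' @export
packing_fraction <- function(pop, mech, delta_rho = 0.25,
                             method = c("auto", "brute", "cell")) {
  if (n_cells(pop) < 1L) stop("population must contain at least one cell")
  method <- .neighbor_code(match.arg(method))
  cpp_packing_fraction(pop$pos, pop$sigma, mech$zeta, delta_rho,
                       mech$rcut_factor, method)
}
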