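## Parameter containers, presets, configuration I/O and seeded randomness.
##
## Unit system (fixed): lengths in micrometres, times in seconds, masses in
## nanograms, concentrations in micromolar. Configuration files may give cell
## cycle durations in hours; they are converted once at load time.

#' Reaction-network parameters
#'
#' Rate constants and concentration scales of the per-cell Hippo-YAP/TAZ
#' reaction system. The three species are cytoplasmic YAP/TAZ (X1), nuclear
#' YAP/TAZ (X2) and phosphorylated cytoplasm-tethered YAP/TAZ (X3).
#'
#' @param a1 Nuclear import rate, cytoplasm to nucleus (1/s).
#' @param a2 Nuclear export rate, nucleus to cytoplasm (1/s).
#' @param a3 Dephosphorylation rate, phospho-YAP/TAZ back to cytoplasm (1/s).
#' @param b1 Density-dependent phosphorylation rate constant (1/(uM s));
#'   the effective phosphorylation rate is `b1 * rho * X0`.
#' @param X0 Input signal concentration transmitted into a cell at packing
#'   fraction 1 (uM).
#' @param X_th Nuclear YAP/TAZ threshold below which the cell cycle
#'   arrests (uM).
#' @return An object of class `reaction_params`.
#' @export
reaction_params <- function(a1 = 5e-2, a2 = 5e-4, a3 = 1e-4, b1 = 1,
                            X0 = 0.15, X_th = 0.012) {
  p <- list(a1 = a1, a2 = a2, a3 = a3, b1 = b1, X0 = X0, X_th = X_th)
  for (nm in c("a1", "a2", "a3", "b1")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0)
      stop("reaction rate '", nm, "' must be a single non-negative number")
  }
  if (X0 <= 0) stop("X0 must be positive")
  if (X_th <= 0) stop("X_th must be positive")
  structure(p, class = "reaction_params")
}

#' Mechanical parameters
#'
#' Geometry, mass, softcore Lennard-Jones force-field constants, friction and
#' integration settings for the center-based mechanics.
#'
#' The softcore potential is
#' \deqn{U(r) = 4\epsilon [ S(r)^{-2} - S(r)^{-1} ],\quad
#'       S(r) = \alpha_{LJ}(1-\lambda)^2 + (r/\sigma_{ij})^6,}
#' whose minimum lies at \eqn{r = \zeta \sigma_{ij}} with
#' \eqn{\zeta = (2 - \alpha_{LJ}(1-\lambda)^2)^{1/6}}. With the pair scale
#' \eqn{\sigma_{ij} = \sigma_i + \sigma_j}, two cells therefore rest exactly at
#' the sum of their radii (radius = \eqn{\zeta\sigma}).
#'
#' @param sigma0_prime Cell radius at birth (um).
#' @param alpha_LJ Dimensionless softcore parameter of the potential.
#' @param lambda_sc Dimensionless coupling parameter in `[0, 1]`. The default
#'   `NULL` solves `zeta = sigma0_prime / 4.53` so that the birth size
#'   parameter is sigma0 = 4.53 um when sigma0_prime = 5 um.
#' @param m0 Cell mass (ng), constant over growth.
#' @param epsilon Well depth of the pair potential (ng um^2 / s^2). The
#'   shipped default is calibrated so a two-cell pair released at 0.9 times
#'   its equilibrium separation settles within 1 percent of equilibrium in at
#'   most one mitosis phase under the default friction.
#' @param mu_fric Linear (Stokes) friction coefficient (ng/s); default gives a
#'   velocity relaxation time m0/mu_fric of 60 s.
#' @param rcut_factor Pair cutoff as a multiple of the equilibrium separation
#'   `zeta * sigma_ij`; energies are shifted to zero at the cutoff.
#' @param dt Global time step (s).
#' @param n_sub Number of velocity-Verlet substeps per global step.
#' @return An object of class `mechanics_params` with derived fields `zeta`,
#'   `sigma0`, `gamma` and `c_soft` (equal to `alpha_LJ * (1-lambda)^2`).
#' @export
mechanics_params <- function(sigma0_prime = 5, alpha_LJ = 0.5,
                             lambda_sc = NULL, m0 = 2,
                             epsilon = NULL, mu_fric = NULL,
                             rcut_factor = 2.5, dt = 3.75, n_sub = 1L) {
  if (sigma0_prime <= 0) stop("sigma0_prime must be positive")
  if (is.null(lambda_sc)) lambda_sc <- lambda_for_zeta(sigma0_prime / 4.53, alpha_LJ)
  if (lambda_sc < 0 || lambda_sc > 1) stop("lambda_sc must lie in [0, 1]")
  if (dt <= 0) stop("dt must be positive")
  n_sub <- as.integer(n_sub)
  if (n_sub < 1L) stop("n_sub must be >= 1")
  c_soft <- alpha_LJ * (1 - lambda_sc)^2
  if (c_soft <= 0 || c_soft >= 2)
    stop("alpha_LJ * (1 - lambda_sc)^2 must lie in (0, 2) for a softcore minimum")
  zeta <- (2 - c_soft)^(1 / 6)
  if (zeta < 1) stop("derived zeta < 1: radius cannot be smaller than sigma")
  if (is.null(epsilon)) epsilon <- .default_epsilon
  if (epsilon < 0) stop("epsilon must be non-negative")
  if (is.null(mu_fric)) mu_fric <- m0 / 60
  if (mu_fric < 0) stop("mu_fric must be non-negative")
  structure(list(
    sigma0_prime = sigma0_prime, alpha_LJ = alpha_LJ, lambda_sc = lambda_sc,
    c_soft = c_soft, zeta = zeta, sigma0 = sigma0_prime / zeta,
    gamma = 2^(1 / 3) - 1, m0 = m0, epsilon = epsilon, mu_fric = mu_fric,
    rcut_factor = rcut_factor, dt = dt, n_sub = n_sub
  ), class = "mechanics_params")
}

## Calibrated well depth (ng um^2/s^2); see scripts/calibrate-epsilon.R.
.default_epsilon <- 1.2674265e-05

#' Solve the coupling parameter for a target radius ratio
#'
#' Inverts `zeta = (2 - alpha_LJ (1 - lambda)^2)^(1/6)` for lambda.
#'
#' @param zeta Target ratio of cell radius to size parameter sigma.
#' @param alpha_LJ Softcore parameter.
#' @return The coupling parameter lambda in `[0, 1]`.
#' @export
lambda_for_zeta <- function(zeta, alpha_LJ = 0.5) {
  c_soft <- 2 - zeta^6
  if (c_soft <= 0 || c_soft > alpha_LJ)
    stop("no lambda in [0,1] gives zeta = ", zeta, " with alpha_LJ = ", alpha_LJ)
  1 - sqrt(c_soft / alpha_LJ)
}

#' Cell-cycle parameters
#'
#' @param T_CC Full cell-cycle duration. Hours if `hours = TRUE` (default),
#'   else seconds.
#' @param T_M Mitosis (M) phase duration, same unit convention.
#' @param dt Global time step (s), used to derive the per-step growth
#'   increment `d_sigma = gamma * dt * sigma0 / T_CC`.
#' @param sigma0 Size parameter at birth (um).
#' @param gamma Geometric division ratio `2^(1/3) - 1`.
#' @param hours Whether `T_CC` and `T_M` are given in hours.
#' @return An object of class `cycle_params`; durations stored in seconds.
#' @export
cycle_params <- function(T_CC = 20, T_M = 1, dt = 3.75,
                         sigma0 = 5 / (5 / 4.53), gamma = 2^(1 / 3) - 1,
                         hours = TRUE) {
  if (hours) {
    T_CC <- T_CC * 3600
    T_M <- T_M * 3600
  }
  if (!(T_M > 0 && T_M < T_CC)) stop("need 0 < T_M < T_CC")
  structure(list(
    T_CC = T_CC, T_M = T_M,
    d_sigma = gamma * dt * sigma0 / T_CC
  ), class = "cycle_params")
}

.preset_concentrations <- list(
  normal = c(0.05, 0.2, 0),
  cancer = c(0.1, 0.4, 0)
)

#' Default simulation configuration for a tissue preset
#'
#' Assembles the full parameter set of the coupled mechanics/signaling
#' simulation. The two presets differ only in initial YAP/TAZ concentrations:
#' cancer tissue carries twofold the normal levels of both cytoplasmic and
#' nuclear YAP/TAZ.
#'
#' @param preset `"normal"` (initial concentrations 0.05, 0.2, 0 uM) or
#'   `"cancer"` (0.1, 0.4, 0 uM).
#' @param L Total number of global steps (default 200000, i.e. 208.3 h at
#'   dt = 3.75 s).
#' @param seed Integer seed controlling all randomness of a run.
#' @param snapshot_every Record a population summary every this many steps.
#' @param ... Overrides passed to [reaction_params()], [mechanics_params()]
#'   or top-level config fields by name.
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- default_config("normal")
#' cfg$initial_concentrations
default_config <- function(preset = c("normal", "cancer"), L = 200000L,
                           seed = 1L, snapshot_every = 160L, ...) {
  preset <- match.arg(preset)
  mech <- mechanics_params()
  cfg <- structure(list(
    preset = preset,
    reaction = reaction_params(),
    mechanics = mech,
    cycle = cycle_params(dt = mech$dt, sigma0 = mech$sigma0, gamma = mech$gamma),
    density = list(delta_rho = 0.25, rho_grid = 1e-3),
    initial_concentrations = .preset_concentrations[[preset]],
    L = as.integer(L), seed = as.integer(seed),
    snapshot_every = as.integer(snapshot_every),
    options = list(sphere_uniform = FALSE, neighbor = "auto",
                   max_N = Inf, verbose = FALSE)
  ), class = "sim_config")
  dots <- list(...)
  for (nm in names(dots)) cfg <- set_config(cfg, nm, dots[[nm]])
  validate_config(cfg)
}

## Assign an override by (possibly nested) name, e.g. "reaction.b1".
set_config <- function(cfg, name, value) {
  path <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (length(path) == 1L && path %in% names(cfg$reaction)) {
    cfg$reaction[[path]] <- value
  } else if (length(path) == 2L) {
    cfg[[path[1]]][[path[2]]] <- value
  } else if (path %in% names(cfg)) {
    cfg[[path]] <- value
  } else {
    stop("unknown configuration key: ", name)
  }
  cfg
}

#' Validate a simulation configuration
#'
#' Re-derives the dependent mechanical and cycle quantities (zeta, sigma0,
#' gamma, d_sigma) from the primitive parameters and checks every structural
#' invariant. Called by [default_config()] and [read_config()].
#'
#' @param cfg A `sim_config` list.
#' @return The validated (and re-derived) configuration, invisibly classed.
#' @export
validate_config <- function(cfg) {
  m <- cfg$mechanics
  cfg$mechanics <- mechanics_params(
    sigma0_prime = m$sigma0_prime, alpha_LJ = m$alpha_LJ,
    lambda_sc = m$lambda_sc, m0 = m$m0, epsilon = m$epsilon,
    mu_fric = m$mu_fric, rcut_factor = m$rcut_factor, dt = m$dt,
    n_sub = m$n_sub)
  m <- cfg$mechanics
  stopifnot(abs(m$zeta * m$sigma0 - m$sigma0_prime) <= 1e-12 * m$sigma0_prime,
            abs(m$gamma - (2^(1 / 3) - 1)) <= 1e-15)
  cy <- cfg$cycle
  cfg$cycle <- cycle_params(T_CC = cy$T_CC, T_M = cy$T_M, dt = m$dt,
                            sigma0 = m$sigma0, gamma = m$gamma, hours = FALSE)
  cfg$reaction <- do.call(reaction_params, unclass(cfg$reaction))
  if (!cfg$preset %in% c("normal", "cancer", "custom"))
    stop("preset must be 'normal', 'cancer' or 'custom'")
  if (cfg$preset %in% names(.preset_concentrations) &&
      !isTRUE(all.equal(cfg$initial_concentrations,
                        .preset_concentrations[[cfg$preset]], tolerance = 0)))
    stop("initial concentrations inconsistent with preset '", cfg$preset, "'")
  if (length(cfg$initial_concentrations) != 3L ||
      any(cfg$initial_concentrations < 0))
    stop("initial_concentrations must be 3 non-negative values")
  if (cfg$L < 0) stop("L must be >= 0")
  if (cfg$snapshot_every < 1L) stop("snapshot_every must be >= 1")
  if (cfg$density$delta_rho <= 0) stop("delta_rho must be positive")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> preset:", x$preset,
      " L:", x$L, " dt:", x$mechanics$dt, "s  seed:", x$seed, "\n")
  cat("  initial [X1,X2,X3] =", paste(x$initial_concentrations, collapse = ", "),
      "uM;  X_th =", x$reaction$X_th, "uM\n")
  cat("  sigma0' =", x$mechanics$sigma0_prime, "um; sigma0 =",
      format(x$mechanics$sigma0, digits = 6), "um; zeta =",
      format(x$mechanics$zeta, digits = 6), "\n")
  invisible(x)
}

## ---- configuration files ---------------------------------------------------

## numbers are serialized with 17 significant digits so that a write/read
## round trip is bit-exact
.yaml_num <- function(x) {
  r <- sprintf("%.17g", x)
  class(r) <- "verbatim"
  r
}

#' Write a configuration to a YAML file
#'
#' Numeric values are serialized with enough digits that reading the file
#' back reproduces every field exactly.
#'
#' @param cfg A `sim_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  x <- rapply(unclass(cfg), f = function(v) v, how = "list")
  x$options$max_N <- if (is.finite(cfg$options$max_N)) cfg$options$max_N else -1
  yaml::write_yaml(x, path, handlers = list(numeric = .yaml_num))
  invisible(path)
}

#' Read a configuration from a YAML file
#'
#' @param path A YAML file as written by [write_config()] (or one of the
#'   shipped presets under `system.file("presets", package = "hipposim")`).
#' @param hours If `TRUE`, `cycle$T_CC` and `cycle$T_M` in the file are in
#'   hours and converted to seconds; the shipped presets store seconds.
#' @return A validated `sim_config`.
#' @export
read_config <- function(path, hours = FALSE) {
  x <- yaml::read_yaml(path)
  ## yaml reads whole numbers as integers; parameters are doubles
  for (sect in c("reaction", "mechanics", "cycle", "density"))
    x[[sect]] <- lapply(x[[sect]], as.numeric)
  if (hours) {
    x$cycle$T_CC <- x$cycle$T_CC * 3600
    x$cycle$T_M <- x$cycle$T_M * 3600
  }
  x$L <- as.integer(x$L)
  x$seed <- as.integer(x$seed)
  x$snapshot_every <- as.integer(x$snapshot_every)
  x$mechanics$n_sub <- as.integer(x$mechanics$n_sub)
  x$initial_concentrations <- as.numeric(x$initial_concentrations)
  if (!is.null(x$options$max_N) && x$options$max_N < 0) x$options$max_N <- Inf
  validate_config(structure(x, class = "sim_config"))
}

#' Load a shipped preset configuration
#'
#' @param preset `"normal"` or `"cancer"`.
#' @return A validated `sim_config`.
#' @export
preset_config <- function(preset = c("normal", "cancer")) {
  preset <- match.arg(preset)
  path <- system.file("presets", paste0(preset, ".yaml"), package = "hipposim",
                      mustWork = TRUE)
  read_config(path)
}

## ---- randomness ------------------------------------------------------------

#' Create a reproducible random stream
#'
#' Wraps R's Mersenne-Twister generator in a self-contained stream object so
#' that simulations are bit-reproducible for a given seed and independent of
#' the caller's global RNG state.
#'
#' @param seed Integer seed.
#' @return An object of class `sim_rng` with a `$unif(n, min, max)` closure.
#' @export
#' @examples
#' r <- make_rng(1)
#' r$unif(3, 0, 2 * pi)
make_rng <- function(seed) {
  state <- local({
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    s
  })
  env <- new.env(parent = emptyenv())
  env$state <- state
  unif <- function(n = 1, min = 0, max = 1) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    x <- stats::runif(n, min, max)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    x
  }
  structure(list(unif = unif, seed = as.integer(seed)), class = "sim_rng")
}

#' Draw a random division direction
#'
#' Samples the azimuthal angle theta uniformly on `[0, 2*pi)` and the polar
#' angle phi uniformly on `[0, pi)`, and returns the radial unit vector
#' `(sin(phi) cos(theta), sin(phi) sin(theta), cos(phi))`. Note that uniform
#' phi is the model's stated convention and is not area-uniform on the
#' sphere; set `sphere_uniform = TRUE` for cos-weighted sampling.
#'
#' @param rng A `sim_rng` stream from [make_rng()].
#' @param sphere_uniform Use area-uniform sampling instead of uniform phi.
#' @return A list with `e_r` (unit 3-vector), `theta` and `phi`.
#' @export
draw_direction <- function(rng, sphere_uniform = FALSE) {
  theta <- rng$unif(1, 0, 2 * pi)
  phi <- if (sphere_uniform) acos(1 - 2 * rng$unif(1)) else rng$unif(1, 0, pi)
  e_r <- c(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  list(e_r = e_r, theta = theta, phi = phi)
}
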