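## The end-to-end simulation loop: two-cell initialization and, per global
## step, (2) classification + growth, (3) division, (4) mechanics,
## (5) density update + reaction propagation.

#' Initialize a two-cell population
#'
#' Places two birth-size daughters symmetrically about the origin at
#' `-/+ gamma sigma0' e_r` with separation velocities
#' `-/+ (1 - gamma) sigma0' e_r / T_M` along one random direction, ages 0 and
#' the preset's initial concentrations.
#'
#' @param cfg A `sim_config` from [default_config()], [preset_config()] or
#'   [read_config()].
#' @param rng A `sim_rng`; defaults to a stream seeded from `cfg$seed`.
#' @return A `cell_population` with N = 2 at t = 0.
#' @export
initialize_population <- function(cfg, rng = make_rng(cfg$seed)) {
  m <- cfg$mechanics
  dir <- draw_direction(rng, cfg$options$sphere_uniform)
  offset <- m$gamma * m$sigma0_prime * dir$e_r
  vsep <- (1 - m$gamma) * m$sigma0_prime * dir$e_r / cfg$cycle$T_M
  X0 <- rbind(cfg$initial_concentrations, cfg$initial_concentrations)
  pop <- new_population(
    id = 1:2,
    pos = rbind(-offset, offset), vel = rbind(-vsep, vsep),
    sigma = rep(m$sigma0, 2), age = c(0, 0), color = c(1L, 1L),
    X = X0, rho = c(0, 0), t = 0, step = 0L)
  pop$rho <- packing_fraction(pop, m, cfg$density$delta_rho,
                              method = cfg$options$neighbor)
  pop
}

#' Advance a population by one global step
#'
#' Applies, in order: growth/arrest discrimination and growth, division of
#' size-threshold cells, `n_sub` velocity-Verlet substeps of the mechanics,
#' then a packing-fraction update followed by exact linear propagation of
#' every cell's reaction system at its (frozen) density.
#'
#' @param pop A `cell_population`.
#' @param cfg A `sim_config`.
#' @param rng A `sim_rng` (consumed by division-direction draws).
#' @param cache Optional propagator cache from across steps (an environment);
#'   created by [run_simulation()].
#' @return The advanced population (step + 1, t = step * dt).
#' @export
sim_step <- function(pop, cfg, rng, cache = NULL) {
  m <- cfg$mechanics
  pop <- grow_step(pop, cfg$reaction, cfg$cycle, m)
  pop <- divide_ready(pop, rng, m, cfg$cycle, cfg$options$sphere_uniform)
  pop <- verlet_step(pop, m, method = cfg$options$neighbor)
  pop$rho <- packing_fraction(pop, m, cfg$density$delta_rho,
                              method = cfg$options$neighbor)
  pop$X <- propagate_population(pop$X, pop$rho, m$dt, cfg$reaction,
                                rho_grid = cfg$density$rho_grid,
                                cache = cache)
  pop$step <- pop$step + 1L
  pop$t <- pop$step * m$dt
  pop
}

## One summary row (time, count, X2/X3 extrema and mean, per-color counts).
record_row <- function(pop) {
  counts <- tabulate(pop$color + 1L, nbins = 4L)
  data.frame(t = pop$t, N = n_cells(pop),
             X2_max = max(pop$X[, 2]), X2_mean = mean(pop$X[, 2]),
             X2_min = min(pop$X[, 2]),
             X3_max = max(pop$X[, 3]), X3_mean = mean(pop$X[, 3]),
             X3_min = min(pop$X[, 3]),
             n_cyan = counts[1], n_orange = counts[2],
             n_blue = counts[3], n_red = counts[4])
}

#' Run a full simulation
#'
#' Executes `cfg$L` global steps from the two-cell initial state, recording a
#' population summary (cell count, nuclear and phospho-YAP/TAZ extrema and
#' means, per-color counts) at step 0 and every `cfg$snapshot_every` steps.
#'
#' @param cfg A `sim_config`.
#' @param keep_snapshots If `TRUE`, full per-cell snapshots are kept at every
#'   recorded step (memory permitting) under `$snapshots`.
#' @return An object of class `sim_result`: list with `timeseries` (one row
#'   per record), `final` (the final `cell_population`), `config`, `seed`
#'   and optionally `snapshots`.
#' @export
#' @examples
#' cfg <- default_config("normal", L = 200, snapshot_every = 100)
#' res <- run_simulation(cfg)
#' res$timeseries
run_simulation <- function(cfg, keep_snapshots = FALSE) {
  cfg <- validate_config(cfg)
  rng <- make_rng(cfg$seed)
  cache <- new_propagator_cache()
  pop <- initialize_population(cfg, rng)
  n_rec <- cfg$L %/% cfg$snapshot_every + 1L
  records <- vector("list", n_rec)
  snapshots <- if (keep_snapshots) vector("list", n_rec) else NULL
  rec <- 1L
  records[[rec]] <- record_row(pop)
  if (keep_snapshots) snapshots[[rec]] <- pop
  if (cfg$L >= 1L) {
    for (k in seq_len(cfg$L)) {
      pop <- tryCatch(sim_step(pop, cfg, rng, cache),
                      error = function(e) stop("at step ", k, ": ",
                                               conditionMessage(e),
                                               call. = FALSE))
      if (k %% cfg$snapshot_every == 0L) {
        rec <- rec + 1L
        records[[rec]] <- record_row(pop)
        if (keep_snapshots) snapshots[[rec]] <- pop
      }
      if (n_cells(pop) > cfg$options$max_N)
        stop("cell count ", n_cells(pop), " exceeded the configured max_N ",
             "guard at step ", k, call. = FALSE)
      if (cfg$options$verbose && k %% (cfg$snapshot_every * 10L) == 0L)
        message(sprintf("step %d / %d  t = %.1f h  N = %d",
                        k, cfg$L, pop$t / 3600, n_cells(pop)))
    }
  }
  structure(list(timeseries = do.call(rbind, records[seq_len(rec)]),
                 final = pop, config = cfg, seed = cfg$seed,
                 snapshots = if (keep_snapshots) snapshots[seq_len(rec)]),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result> preset:", x$config$preset, " seed:", x$seed, "\n")
  cat("  final: N =", n_cells(x$final), "at t =",
      format(x$final$t / 3600, digits = 5), "h (",
      nrow(x$timeseries), "records )\n")
  invisible(x)
}

#' Fraction of cells in cell-cycle arrest
#'
#' @param pop A `cell_population`.
#' @return Fraction of cells with color cyan (0) or blue (2), i.e. whose
#'   nuclear YAP/TAZ was at or below threshold at the last classification.
#' @export
arrest_fraction <- function(pop) mean(pop$color %in% c(0L, 2L))
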