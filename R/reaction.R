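## Per-cell Hippo-YAP/TAZ reaction system.
##
## The three species are X1 (cytoplasmic YAP/TAZ), X2 (nuclear YAP/TAZ) and
## X3 (phospho-YAP/TAZ). The system is linear for a fixed packing fraction
## rho, with rate matrix
##
##   A(rho) = [ -a1 - b1 rho X0    a2     a3 ]
##            [        a1         -a2      0 ]
##            [   b1 rho X0         0    -a3 ]
##
## Columns sum to zero, so the total X1 + X2 + X3 is conserved; off-diagonal
## entries are non-negative (Metzler structure), so non-negative states stay
## non-negative under propagation.

#' Time derivative of the per-cell YAP/TAZ concentrations
#'
#' @param X Numeric 3-vector `(X1, X2, X3)` in uM, componentwise >= 0.
#' @param rho Local packing fraction (dimensionless, >= 0).
#' @param p A [reaction_params()] object.
#' @return The derivative 3-vector `(dX1, dX2, dX3)/dt` in uM/s; its
#'   components sum to zero.
#' @export
#' @examples
#' reaction_rhs(c(0.05, 0.2, 0), rho = 1, reaction_params())
reaction_rhs <- function(X, rho, p) {
  if (rho < 0) stop("packing fraction rho cannot be negative")
  k <- p$b1 * rho * p$X0
  c(-p$a1 * X[1] + p$a2 * X[2] + p$a3 * X[3] - k * X[1],
    p$a1 * X[1] - p$a2 * X[2],
    -p$a3 * X[3] + k * X[1])
}

#' Rate matrix of the reaction system at a given density
#'
#' @inheritParams reaction_rhs
#' @return A 3x3 matrix `A` with `reaction_rhs(X, rho, p) == A %*% X`,
#'   zero column sums and non-negative off-diagonal entries, with
#'   attribute `rho`.
#' @export
rate_matrix <- function(rho, p) {
  if (rho < 0) stop("packing fraction rho cannot be negative")
  k <- p$b1 * rho * p$X0
  A <- matrix(c(-p$a1 - k, p$a1, k,
                p$a2, -p$a2, 0,
                p$a3, 0, -p$a3), nrow = 3, ncol = 3)
  attr(A, "rho") <- rho
  A
}

## exp(A dt) via eigendecomposition; falls back to Pade scaling-and-squaring
## (Matrix::expm) when the eigenbasis is ill-conditioned.
propagator_matrix <- function(rho, dt, p, cond_limit = 1e8) {
  A <- rate_matrix(rho, p)
  e <- tryCatch(eigen(A * dt), error = function(err) NULL)
  if (!is.null(e)) {
    V <- e$vectors
    Vi <- tryCatch(solve(V), error = function(err) NULL)
    if (!is.null(Vi)) {
      cond <- norm(V, "2") * norm(Vi, "2")
      if (is.finite(cond) && cond <= cond_limit) {
        P <- V %*% (exp(e$values) * Vi)
        return(Re(P))
      }
    }
  }
  as.matrix(Matrix::expm(Matrix::Matrix(A * dt)))
}

#' Propagate the reaction system exactly over one step
#'
#' Advances `X` by `exp(A(rho) * dt) %*% X`, the exact solution of the linear
#' reaction system at frozen density. The matrix exponential is computed from
#' the eigendecomposition of the rate matrix; if the eigenbasis condition
#' number exceeds `1e8` the computation falls back to Pade
#' scaling-and-squaring.
#'
#' @inheritParams reaction_rhs
#' @param dt Time step (s), >= 0.
#' @return The propagated non-negative 3-vector; `sum(X)` is preserved.
#' @export
#' @examples
#' propagate(c(0.05, 0.2, 0), rho = 1, dt = 3.75, reaction_params())
propagate <- function(X, rho, dt, p) {
  if (!all(is.finite(X))) stop("non-finite concentrations")
  if (dt < 0) stop("dt must be >= 0")
  if (dt == 0) return(X)
  out <- drop(propagator_matrix(rho, dt, p) %*% X)
  pmax(out, 0)
}

#' Analytic steady state of the reaction system
#'
#' For fixed density rho the unique steady state with conserved total
#' `X1 + X2 + X3 = total` is
#' \deqn{X_1^* = total / (1 + a_1/a_2 + b_1 \rho X_0 / a_3),\quad
#'       X_2^* = (a_1/a_2) X_1^*,\quad X_3^* = (b_1 \rho X_0 / a_3) X_1^*.}
#'
#' @inheritParams reaction_rhs
#' @param total Conserved total concentration (uM), > 0.
#' @return A list of class `steady_state` with `X1`, `X2`, `X3`, `rho`,
#'   `total`.
#' @export
steady_state <- function(rho, total, p) {
  if (rho < 0) stop("packing fraction rho cannot be negative")
  if (total <= 0) stop("total concentration must be positive")
  r12 <- p$a1 / p$a2
  r13 <- p$b1 * rho * p$X0 / p$a3
  X1 <- total / (1 + r12 + r13)
  structure(list(X1 = X1, X2 = r12 * X1, X3 = r13 * X1,
                 rho = rho, total = total), class = "steady_state")
}

#' Critical packing fraction for cell-cycle arrest
#'
#' The steady-state nuclear YAP/TAZ `X2*` decreases monotonically with
#' density; this returns the unique density at which it equals the arrest
#' threshold `X_th`. Tissue denser than this arrests at steady state.
#'
#' @param total Conserved total concentration (uM); must exceed
#'   `X_th * (1 + a2/a1)` for a non-negative solution to exist.
#' @param p A [reaction_params()] object.
#' @return The critical packing fraction (dimensionless).
#' @export
#' @examples
#' critical_density(total = 0.25, reaction_params())  # normal preset
#' critical_density(total = 0.5, reaction_params())   # cancer preset
critical_density <- function(total, p) {
  r12 <- p$a1 / p$a2
  if (total <= p$X_th * (1 + 1 / r12) * (1 + 1e-15))
    stop("total concentration too small: steady-state X2 cannot reach X_th ",
         "at any non-negative density")
  (p$a3 / (p$b1 * p$X0)) * (total * r12 / p$X_th - 1 - r12)
}

## ---- cached propagation over a population ---------------------------------

## Propagators are cached on a quantized rho grid (A depends on rho only),
## so each global step costs one 3x3 matrix product per cell instead of one
## eigendecomposition per cell.
new_propagator_cache <- function() new.env(parent = emptyenv(), size = 1024L)

#' Propagate every cell's concentrations over one global step
#'
#' Vectorized, cached version of [propagate()]: densities are quantized on a
#' grid (`cfg$density$rho_grid`, default 1e-3), one propagator is built per
#' distinct quantized density and applied to all cells sharing it.
#'
#' @param X N x 3 matrix of concentrations (uM).
#' @param rho Length-N vector of packing fractions.
#' @param dt Time step (s).
#' @param p A [reaction_params()] object.
#' @param rho_grid Quantization width for the cache (0 disables quantization).
#' @param cache Environment from `new_propagator_cache()`, or `NULL` for no
#'   caching across calls.
#' @return The propagated N x 3 concentration matrix.
#' @export
propagate_population <- function(X, rho, dt, p, rho_grid = 1e-3,
                                 cache = NULL) {
  if (rho_grid > 0) rho <- round(rho / rho_grid) * rho_grid
  groups <- split(seq_along(rho), rho)
  for (key in names(groups)) {
    idx <- groups[[key]]
    P <- if (!is.null(cache) && !is.null(cache[[key]])) {
      cache[[key]]
    } else {
      Pm <- propagator_matrix(rho[idx[1]], dt, p)
      if (!is.null(cache)) cache[[key]] <- Pm
      Pm
    }
    X[idx, ] <- X[idx, , drop = FALSE] %*% t(P)
  }
  pmax(X, 0)
}
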