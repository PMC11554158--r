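## Non-normative figure helpers (require ggplot2; nothing in the model or
## tests depends on these).

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
}

#' Plot growth curves with the doubling-law reference
#'
#' Semi-log cell-count trajectories for one or more runs, overlaid with the
#' uncoupled doubling law `2^(1 + floor(t/T_CC))`.
#'
#' @param ... Named timeseries data frames from [run_simulation()].
#' @param T_CC Cell-cycle duration (s) for the reference curve.
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(..., T_CC = 20 * 3600) {
  .need_ggplot()
  runs <- list(...)
  if (is.null(names(runs)) || any(names(runs) == ""))
    names(runs) <- paste0("run", seq_along(runs))
  df <- do.call(rbind, lapply(names(runs), function(nm)
    cbind(growth_curve(runs[[nm]]), run = nm)))
  tref <- seq(0, max(df$t), length.out = 512)
  ref <- data.frame(t = tref, N = reference_curve(tref, T_CC))
  ggplot2::ggplot(df, ggplot2::aes(x = t / 3600, y = N, color = run)) +
    ggplot2::geom_line() +
    ggplot2::geom_step(data = ref, ggplot2::aes(color = NULL),
                       linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "cell count",
                  caption = "dashed: doubling law") +
    ggplot2::theme_minimal()
}

#' Plot the nuclear YAP/TAZ envelope of a run
#'
#' Max/mean/min nuclear YAP/TAZ over time with the arrest threshold.
#'
#' @param records Timeseries data frame from [run_simulation()].
#' @param X_th Arrest threshold (uM).
#' @return A ggplot object.
#' @export
plot_x2_envelope <- function(records, X_th = 0.012) {
  .need_ggplot()
  df <- rbind(
    data.frame(t = records$t, X2 = records$X2_max, stat = "max"),
    data.frame(t = records$t, X2 = records$X2_mean, stat = "mean"),
    data.frame(t = records$t, X2 = records$X2_min, stat = "min"))
  ggplot2::ggplot(df, ggplot2::aes(x = t / 3600, y = X2, color = stat)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = X_th, linetype = "dashed") +
    ggplot2::labs(x = "time (h)", y = "nuclear YAP/TAZ (uM)") +
    ggplot2::theme_minimal()
}

#' Plot a tissue cross-section at x = 0
#'
#' Cells intersecting the x = 0 plane (those with `|x| < radius`) drawn as
#' circles in the y-z plane, colored by cycle state.
#'
#' @param pop A `cell_population`.
#' @param mech A [mechanics_params()] object.
#' @return A ggplot object.
#' @export
plot_cross_section <- function(pop, mech = mechanics_params()) {
  .need_ggplot()
  radius <- cell_radii(pop, mech)
  sel <- abs(pop$pos[, 1]) < radius
  df <- data.frame(y = pop$pos[sel, 2], z = pop$pos[sel, 3],
                   r = sqrt(pmax(radius[sel]^2 - pop$pos[sel, 1]^2, 0)),
                   state = .color_names[pop$color[sel] + 1L])
  ggplot2::ggplot(df, ggplot2::aes(x = y, y = z, size = r, color = state)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_color_manual(values = c(cyan = "cyan", orange = "orange",
                                           blue = "blue", red = "red")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "y (um)", y = "z (um)") +
    ggplot2::theme_minimal()
}
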