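## Plain-text trajectory output: versioned tab-separated snapshots and
## timeseries (round-trip exact), plus extended-XYZ export for 3D viewers.

.snapshot_version <- "hipposim-snapshot v1"
.timeseries_version <- "hipposim-timeseries v1"

## round-trip-safe float formatting
.fmt <- function(x) sprintf("%.17g", x)

.write_versioned_tsv <- function(df, path, version, float_cols) {
  out <- df
  for (nm in float_cols) out[[nm]] <- .fmt(df[[nm]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", version), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_versioned_tsv <- function(path, version) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!identical(first, paste0("# ", version)))
    stop("unsupported schema: expected '# ", version, "' as the first line ",
         "of ", path, " but found '", first, "'")
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  df
}

#' Write a per-cell snapshot
#'
#' Tab-separated table, one row per cell (id, t, position, velocity, sigma,
#' radius, age, color, concentrations, rho) under a schema-version header
#' line. Floats are serialized with round-trip-safe precision so
#' `read_snapshot(write_snapshot(pop))` reproduces the population exactly.
#'
#' @param pop A `cell_population`.
#' @param path Output file path.
#' @param mech A [mechanics_params()] object (for the radius column).
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(pop, path, mech = mechanics_params()) {
  df <- as.data.frame(pop, mech = mech)
  float_cols <- setdiff(names(df), c("id", "color"))
  .write_versioned_tsv(df, path, .snapshot_version, float_cols)
}

#' Read a per-cell snapshot
#'
#' @param path A file written by [write_snapshot()]. Files whose schema
#'   version line does not match are rejected.
#' @return A `cell_population`.
#' @export
read_snapshot <- function(path) {
  df <- .read_versioned_tsv(path, .snapshot_version)
  needed <- c("id", "t", "x", "y", "z", "vx", "vy", "vz", "sigma", "age",
              "color", "X1", "X2", "X3", "rho")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("malformed snapshot ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  new_population(id = df$id, pos = cbind(df$x, df$y, df$z),
                 vel = cbind(df$vx, df$vy, df$vz), sigma = df$sigma,
                 age = df$age, color = df$color,
                 X = cbind(df$X1, df$X2, df$X3), rho = df$rho,
                 t = df$t[1], step = 0L)
}

#' Export a snapshot in extended-XYZ format
#'
#' Standard extended-XYZ layout for 3D structure viewers: first line the cell
#' count, second line a `Properties=...` comment, then one row per cell with
#' the color name as the species label and radius and nuclear YAP/TAZ as
#' auxiliary columns.
#'
#' @inheritParams write_snapshot
#' @return `path`, invisibly.
#' @export
write_xyz <- function(pop, path, mech = mechanics_params()) {
  n <- n_cells(pop)
  lines <- c(
    as.character(n),
    sprintf("Properties=species:S:1:pos:R:3:radius:R:1:X2:R:1 Time=%s",
            .fmt(pop$t)),
    sprintf("%s %.8f %.8f %.8f %.8f %.8g",
            .color_names[pop$color + 1L],
            pop$pos[, 1], pop$pos[, 2], pop$pos[, 3],
            mech$zeta * pop$sigma, pop$X[, 2]))
  writeLines(lines, path)
  invisible(path)
}

#' Write a run timeseries
#'
#' @param records Timeseries data frame from [run_simulation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(records, path) {
  float_cols <- setdiff(names(records),
                        c("N", "n_cyan", "n_orange", "n_blue", "n_red"))
  .write_versioned_tsv(records, path, .timeseries_version, float_cols)
}

#' Read a run timeseries
#'
#' @param path A file written by [write_timeseries()]. Files whose schema
#'   version line does not match are rejected.
#' @return The timeseries data frame.
#' @export
read_timeseries <- function(path) .read_versioned_tsv(path, .timeseries_version)
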