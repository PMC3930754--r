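# Trajectory container shared by all models, plus delimited-table I/O.

#' Construct a trajectory object
#'
#' A trajectory is a time grid plus a state matrix (one column per state
#' variable) and metadata sufficient to identify the run: model id, a hash
#' of the parameter set, the time unit, and per-column unit strings.
#'
#' @param time Numeric vector of times (strictly increasing).
#' @param state Numeric matrix, `length(time)` rows, named columns.
#' @param model Model identifier string (`"smad"`, `"cellular"`, `"tissue"`,
#'   `"bone"`, `"multiscale"`).
#' @param time_unit Unit of the time column.
#' @param units Named character vector of per-column unit strings (optional).
#' @param meta Named list of extra metadata (parameter hash, seed,
#'   integrator settings, ...).
#' @return An object of class `tgfb_trajectory`.
#' @export
trajectory <- function(time, state, model, time_unit = "s", units = NULL,
                       meta = list()) {
  state <- as.matrix(state)
  stopifnot(length(time) == nrow(state), !is.null(colnames(state)))
  if (length(time) > 1 && any(diff(time) <= 0)) {
    stop("trajectory time grid must be strictly increasing")
  }
  structure(list(time = as.numeric(time), state = state, model = model,
                 time_unit = time_unit, units = units, meta = meta),
            class = "tgfb_trajectory")
}

#' @export
print.tgfb_trajectory <- function(x, ...) {
  cat(sprintf("<tgfb_trajectory> model '%s': %d time points in [%g, %g] %s, %d states\n",
              x$model, length(x$time), min(x$time), max(x$time),
              x$time_unit, ncol(x$state)))
  cat("  states:", paste(colnames(x$state), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.tgfb_trajectory <- function(x, ...) {
  data.frame(time = x$time, x$state, check.names = FALSE)
}

#' Interpolate a trajectory at a time point
#'
#' Linear interpolation of every state column at time `t`; errors if `t`
#' lies outside the trajectory span.
#'
#' @param traj A `tgfb_trajectory`.
#' @param t Time at which to evaluate.
#' @return Named numeric vector of state values.
#' @export
trajectory_at <- function(traj, t) {
  if (t < min(traj$time) || t > max(traj$time)) {
    stop(sprintf("time %g outside trajectory span [%g, %g]",
                 t, min(traj$time), max(traj$time)))
  }
  vapply(seq_len(ncol(traj$state)), function(j) {
    approx(traj$time, traj$state[, j], xout = t)$y
  }, numeric(1)) |> setNames(colnames(traj$state))
}

.format_num <- function(x) sprintf("%.17g", x)

#' Write a trajectory as a delimited table
#'
#' Plain-text output: a header row carrying variable names with unit
#' strings (time first), then one row per time point. Numbers are printed
#' with 17 significant digits, so the table round-trips losslessly and
#' write -> read -> write is byte-identical.
#'
#' @param traj A `tgfb_trajectory`.
#' @param path Output file path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @seealso [read_trajectory()]
#' @export
write_trajectory <- function(traj, path, sep = ",") {
  stopifnot(inherits(traj, "tgfb_trajectory"), length(traj$time) >= 1)
  units <- traj$units
  cols <- colnames(traj$state)
  unit_of <- function(nm) {
    if (!is.null(units) && nm %in% names(units)) sprintf("%s [%s]", nm, units[[nm]])
    else nm
  }
  header <- paste(c(sprintf("time [%s]", traj$time_unit),
                    vapply(cols, unit_of, character(1))), collapse = sep)
  body <- apply(cbind(traj$time, traj$state), 1L,
                function(row) paste(.format_num(row), collapse = sep))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, useBytes = TRUE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path File path.
#' @param sep Field separator used at write time.
#' @param model Model identifier to attach (the table itself carries only
#'   variable names and units).
#' @return A `tgfb_trajectory`.
#' @export
read_trajectory <- function(path, sep = ",", model = "unknown") {
  lines <- readLines(path)
  header <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  vals <- do.call(rbind, lapply(lines[-1], function(l) {
    as.numeric(strsplit(l, sep, fixed = TRUE)[[1]])
  }))
  nm <- sub("^\\s*(.*?)\\s*\\[.*\\]\\s*$", "\\1", header)
  has_unit <- grepl("\\[", header)
  un <- ifelse(has_unit, sub("^.*\\[(.*)\\].*$", "\\1", header), NA_character_)
  state <- vals[, -1, drop = FALSE]
  colnames(state) <- nm[-1]
  units <- setNames(un[-1], nm[-1])
  units <- units[!is.na(units)]
  trajectory(vals[, 1], state, model = model,
             time_unit = if (has_unit[1]) un[1] else "s",
             units = if (length(units)) units else NULL)
}

# deterministic hash of a parameter set (md5 of its canonical serialization)
params_hash <- function(params) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  writeLines(write_parameters(params), tmp, useBytes = TRUE)
  unname(tools::md5sum(tmp))
}

#' Build a run manifest
#'
#' A manifest records everything needed to reproduce a run bit-for-bit:
#' model id, the md5 hash of the serialized parameter set, the seed, the
#' integrator settings and the package version.
#'
#' @param model Model identifier.
#' @param params Parameter set used.
#' @param seed Seed used (or `NA` for deterministic runs).
#' @param integrator Named list of integrator settings.
#' @param extra Additional fields to record.
#' @return Named list of class `tgfb_manifest`.
#' @export
run_manifest <- function(model, params, seed = NA_integer_,
                         integrator = list(), extra = list()) {
  m <- c(list(model = model,
              parameters_md5 = params_hash(params),
              seed = seed,
              tool = "tgfbms",
              version = as.character(utils::packageVersion("tgfbms")),
              integrator = integrator),
         extra)
  class(m) <- "tgfb_manifest"
  m
}

#' Write a run manifest as JSON
#'
#' @param manifest A `tgfb_manifest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
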