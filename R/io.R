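# Plain-text I/O: XYZ trajectories, JSONL frame records, YAML run configs.

#' Write an XYZ trajectory
#'
#' Standard multi-frame XYZ: atom count, a comment line, then one
#' `element x y z` line per atom.
#'
#' @param traj frames x atoms x 3 array, or a single n x 3 matrix.
#' @param file Output path.
#' @param elements Element symbol(s), recycled over atoms.
#' @param comment Comment-line prefix; the frame index is appended.
#' @return `file`, invisibly.
#' @export
write_xyz <- function(traj, file, elements = "Ar", comment = "frame") {
  if (is.matrix(traj)) traj <- array(traj, c(1, dim(traj)))
  n_frames <- dim(traj)[1]; n_atoms <- dim(traj)[2]
  el <- rep_len(elements, n_atoms)
  con <- base::file(file, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames)) {
    writeLines(c(as.character(n_atoms), paste(comment, f)), con)
    writeLines(sprintf("%s %.10g %.10g %.10g", el, traj[f, , 1],
                       traj[f, , 2], traj[f, , 3]), con)
  }
  invisible(file)
}

#' Read an XYZ trajectory
#'
#' @param file Path to a (multi-frame) XYZ file.
#' @return List with `traj` (frames x atoms x 3) and `elements`.
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  frames <- list(); elements <- NULL; i <- 1L; f <- 0L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ at line ", i, ": expected atom count")
    if (i + 1L + n > length(lines)) stop("truncated XYZ frame at line ", i)
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    elements <- vapply(rows, `[`, character(1), 1)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    f <- f + 1L
    frames[[f]] <- xyz
    i <- i + 2L + n
  }
  traj <- array(0, c(f, nrow(frames[[1]]), 3))
  for (j in seq_len(f)) traj[j, , ] <- frames[[j]]
  list(traj = traj, elements = elements)
}

#' Write frame records as JSON lines
#'
#' One JSON object per frame (newline-delimited), the portable exchange
#' format for per-frame observables.
#'
#' @param frames Data frame of frame records (an `sg_run`'s `$frames`).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_frames_jsonl <- function(frames, file) {
  con <- base::file(file, "w")
  on.exit(close(con))
  jsonlite::stream_out(frames, con, verbose = FALSE, digits = NA)
  invisible(file)
}

#' Read JSONL frame records
#'
#' @param file Path to a JSONL file written by [write_frames_jsonl()].
#' @return A data frame of frame records.
#' @export
read_frames_jsonl <- function(file) {
  con <- base::file(file, "r")
  on.exit(close(con))
  jsonlite::stream_in(con, verbose = FALSE)
}

#' Read a simulation configuration file
#'
#' YAML with sections `system` (type: sdw | lj | harmonic plus the
#' potential's parameters), `integrator` (dt, n_steps, temperature,
#' record_every, seed, ...), `guiding` (mode, lambda, mu, t_L, t_avg,
#' gamma), and optionally `stages` (a list of \{temperature, lambda, mu\})
#' with `exchange` (interval, cycles, mode) for replica-exchange runs.
#'
#' @param file Path to the YAML config.
#' @return List with `system` (an `sg_system`; for LJ also `positions` and
#'   `velocities`), `config` (an [sg_config()]), and when present `stages`
#'   (a [stage_ladder()]) and `exchange` settings.
#' @export
read_sg_config <- function(file) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading config files requires the 'yaml' package")
  raw <- yaml::read_yaml(file)
  for (sec in c("system", "integrator"))
    if (is.null(raw[[sec]]))
      stop("config '", file, "': missing required section '", sec, "'")
  sysd <- raw$system
  positions <- NULL; velocities <- NULL
  sys <- switch(
    tolower(sysd$type %||na% stop("config: system.type is required")),
    sdw = sdw_system(sdw_params(sysd$a %||na% 1, sysd$b %||na% 0.25,
                                sysd$c %||na% 1000, sysd$y0 %||na% 1),
                     mass = sysd$mass %||na% 39.948),
    harmonic = harmonic_system(sysd$k %||na% 1, mass = sysd$mass %||na% 39.948,
                               n_atoms = sysd$n_atoms %||na% 1),
    lj = {
      eps <- if (!is.null(sysd$epsilon_K)) sysd$epsilon_K * .kB
             else sysd$epsilon %||na% (119.8 * .kB)
      pars <- lj_params(eps, sysd$sigma %||na% 3.405, sysd$cutoff %||na% 10)
      built <- build_argon_system(sysd$n_atoms %||na% 500,
                                  sysd$box %||na% 28.53,
                                  raw$integrator$temperature %||na% 100,
                                  params = pars,
                                  mass = sysd$mass %||na% 39.948)
      positions <- built$positions; velocities <- built$velocities
      built$system
    },
    stop("config: unknown system.type '", sysd$type, "'"))
  gd <- raw$guiding %||na% list()
  guiding <- guiding_params(gd$mode %||na% "LD", gd$lambda %||na% 0,
                            gd$mu %||na% 0, gd$t_L %||na% 0.2,
                            gd$t_avg %||na% (10 * (gd$t_L %||na% 0.2)),
                            gd$gamma)
  it <- raw$integrator
  config <- sg_config(n_steps = it$n_steps %||na% 1000,
                      dt = it$dt %||na% 0.001,
                      temperature = it$temperature %||na% 300,
                      guiding = guiding, seed = it$seed,
                      record_every = it$record_every %||na% 10,
                      record_positions = isTRUE(it$record_positions),
                      record_velocities = isTRUE(it$record_velocities),
                      eta = !isFALSE(it$eta))
  out <- list(system = sys, config = config, positions = positions,
              velocities = velocities)
  if (!is.null(raw$stages)) {
    st <- raw$stages
    out$stages <- stage_ladder(
      vapply(st, function(s) s$temperature %||na% config$temperature,
             numeric(1)),
      vapply(st, function(s) s$lambda %||na% 0, numeric(1)),
      vapply(st, function(s) s$mu %||na% 0, numeric(1)))
    ex <- raw$exchange %||na% list()
    out$exchange <- list(interval = ex$interval %||na% 1000,
                         cycles = ex$cycles %||na% 10,
                         mode = ex$mode %||na% "generalized")
  }
  out
}

`%||na%` <- function(a, b) if (is.null(a)) b else a
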