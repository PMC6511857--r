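## Configuration and data I/O.  Config files are YAML with three tables —
## params, protocol, solver — validated fail-closed: any unknown section or
## key is an error naming the offender, so a typo in a 25+-parameter model
## cannot silently fall back to a default.

#' Parse a latch configuration file
#'
#' @param path YAML file with optional sections \code{params} (any
#'   \linkS4class{LatchParams} field), \code{protocol} (\code{starts},
#'   \code{durations}, \code{horizon}, optional \code{inducer}) and
#'   \code{solver} (\code{rtol}, \code{atol}).  Omitted keys take the
#'   package defaults; unknown keys are rejected.
#' @return list with validated \code{params}, \code{protocol} and
#'   \code{solver} elements.
#' @examples
#' cfg <- parseLatchConfig(system.file("extdata", "latch-default.yaml",
#'                                     package = "latchSim"))
#' @export
parseLatchConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  bad <- setdiff(names(cfg), c("params", "protocol", "solver"))
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "))

  params <- do.call(latchParams, as.list(cfg$params))

  prot <- cfg$protocol
  if (is.null(prot)) {
    protocol <- pulseProtocol(0.5, 0.2, horizon = 24)
  } else {
    badk <- setdiff(names(prot), c("starts", "durations", "horizon", "inducer"))
    if (length(badk))
      stop("unknown protocol key(s): ", paste(badk, collapse = ", "))
    if (is.null(prot$horizon)) stop("protocol requires 'horizon'")
    protocol <- pulseProtocol(
      starts = if (is.null(prot$starts)) numeric(0) else unlist(prot$starts),
      durations = if (is.null(prot$durations)) numeric(0)
                  else unlist(prot$durations),
      horizon = prot$horizon,
      inducer = if (is.null(prot$inducer)) "ara" else prot$inducer)
  }

  solver <- list(rtol = 1e-8, atol = 1e-10)
  if (!is.null(cfg$solver)) {
    badk <- setdiff(names(cfg$solver), names(solver))
    if (length(badk))
      stop("unknown solver key(s): ", paste(badk, collapse = ", "))
    solver[names(cfg$solver)] <- cfg$solver
    for (k in names(solver)) assertScalar(solver[[k]], paste0("solver$", k))
  }
  list(params = params, protocol = protocol, solver = solver)
}

#' Serialise a configuration back to YAML
#'
#' Inverse of \code{\link{parseLatchConfig}}: writing then re-parsing yields
#' equal objects.
#'
#' @param config list as returned by \code{\link{parseLatchConfig}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeLatchConfig <- function(config, path) {
  p <- config$params
  fields <- setNames(lapply(slotNames(p), function(s) slot(p, s)),
                     slotNames(p))
  prot <- config$protocol
  out <- list(
    params = fields,
    protocol = list(starts = prot@pulses$start,
                    durations = prot@pulses$duration,
                    horizon = prot@horizon,
                    inducer = unique(prot@pulses$inducer)),
    solver = config$solver)
  if (!length(out$protocol$inducer)) out$protocol$inducer <- "ara"
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a trajectory as tidy CSV
#'
#' Writes two files: \code{<stem>_species.csv} (columns time_h, species,
#' value — one row per species per time point) and \code{<stem>_summary.csv}
#' (time_h, fraction_lr).
#'
#' @param traj a \linkS4class{LatchTrajectory}.
#' @param stem output path stem (no extension).
#' @param digits significant digits (default 12, lossless round-trip).
#' @return the two file paths, invisibly.
#' @export
writeTrajectory <- function(traj, stem, digits = 12) {
  stopifnot(is(traj, "LatchTrajectory"))
  st <- traj@states
  tidy <- data.frame(
    time_h = rep(traj@times, times = ncol(st)),
    species = rep(colnames(st), each = nrow(st)),
    value = signif(as.vector(st), digits))
  f1 <- paste0(stem, "_species.csv")
  f2 <- paste0(stem, "_summary.csv")
  write.csv(tidy, f1, row.names = FALSE)
  write.csv(data.frame(time_h = traj@times,
                       fraction_lr = signif(fractionLR(traj), digits)),
            f2, row.names = FALSE)
  invisible(c(f1, f2))
}

#' Write a time course as CSV
#'
#' Schema: \code{time_h, fraction_lr, protocol_id}.
#'
#' @param data a \linkS4class{TimeCourseData}.
#' @param path output file.
#' @param protocol_id identifier written in the third column.
#' @return \code{path}, invisibly.
#' @export
writeTimecourse <- function(data, path, protocol_id = "p1") {
  stopifnot(is(data, "TimeCourseData"))
  write.csv(data.frame(time_h = data@times,
                       fraction_lr = signif(data@fraction_lr, 12),
                       protocol_id = protocol_id),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a fraction-LR time course from CSV
#'
#' Validates the schema (\code{time_h, fraction_lr, protocol_id}), strictly
#' increasing times within each protocol and fraction bounds, reporting the
#' offending row on failure.
#'
#' @param path CSV file.
#' @param protocol optional \linkS4class{PulseProtocol} to attach; defaults
#'   to a single 12-min pulse covering the observed time range.
#' @param init_state,noise_sd stored on the returned object.
#' @return a \linkS4class{TimeCourseData} (the first protocol_id in the
#'   file), or a named list of them if several protocol_ids are present.
#' @export
readTimecourse <- function(path, protocol = NULL, init_state = "PB",
                           noise_sd = 0.03) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty time-course file: ", path)
  need <- c("time_h", "fraction_lr")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$protocol_id)) df$protocol_id <- "p1"
  bad <- which(!is.finite(df$time_h) | !is.finite(df$fraction_lr) |
                 df$fraction_lr < 0 | df$fraction_lr > 1)
  if (length(bad))
    stop("invalid time or fraction at row ", bad[1L])
  out <- lapply(split(df, df$protocol_id), function(d) {
    dt <- diff(d$time_h)
    if (any(dt <= 0))
      stop("time_h not strictly increasing at row ",
           which(dt <= 0)[1L] + 1L, " of protocol '", d$protocol_id[1L], "'")
    pp <- if (is.null(protocol))
      pulseProtocol(0.5, 0.2, horizon = max(d$time_h) + 1) else protocol
    timeCourseData(d$time_h, d$fraction_lr, pp, init_state = init_state,
                   noise_sd = noise_sd)
  })
  if (length(out) == 1L) out[[1L]] else out
}

#' Build and write a run manifest
#'
#' Every stochastic output file of the CLI is referenced by a manifest that
#' records the command, config hash, seeds, package version, timestamp and
#' output list, so any file can be traced back to its seed.
#'
#' @param command character command line or description.
#' @param seeds named or unnamed integer seeds used.
#' @param outputs character vector of files written.
#' @param config_path optional config file to hash (md5 of contents).
#' @return manifest list.
#' @export
runManifest <- function(command, seeds, outputs, config_path = NULL) {
  list(command = command,
       config_md5 = if (!is.null(config_path) && file.exists(config_path))
         unname(tools::md5sum(config_path)) else NA_character_,
       seeds = as.list(seeds),
       package_version = as.character(packageVersion("latchSim")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       outputs = as.character(outputs))
}

#' @rdname runManifest
#' @param manifest manifest list from \code{runManifest}.
#' @param path output JSON file.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
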