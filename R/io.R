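#' Write a trajectory in extended XYZ format
#'
#' One frame per sampled configuration: the first line holds the particle
#' count, the comment line carries `time=`, `box=` and `energy=` fields, and
#' each atom line gives the species label and x, y, z (written with 12
#' significant digits so a round trip preserves values to 1e-9).
#'
#' @param run A `cg_run` with recorded frames, or a `cg_system` (single
#'   frame).
#' @param file Output path.
#' @param energies Optional per-frame total energies for the comment line.
#' @return Invisibly, the path.
#' @export
write_xyz <- function(run, file, energies = NULL) {
  if (inherits(run, "cg_system")) {
    frames <- array(run$pos, c(nrow(run$pos), 3, 1))
    times <- run$time
    labels <- names(run$species)[run$species_index]
    box <- run$box
  } else {
    if (is.null(run$frames)) abort("run has no recorded frames")
    frames <- run$frames
    times <- run$frame_times
    labels <- names(run$state$species)[run$state$species_index]
    box <- run$state$box
  }
  con <- file(file, "w")
  on.exit(close(con))
  n <- dim(frames)[1]
  for (f in seq_len(dim(frames)[3])) {
    e <- if (!is.null(energies)) energies[f] else NA
    writeLines(as.character(n), con)
    writeLines(sprintf("time=%.12g box=%.12g,%.12g,%.12g energy=%.12g",
                       times[f], box$lx, box$ly, box$lz, e), con)
    writeLines(sprintf("%s %.12g %.12g %.12g", labels,
                       frames[, 1, f], frames[, 2, f], frames[, 3, f]), con)
  }
  invisible(file)
}

#' Read an extended XYZ trajectory
#'
#' @param file Path written by [write_xyz()].
#' @return A list with `frames` (N x 3 x nframes array), `times`, `box`
#'   (numeric length 3), `labels`, `energies`.
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  frames <- list(); times <- c(); energies <- c(); labels <- NULL; box <- NULL
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    meta <- lines[i + 1]
    gv <- function(key) {
      m <- regmatches(meta, regexec(paste0(key, "=([^ ]+)"), meta))[[1]]
      if (length(m) < 2) NA else m[2]
    }
    times <- c(times, as.numeric(gv("time")))
    energies <- c(energies, as.numeric(gv("energy")))
    if (is.null(box)) box <- as.numeric(strsplit(gv("box"), ",")[[1]])
    rows <- strsplit(lines[i + 1 + seq_len(n)], " +")
    if (is.null(labels)) labels <- vapply(rows, `[[`, character(1), 1)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <- xyz
    i <- i + 2 + n
  }
  arr <- array(unlist(frames), c(nrow(frames[[1]]), 3, length(frames)))
  list(frames = arr, times = times, box = box, labels = labels,
       energies = energies)
}

#' Read an experiment configuration file
#'
#' Structured key-value (YAML) configuration with a mandatory `units`
#' section declaring the reduced-unit system; unknown keys are hard errors.
#'
#' @param path Path to a YAML config file. Top-level keys: `units` (must
#'   declare `energy: eps0`, `length: sigma_R`, `time: tau`) and
#'   `experiment` (fields of [experiment_spec()]; a `linker` sub-map with
#'   `n_monomers`, `monomer_size`, `persistence_length` builds the linker).
#' @return A `cg_experiment`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed_top <- c("units", "experiment")
  extra <- setdiff(names(cfg), allowed_top)
  if (length(extra))
    abort(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  u <- cfg$units
  if (is.null(u) || !identical(u$energy, "eps0") ||
      !identical(u$length, "sigma_R") || !identical(u$time, "tau"))
    abort("config must declare units: {energy: eps0, length: sigma_R, time: tau}")
  ex <- cfg$experiment
  if (is.null(ex)) abort("config must contain an `experiment` section")
  if (!is.null(ex$linker)) {
    lk <- ex$linker
    bad <- setdiff(names(lk), c("n_monomers", "monomer_size",
                                "persistence_length"))
    if (length(bad))
      abort(sprintf("unknown linker key(s): %s", paste(bad, collapse = ", ")))
    ex$linker <- linker_spec(lk$n_monomers, lk$monomer_size,
                             lk$persistence_length)
  }
  allowed <- names(formals(experiment_spec))
  extra <- setdiff(names(ex), allowed)
  if (length(extra))
    abort(sprintf("unknown experiment key(s): %s", paste(extra, collapse = ", ")))
  do.call(experiment_spec, ex)
}

#' Run manifest
#'
#' JSON manifest for a finished experiment: configuration snapshot, package
#' version, per-replicate seeds, wall-clock bounds and an inventory of
#' output files with md5 checksums, sufficient to reproduce the run.
#'
#' @param spec The `cg_experiment` that was run.
#' @param outputs Character vector of output file paths.
#' @param path Where to write the manifest JSON.
#' @param started,finished POSIXct timestamps.
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(spec, outputs, path, started = Sys.time(),
                           finished = Sys.time()) {
  man <- list(
    package = "cgligand",
    version = as.character(utils::packageVersion("cgligand")),
    config = spec[!vapply(spec, is.null, logical(1))],
    seeds = spec$seed + seq_len(spec$n_replicates) - 1,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    outputs = lapply(outputs, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  man$config$linker <- if (!is.null(spec$linker)) unclass(spec$linker)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(man)
}

#' Read a run manifest
#'
#' @param path Manifest JSON path.
#' @param check Verify output checksums against the files next to the
#'   manifest (error on mismatch).
#' @return The manifest list.
#' @export
read_manifest <- function(path, check = TRUE) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (check && length(man$outputs)) {
    dir <- dirname(path)
    for (i in seq_len(nrow(man$outputs))) {
      f <- file.path(dir, man$outputs$file[i])
      if (!file.exists(f)) abort(sprintf("manifest output missing: %s", f))
      if (!identical(unname(tools::md5sum(f)), man$outputs$md5[i]))
        abort(sprintf("checksum mismatch for %s", f))
    }
  }
  man
}

#' Write rate estimates as a results CSV
#'
#' One row per estimate: protocol, parameters, value, stderr, goodness of
#' fit and the seed, in tidy form.
#'
#' @param estimates Named list of `cg_rate` objects.
#' @param spec The experiment.
#' @param file Output CSV path.
#' @return Invisibly, the written tibble.
#' @export
write_results_csv <- function(estimates, spec, file) {
  rows <- dplyr::bind_rows(lapply(names(estimates), function(nm) {
    r <- estimates[[nm]]
    tibble(protocol = spec$protocol, estimate = nm, value = r$value,
           stderr = r$stderr, fit_model = r$fit_model, gof = r$gof,
           epsilon = spec$epsilon %||% NA_real_,
           n_geom = spec$n_geom %||% NA_real_, seed = spec$seed)
  }))
  write.csv(rows, file, row.names = FALSE)
  invisible(rows)
}
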