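#' Load and validate a simulation configuration
#'
#' Reads a JSON configuration, rejects unknown keys, validates values and
#' fills in defaults, returning a fully materialized config list. An empty
#' object `{}` yields the standard defaults for the requested protocol
#' (weights 0.2/0.2, beta 35, x0 0.3, rest 0, decay 0, and the protocol's
#' canonical input level: 2 for timing, 1 for resting activation,
#' `c(1, 9)` for density).
#'
#' @param path path to a JSON file, or a list already parsed.
#' @param simulation protocol number used to pick defaults when the file
#'   does not name one.
#' @return A named list of class `simulation_config` with all defaults
#'   materialized.
#' @export
load_config <- function(path, simulation = 1) {
  cfg <- if (is.list(path)) path else {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(cfg)) cfg <- list()

  allowed <- c("simulation", "input_level", "input_levels", "n_cycles",
               "persistence_mode", "high_rest", "low_rest", "rest_delta",
               "n_neighbors", "shared_slot", "threshold", "params")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sim <- as.integer(cfg$simulation %||% simulation)
  if (!sim %in% 1:3) stop("simulation must be 1, 2 or 3", call. = FALSE)

  par_args <- cfg$params %||% list()
  if (!is.list(par_args)) stop("params must be an object", call. = FALSE)
  bad <- setdiff(names(par_args), names(formals(activation_params)))
  if (length(bad) > 0L) {
    stop("unknown params field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  params <- do.call(activation_params, par_args)

  out <- list(
    simulation = sim,
    input_level = as.numeric(cfg$input_level %||%
                               switch(sim, 2, 1, NA_real_)),
    input_levels = as.numeric(cfg$input_levels %||%
                                if (sim == 3) c(1, 9) else NA_real_),
    n_cycles = as.numeric(cfg$n_cycles %||% 100),
    persistence_mode = as.character(cfg$persistence_mode %||% "cumulative"),
    high_rest = as.numeric(cfg$high_rest %||% 0.7),
    low_rest = as.numeric(cfg$low_rest %||% 0.1),
    rest_delta = as.numeric(cfg$rest_delta %||% 0),
    n_neighbors = as.integer(cfg$n_neighbors %||%
                               if (sim == 3) c(1L, 4L) else 1L),
    shared_slot = as.character(cfg$shared_slot %||% "location"),
    threshold = as.numeric(cfg$threshold %||% 0.5),
    params = params
  )
  if (!out$persistence_mode %in% c("cumulative", "exclusive")) {
    stop("persistence_mode must be 'cumulative' or 'exclusive'",
         call. = FALSE)
  }
  if (!out$shared_slot %in% SLOT_ROLES) {
    stop("shared_slot must be one of ", paste(SLOT_ROLES, collapse = ", "),
         call. = FALSE)
  }
  if (sim != 3 && (!is.finite(out$input_level) || out$input_level <= 0)) {
    stop("input_level must be > 0", call. = FALSE)
  }
  if (sim == 3 && any(!is.finite(out$input_levels) | out$input_levels <= 0)) {
    stop("input_levels must all be > 0", call. = FALSE)
  }
  if (out$n_cycles < 11) stop("n_cycles must exceed the last onset cycle",
                              call. = FALSE)
  class(out) <- c("simulation_config", "list")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a configuration to JSON
#'
#' Round-trips with [load_config()]: `load_config(save_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param config a `simulation_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  obj <- unclass(config)
  obj$params <- unclass(obj$params)
  obj <- obj[!vapply(obj, function(x) !is.list(x) && all(is.na(x)),
                     logical(1))]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Run the protocol described by a configuration
#'
#' @param config a `simulation_config` from [load_config()].
#' @return The protocol's summary data frame.
#' @export
run_config <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  switch(config$simulation,
    run_simulation_1(input_level = config$input_level,
                     n_cycles = config$n_cycles, params = config$params,
                     mode = config$persistence_mode,
                     threshold = config$threshold),
    run_simulation_2(input_level = config$input_level,
                     high_rest = config$high_rest,
                     low_rest = config$low_rest,
                     rest_delta = config$rest_delta,
                     n_cycles = config$n_cycles, params = config$params,
                     threshold = config$threshold),
    run_simulation_3(input_levels = config$input_levels,
                     n_neighbors = config$n_neighbors,
                     shared_slot = config$shared_slot,
                     n_cycles = config$n_cycles, params = config$params,
                     threshold = config$threshold)
  )
}

#' Write a trajectory to CSV
#'
#' One row per unit per cycle, with columns
#' `simulation,condition,cycle,unit_id,layer,role,activation`; activations
#' are printed with 15 significant digits.
#'
#' @param trajectory a `sign_trajectory`.
#' @param path output path.
#' @param simulation,condition labels recorded in the first two columns.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path, simulation = "",
                                 condition = "") {
  act <- trajectory$activation
  units <- trajectory$units
  n_cyc <- nrow(act)
  d <- data.frame(
    simulation = simulation,
    condition = condition,
    cycle = rep(0:(n_cyc - 1L), times = ncol(act)),
    unit_id = rep(colnames(act), each = n_cyc),
    layer = rep(units$layer[match(colnames(act), units$id)], each = n_cyc),
    role = rep(units$role[match(colnames(act), units$id)], each = n_cyc),
    activation = sprintf("%.15g", as.numeric(act)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reproduce the three canonical simulations
#'
#' Runs all three protocols at their standard settings, writes per-run
#' trajectory CSVs, a combined summary CSV and a JSON manifest to
#' `out_dir`, and checks the expected qualitative pattern: timing
#' (inhibitory, facilitatory), resting activation (inhibitory,
#' facilitatory), density (facilitatory at low input, inhibitory at high,
#' both densities alike). If any label deviates the function stops with an
#' error after writing its outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param n_cycles trial length used for all protocols.
#' @param params an [activation_params()].
#' @return The combined summary data frame, invisibly.
#' @export
reproduce_all <- function(out_dir, n_cycles = 100,
                          params = activation_params()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir,
                  call. = FALSE)
  }
  if (file.access(out_dir, mode = 2) != 0) {
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  }

  s1 <- run_simulation_1(n_cycles = n_cycles, params = params)
  s2 <- run_simulation_2(n_cycles = n_cycles, params = params)
  s3 <- run_simulation_3(n_cycles = n_cycles, params = params)

  for (nm in names(attr(s1, "trajectories"))) {
    write_trajectory_csv(attr(s1, "trajectories")[[nm]],
                         file.path(out_dir, paste0("timing_", nm, ".csv")),
                         "timing", nm)
  }
  for (nm in names(attr(s2, "trajectories"))) {
    write_trajectory_csv(attr(s2, "trajectories")[[nm]],
                         file.path(out_dir,
                                   paste0("resting_activation_", nm, ".csv")),
                         "resting_activation", nm)
  }

  summary <- rbind(s1, s2, s3)
  utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "signia",
    version = as.character(utils::packageVersion("signia")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_cycles = n_cycles,
    params = unclass(params),
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  expected <- list(
    c("timing", "early_shared", "inhibitory"),
    c("timing", "late_shared", "facilitatory"),
    c("resting_activation", "high_rest_shared", "inhibitory"),
    c("resting_activation", "low_rest_shared", "facilitatory")
  )
  bad <- character()
  for (e in expected) {
    got <- summary$label[summary$simulation == e[1] &
                           summary$condition == e[2]]
    if (!identical(got, e[3])) {
      bad <- c(bad, sprintf("%s/%s: expected %s, got %s",
                            e[1], e[2], e[3], got))
    }
  }
  dens <- summary[summary$simulation == "density", ]
  lo_in <- dens[dens$input_level == min(dens$input_level), ]
  hi_in <- dens[dens$input_level == max(dens$input_level), ]
  if (!all(lo_in$label == "facilitatory")) {
    bad <- c(bad, "density at low input: expected all facilitatory")
  }
  if (!all(hi_in$label == "inhibitory")) {
    bad <- c(bad, "density at high input: expected all inhibitory")
  }
  if (length(bad) > 0L) {
    stop("label pattern check failed:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(summary)
}
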