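# Polynomial rolling hash of a string (32-bit, base 31); used to stamp output
# headers so a trajectory can be traced back to the configuration that
# produced it. Provenance fingerprint, not cryptographic.
fnv1a_hash_ <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%08x", as.integer(h %% 2147483648))
}

config_as_list_ <- function(config) {
  list(
    geometry = list(half_length = config$geometry$half_length,
                    half_width = config$geometry$half_width),
    kinetics = list(v_grow = config$kinetics$v_grow,
                    v_contact = config$kinetics$v_contact,
                    v_shrink = config$kinetics$v_shrink,
                    stall_force = config$kinetics$stall_force,
                    flexural_rigidity = config$kinetics$flexural_rigidity),
    catastrophe = list(
      step_parameter = config$kinetics$catastrophe$step_parameter,
      timescale = config$kinetics$catastrophe$timescale,
      tau0 = config$kinetics$catastrophe$tau0),
    drag = list(viscosity = config$drag$viscosity,
                nucleus_radius = config$drag$nucleus_radius,
                mt_radius = config$drag$mt_radius),
    simulation = list(n_right = config$n_right, n_left = config$n_left,
                      lr_mode = config$lr_mode,
                      theta_spread = config$theta_spread,
                      duration = config$duration, dt = config$dt,
                      burn_in = config$burn_in,
                      record_dt = config$record_dt, seed = config$seed,
                      catastrophe_mode = config$catastrophe_mode))
}

config_hash_ <- function(config) {
  fnv1a_hash_(yaml::as.yaml(config_as_list_(config)))
}

#' Save a simulation configuration to YAML
#'
#' @param config A [sim_config()].
#' @param path Output file.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(config_as_list_(config), path)
  invisible(path)
}

#' Load a simulation configuration from YAML
#'
#' Reads a declarative config with sections `geometry`, `kinetics`,
#' `catastrophe`, `drag` and `simulation` (all keys optional; units are
#' micrometers, seconds and piconewtons, with viscosity in pN s / um^2).
#' Missing keys take the calibrated defaults of [sim_config()]; unknown keys
#' raise an error naming the key. The returned config carries a `provenance`
#' attribute recording which keys were user-supplied.
#'
#' @param path Path to a YAML file; an empty file yields all defaults.
#' @return A [sim_config()].
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- config_as_list_(sim_config())
  for (sec in names(user)) {
    if (!sec %in% names(defaults))
      stop("unknown config section: ", sec)
    for (key in names(user[[sec]])) {
      if (!key %in% names(defaults[[sec]]))
        stop("unknown config key: ", sec, "$", key)
    }
  }
  merged <- modifyList(defaults, user)
  config <- sim_config(
    geometry = cell_geometry(merged$geometry$half_length,
                             merged$geometry$half_width),
    kinetics = kinetic_params(
      v_grow = merged$kinetics$v_grow,
      v_contact = merged$kinetics$v_contact,
      v_shrink = merged$kinetics$v_shrink,
      stall_force = merged$kinetics$stall_force,
      flexural_rigidity = merged$kinetics$flexural_rigidity,
      catastrophe = catastrophe_model(merged$catastrophe$step_parameter,
                                      merged$catastrophe$timescale,
                                      merged$catastrophe$tau0)),
    drag = drag_environment(merged$drag$viscosity,
                            merged$drag$nucleus_radius,
                            merged$drag$mt_radius),
    n_right = merged$simulation$n_right, n_left = merged$simulation$n_left,
    lr_mode = merged$simulation$lr_mode,
    theta_spread = merged$simulation$theta_spread,
    duration = merged$simulation$duration, dt = merged$simulation$dt,
    burn_in = merged$simulation$burn_in,
    record_dt = merged$simulation$record_dt,
    seed = merged$simulation$seed,
    catastrophe_mode = merged$simulation$catastrophe_mode)
  attr(config, "provenance") <- list(
    user = unlist(lapply(names(user), function(s)
      paste(s, names(user[[s]]), sep = "$"))))
  config
}

#' Write a trajectory as tab-separated text
#'
#' Columns `time_s`, `x_um`, `y_um`, `omega_rad`, `spb_x_um`, `spb_y_um`,
#' preceded by comment lines carrying the config hash and seed.
#'
#' @param traj A `centering_trajectory`.
#' @param path Output file.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(is.data.frame(traj))
  cfg <- attr(traj, "config")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# mtcentering trajectory",
               sprintf("# config_hash: %s",
                       if (!is.null(cfg)) config_hash_(cfg) else "none"),
               sprintf("# seed: %s",
                       if (!is.null(cfg)) cfg$seed else "none")), con)
  df <- data.frame(time_s = traj$time, x_um = traj$x,
                   y_um = if ("y" %in% names(traj)) traj$y else 0,
                   omega_rad = if ("omega" %in% names(traj)) traj$omega else 0,
                   spb_x_um = if ("spb_x" %in% names(traj)) traj$spb_x else NA,
                   spb_y_um = if ("spb_y" %in% names(traj)) traj$spb_y else NA)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory file
#'
#' Reads the package's tab-separated trajectory format, or any delimited file
#' with 2-3 columns interpreted as time, x and optionally y.
#'
#' @param path Input file.
#' @return A `centering_trajectory` data frame.
#' @export
read_trajectory <- function(path) {
  df <- read.table(path, header = TRUE, sep = "", comment.char = "#")
  nm <- names(df)
  if (all(c("time_s", "x_um") %in% nm)) {
    traj <- data.frame(time = df$time_s, x = df$x_um, y = df$y_um,
                       omega = df$omega_rad, spb_x = df$spb_x_um,
                       spb_y = df$spb_y_um)
  } else if (ncol(df) >= 2) {
    traj <- data.frame(time = df[[1]], x = df[[2]],
                       y = if (ncol(df) >= 3) df[[3]] else 0)
  } else stop("unrecognized trajectory format: ", path)
  class(traj) <- c("centering_trajectory", "data.frame")
  traj
}

#' Read a catastrophe-time event list
#'
#' One catastrophe time (seconds) per row; optional comment-header keys
#' `min_window` and `max_window` define the observation window.
#'
#' @param path Input file.
#' @return A [catastrophe_dataset()].
#' @export
read_catastrophe_data <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getkey <- function(key) {
    m <- grep(paste0(key, ":"), hdr, value = TRUE)
    if (length(m)) as.numeric(sub(paste0(".*", key, ":\\s*"), "", m[1]))
    else NA_real_
  }
  times <- as.numeric(grep("^[^#]", lines, value = TRUE))
  times <- times[is.finite(times)]
  wmin <- getkey("min_window"); wmax <- getkey("max_window")
  window <- if (is.finite(wmin) && is.finite(wmax)) c(wmin, wmax) else NULL
  catastrophe_dataset(times, window)
}

#' Write a catastrophe-time event list
#'
#' @param data A [catastrophe_dataset()].
#' @param path Output file.
#' @export
write_catastrophe_data <- function(data, path) {
  stopifnot(inherits(data, "catastrophe_dataset"))
  writeLines(c(sprintf("# min_window: %g", data$window[1]),
               sprintf("# max_window: %g", data$window[2]),
               format(data$times, digits = 10, trim = TRUE)), path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration, seed, package version, timestamp and output
#' files of a run as JSON, so any output can be regenerated from its
#' manifest.
#'
#' @param path Manifest file.
#' @param config A [sim_config()].
#' @param outputs Character vector of output paths.
#' @export
write_manifest <- function(path, config, outputs = character()) {
  stopifnot(inherits(config, "sim_config"))
  manifest <- list(package = "mtcentering",
                   version = as.character(packageVersion("mtcentering")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   config_hash = config_hash_(config),
                   seed = config$seed,
                   config = config_as_list_(config),
                   outputs = as.list(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Reproduce the cell-length x microtubule-number maps
#'
#' Runs the sweep over cell lengths and microtubule numbers, writes the mean
#' reliability (`delta`), robustness (`sigma_x`) and failure-coefficient
#' (`Phi`) grids as tab-separated tables plus rendered tile maps, and asserts
#' the qualitative structure: `delta` increases with cell length beyond the
#' wild-type-like 14 um, `sigma_x` and `Phi` decrease with microtubule number
#' at fixed 14 um, and `Phi` attains an interior minimum in cell length at 18
#' microtubules.
#'
#' @param out_dir Output directory (created if needed).
#' @param scale `"desk"` (6 lengths x 5 MT numbers x 20 replicates) or
#'   `"full"` (denser grid, 50 replicates).
#' @param base Base [sim_config()].
#' @return Invisible character vector of files written; errors if a trend
#'   assertion fails.
#' @export
reproduce_fig7_maps <- function(out_dir, scale = c("desk", "full"),
                                base = sim_config()) {
  scale <- match.arg(scale)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lengths <- c(10, 12, 14, 16, 18, 20)
  numbers <- c(6, 10, 14, 18, 22)
  reps <- if (scale == "desk") 20 else 50
  if (scale == "full") {
    lengths <- seq(10, 20, by = 1)
    numbers <- seq(6, 26, by = 2)
  }
  sw <- sweep_centering(base, lengths, numbers, replicates = reps)
  agg <- stats::aggregate(cbind(delta, sigma_x, phi) ~ length + n_mt,
                          data = sw, FUN = mean)

  files <- character()
  for (what in c("delta", "sigma_x", "phi")) {
    grid_file <- file.path(out_dir, paste0(what, "_grid.tsv"))
    write.table(agg[, c("length", "n_mt", what)], grid_file, sep = "\t",
                quote = FALSE, row.names = FALSE)
    map_file <- file.path(out_dir, paste0(what, "_map.pdf"))
    agg$value <- agg[[what]]
    p <- ggplot2::ggplot(agg, ggplot2::aes(x = length, y = n_mt,
                                           fill = value)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c(name = what) +
      ggplot2::labs(x = "cell length (um)", y = "MT number") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(map_file, p, width = 5, height = 4)
    files <- c(files, grid_file, map_file)
  }
  manifest <- file.path(out_dir, "manifest.json")
  write_manifest(manifest, base, files)
  files <- c(files, manifest)

  at18 <- agg[agg$n_mt == 18, ]
  at14 <- agg[agg$length == 14, ]
  beyond <- at18[at18$length >= 14, ]
  problems <- character()
  if (!all(diff(beyond$delta[order(beyond$length)]) > 0))
    problems <- c(problems, "delta not increasing in cell length beyond 14 um")
  if (stats::cor(at14$n_mt, at14$sigma_x, method = "spearman") >= 0)
    problems <- c(problems, "sigma_x not decreasing in MT number")
  if (stats::cor(at14$n_mt, at14$phi, method = "spearman") >= 0)
    problems <- c(problems, "Phi not decreasing in MT number")
  phi18 <- at18$phi[order(at18$length)]
  if (which.min(phi18) %in% c(1L, length(phi18)))
    problems <- c(problems, "Phi minimum not interior in cell length")
  if (length(problems))
    stop("qualitative trend assertions failed:\n  ",
         paste(problems, collapse = "\n  "))
  invisible(files)
}
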