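#' Read an experiment configuration
#'
#' Experiments are configured in a flat YAML file. Recognised keys (all
#' optional unless noted): \code{network} (path to a network JSON),
#' \code{generator} (sub-map passed to \code{\link{generator_spec}}),
#' \code{dataset} (path to a binary CSV to estimate a network from),
#' \code{connectivity} (list, default \code{0.80, 1.10, 2.00}),
#' \code{n_steps} (default 10000), \code{seeds} (list, default 1),
#' \code{b_mode}, \code{stress} (sub-map \code{s_min,s_max,step_size}),
#' \code{bin_width}, \code{ew_window}, \code{out_dir} (required for the
#' commands that write files).
#'
#' @param path YAML file, or a named list already in memory.
#' @return a validated \code{experiment_config} list.
#' @export
read_experiment_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path))
      stop("config file not found: ", path, call. = FALSE)
    yaml::read_yaml(path)
  } else as.list(path)
  defaults <- list(connectivity = c(0.80, 1.10, 2.00), n_steps = 10000,
                   seeds = 1, b_mode = "abs", bin_width = 0.20,
                   ew_window = 100)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  cfg$connectivity <- as.numeric(unlist(cfg$connectivity))
  cfg$seeds <- as.integer(unlist(cfg$seeds))
  if (length(cfg$connectivity) < 1 || any(cfg$connectivity <= 0))
    stop("config needs at least one positive connectivity value",
         call. = FALSE)
  if (is.null(cfg$network) && is.null(cfg$generator) &&
      is.null(cfg$dataset))
    stop("config must name a network source: 'network' (JSON path), ",
         "'generator' (spec), or 'dataset' (CSV to estimate from)",
         call. = FALSE)
  structure(cfg, class = "experiment_config")
}

# Resolve the configured network source into a symptom_network.
resolve_network <- function(cfg) {
  if (!is.null(cfg$network)) return(read_network_json(cfg$network))
  if (!is.null(cfg$generator))
    return(random_network(do.call(generator_spec, cfg$generator)))
  estimate_network(read_binary_dataset(cfg$dataset))
}

write_manifest <- function(out_dir, command, cfg, files) {
  manifest <- list(command = command,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = unclass(cfg), outputs = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

log_msg <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), sprintf(...))
}

#' Run the connectivity-vulnerability simulation experiment
#'
#' For every (connectivity, seed) pair, simulates the stress-free
#' dynamics from the all-off state, writes one trace CSV per run, and a
#' summary table with the mean and maximum state sum and the fraction of
#' time spent fully symptom-free.
#'
#' @param config an \code{experiment_config} (or a path/list accepted by
#'   \code{\link{read_experiment_config}}).
#' @return the summary data frame, invisibly; files land in
#'   \code{config$out_dir}.
#' @export
cmd_simulate <- function(config) {
  cfg <- if (inherits(config, "experiment_config")) config
         else read_experiment_config(config)
  if (is.null(cfg$out_dir)) stop("config needs 'out_dir'", call. = FALSE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- resolve_network(cfg)
  rows <- list(); files <- character(0)
  for (cc in cfg$connectivity) for (sd in cfg$seeds) {
    tr <- simulate_network(net, sim_config(
      connectivity = cc, n_steps = cfg$n_steps, b_mode = cfg$b_mode,
      seed = sd))
    f <- file.path(cfg$out_dir,
                   sprintf("trace_c%.2f_seed%d.csv", cc, sd))
    write_trace_csv(tr, f)
    files <- c(files, f)
    rows[[length(rows) + 1L]] <- data.frame(
      connectivity = cc, seed = sd, mean_D = mean(tr$D),
      max_D = max(tr$D), frac_time_D0 = mean(tr$D == 0))
    log_msg("simulate c=%.2f seed=%d mean_D=%.3f", cc, sd, mean(tr$D))
  }
  summary <- do.call(rbind, rows)
  sf <- file.path(cfg$out_dir, "summary.csv")
  utils::write.csv(summary, sf, row.names = FALSE)
  write_manifest(cfg$out_dir, "simulate", cfg, c(files, sf))
  invisible(summary)
}

#' Run the stress-ramp (hysteresis) experiment
#'
#' For every (connectivity, seed) pair, sweeps the stress ramp, writes
#' the trace, the binned hysteresis curve, and the sliding
#' autocorrelation series, and summarises hysteresis area and the
#' forbidden zone per run.
#'
#' @param config as in \code{\link{cmd_simulate}}; the \code{stress}
#'   sub-map sets \code{s_min}, \code{s_max}, \code{step_size} (defaults
#'   -15, 15, 0.01).
#' @return the summary data frame, invisibly.
#' @export
cmd_stress <- function(config) {
  cfg <- if (inherits(config, "experiment_config")) config
         else read_experiment_config(config)
  if (is.null(cfg$out_dir)) stop("config needs 'out_dir'", call. = FALSE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- resolve_network(cfg)
  st <- cfg$stress
  sch <- make_ramp_schedule(
    s_min = if (is.null(st$s_min)) -15 else st$s_min,
    s_max = if (is.null(st$s_max)) 15 else st$s_max,
    step_size = if (is.null(st$step_size)) 0.01 else st$step_size,
    n_steps = cfg$n_steps)
  rows <- list(); files <- character(0)
  for (cc in cfg$connectivity) for (sd in cfg$seeds) {
    tr <- run_stress_experiment(net, sim_config(
      connectivity = cc, n_steps = cfg$n_steps, b_mode = cfg$b_mode,
      seed = sd), sch)
    curve <- bin_hysteresis_curve(tr, cfg$bin_width)
    ew <- sliding_autocorrelation(tr, window = cfg$ew_window)
    base <- sprintf("c%.2f_seed%d", cc, sd)
    f1 <- file.path(cfg$out_dir, paste0("trace_", base, ".csv"))
    f2 <- file.path(cfg$out_dir, paste0("hysteresis_", base, ".csv"))
    f3 <- file.path(cfg$out_dir, paste0("ew_", base, ".csv"))
    write_trace_csv(tr, f1); write_hysteresis_csv(curve, f2)
    write_ew_csv(ew, f3)
    files <- c(files, f1, f2, f3)
    area <- hysteresis_area(curve)
    fz <- forbidden_zone(tr)
    rows[[length(rows) + 1L]] <- data.frame(
      connectivity = cc, seed = sd, hysteresis_area = area,
      forbidden_lo = if (is.null(fz)) NA_integer_ else fz[1],
      forbidden_hi = if (is.null(fz)) NA_integer_ else fz[2])
    log_msg("stress c=%.2f seed=%d area=%.2f", cc, sd, area)
  }
  summary <- do.call(rbind, rows)
  sf <- file.path(cfg$out_dir, "summary.csv")
  utils::write.csv(summary, sf, row.names = FALSE)
  write_manifest(cfg$out_dir, "stress", cfg, c(files, sf))
  invisible(summary)
}

#' Estimate a network from a dataset file and write it as JSON
#'
#' @param dataset_path CSV of binary data (header = symptom labels).
#' @param out_path output network JSON path.
#' @param config an \code{\link{estimation_config}}.
#' @return the estimated \code{symptom_network}, invisibly.
#' @export
cmd_estimate <- function(dataset_path, out_path,
                         config = estimation_config()) {
  dat <- read_binary_dataset(dataset_path)
  net <- estimate_network(dat, config)
  write_network_json(net, out_path)
  log_msg("estimated %d-node network -> %s", net$J, out_path)
  invisible(net)
}

#' Generate a synthetic network and dataset and write them to disk
#'
#' @param spec a \code{\link{generator_spec}}.
#' @param out_dir output directory; writes \code{network.json} and
#'   \code{dataset.csv} (exact sampler for J <= 20, Gibbs otherwise).
#' @return list with the network and dataset, invisibly.
#' @export
cmd_generate <- function(spec = generator_spec(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- random_network(spec)
  seed2 <- if (is.null(spec$seed)) NULL else spec$seed + 1L
  dat <- if (net$J <= 20) sample_ising_exact(net, spec$N, seed = seed2)
         else sample_ising_gibbs(net, spec$N, seed = seed2)
  write_network_json(net, file.path(out_dir, "network.json"))
  write_binary_dataset(dat, file.path(out_dir, "dataset.csv"))
  write_manifest(out_dir, "generate", unclass(spec),
                 file.path(out_dir, c("network.json", "dataset.csv")))
  invisible(list(network = net, dataset = dat))
}
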