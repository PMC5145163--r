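#' Build a triangular stress-ramp schedule
#'
#' The stress protocol sweeps a scalar stress value, applied identically
#' to every symptom, up from \code{s_min} to \code{s_max} and back down
#' in fixed small increments, repeating until \code{n_steps} values have
#' been emitted (the final cycle may be partial). The canonical sweep is
#' -15 to 15 in steps of 0.01, one full up-down cycle every 6000 steps.
#'
#' @param s_min,s_max sweep range, \code{s_min < s_max}.
#' @param step_size positive increment; must divide \code{s_max - s_min}
#'   to within tolerance.
#' @param n_steps number of schedule values to emit.
#' @return a \code{stress_schedule}: list with \code{values} (length
#'   \code{n_steps}), \code{direction} (\code{"up"}/\code{"down"} per
#'   step), and \code{spec}.
#' @examples
#' sch <- make_ramp_schedule(-15, 15, 0.01, 6000)
#' range(sch$values)
#' @export
make_ramp_schedule <- function(s_min = -15, s_max = 15, step_size = 0.01,
                               n_steps = 10000) {
  if (!is.numeric(step_size) || step_size <= 0)
    stop("`step_size` must be positive", call. = FALSE)
  if (s_min >= s_max)
    stop("`s_min` must be strictly less than `s_max`", call. = FALSE)
  M <- (s_max - s_min) / step_size
  if (abs(M - round(M)) > 1e-8)
    stop("`step_size` must divide s_max - s_min", call. = FALSE)
  M <- round(M)
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1)
    stop("`n_steps` must be >= 1", call. = FALSE)
  period <- 2L * M
  k <- (seq_len(n_steps) - 1L) %% period
  up <- k <= M
  values <- ifelse(up, s_min + step_size * k,
                   s_min + step_size * (period - k))
  direction <- ifelse(up, "up", "down")
  # k = 0 (the trough) is reached by a downward step on every cycle after
  # the first; keep it labelled "up" so each ascent owns its start point.
  structure(list(values = values, direction = direction,
                 spec = list(s_min = s_min, s_max = s_max,
                             step_size = step_size,
                             cycle_length = period)),
            class = "stress_schedule")
}

#' @export
print.stress_schedule <- function(x, ...) {
  cat(sprintf(
    "Stress ramp: [%g, %g] in steps of %g; %d steps (%.2f cycles)\n",
    x$spec$s_min, x$spec$s_max, x$spec$step_size, length(x$values),
    length(x$values) / x$spec$cycle_length))
  invisible(x)
}

#' Run a stress-ramp experiment
#'
#' Simulates the symptom dynamics while the scheduled stress value is
#' added to every symptom's total activation. State is carried
#' continuously across ramp reversals; nothing is reset at a peak or
#' trough, which is what produces hysteresis when the system is bistable.
#'
#' @param net a \code{symptom_network}.
#' @param config a \code{\link{sim_config}} with \code{n_steps} equal to
#'   the schedule length.
#' @param schedule a \code{\link{make_ramp_schedule}} result.
#' @return a \code{sim_trace} carrying the stress column and per-step
#'   direction flags.
#' @export
run_stress_experiment <- function(net, config, schedule) {
  stopifnot(inherits(schedule, "stress_schedule"))
  simulate_network(net, config, schedule)
}

#' Bin a stress trace into an averaged hysteresis curve
#'
#' Because each stress level is visited many times over the sweep, the
#' response is summarised by averaging the state sum D within
#' non-overlapping stress bins of width \code{bin_width} (default 0.20),
#' separately for ascending and descending steps. Bins are half-open
#' intervals anchored at the sweep minimum.
#'
#' @param trace a \code{sim_trace} from \code{run_stress_experiment}.
#' @param bin_width positive bin width on the stress axis.
#' @return a \code{hysteresis_curve}: data frame with columns
#'   \code{bin_center}, \code{mean_D_up}, \code{mean_D_down},
#'   \code{count_up}, \code{count_down}; means are \code{NA} for bins a
#'   direction never visited.
#' @export
bin_hysteresis_curve <- function(trace, bin_width = 0.20) {
  stopifnot(inherits(trace, "sim_trace"))
  if (nrow(trace) == 0) stop("empty trace", call. = FALSE)
  dir <- attr(trace, "direction")
  if (is.null(dir))
    stop("trace has no direction flags; run it through ",
         "run_stress_experiment()", call. = FALSE)
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("`bin_width` must be positive", call. = FALSE)
  s <- trace$stress
  lo <- min(s)
  # half-open bins [lo + k*w, lo + (k+1)*w); tiny epsilon keeps exact
  # multiples of w on their left edge despite float rounding
  idx <- floor((s - lo) / bin_width + 1e-9)
  nb <- max(idx) + 1L
  centers <- lo + (seq_len(nb) - 0.5) * bin_width
  agg <- function(which_dir) {
    sel <- dir == which_dir
    cnt <- tabulate(idx[sel] + 1L, nbins = nb)
    sums <- rep(0, nb)
    if (any(sel)) {
      tb <- tapply(trace$D[sel], idx[sel], sum)
      sums[as.integer(names(tb)) + 1L] <- tb
    }
    list(mean = ifelse(cnt > 0, sums / cnt, NA_real_), count = cnt)
  }
  up <- agg("up"); down <- agg("down")
  structure(data.frame(bin_center = centers,
                       mean_D_up = up$mean, mean_D_down = down$mean,
                       count_up = up$count, count_down = down$count),
            class = c("hysteresis_curve", "data.frame"),
            bin_width = bin_width)
}

#' Hysteresis area of a binned stress-response curve
#'
#' Total absolute gap between the ascending and descending mean-response
#' curves, integrated over the stress bins both directions visited:
#' \code{sum |mean_D_up - mean_D_down| * bin_width}. Zero when the two
#' curves coincide (a memoryless system); large when the system tips up
#' at a higher stress than it tips back down.
#'
#' @param curve a \code{\link{bin_hysteresis_curve}} result.
#' @return non-negative scalar.
#' @export
hysteresis_area <- function(curve) {
  stopifnot(inherits(curve, "hysteresis_curve"))
  w <- attr(curve, "bin_width")
  shared <- !is.na(curve$mean_D_up) & !is.na(curve$mean_D_down)
  if (sum(shared) < 2)
    stop("need both sweep directions in at least 2 shared bins",
         call. = FALSE)
  sum(abs(curve$mean_D_up[shared] - curve$mean_D_down[shared])) * w
}

#' Locate the forbidden zone of a stress experiment
#'
#' In a bistable system the intermediate severity levels between the
#' 'healthy' and 'depressed' attractors are dynamically unstable and
#' almost never observed. This finds the widest contiguous band of D
#' values each occupied for less than \code{dwell_threshold} of all
#' steps, lying strictly between two D levels that exceed the threshold.
#'
#' @param trace a \code{sim_trace}.
#' @param dwell_threshold occupancy fraction below which a D level counts
#'   as unvisited (default 0.005).
#' @return \code{c(lo, hi)} bounding the zone (inclusive), or \code{NULL}
#'   when no interior low-occupancy band exists.
#' @export
forbidden_zone <- function(trace, dwell_threshold = 0.005) {
  stopifnot(inherits(trace, "sim_trace"))
  J <- length(attr(trace, "labels"))
  n <- nrow(trace)
  occ <- tabulate(trace$D + 1L, nbins = J + 1L) / n
  low <- occ < dwell_threshold
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- NULL
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    if (i == 1 || i == length(r$values)) next  # must be interior
    band <- c(starts[i] - 1L, ends[i] - 1L)   # D values, 0-based
    if (is.null(best) || diff(band) > diff(best)) best <- band
  }
  best
}

#' Write a hysteresis curve to CSV
#'
#' @param curve a \code{hysteresis_curve}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_hysteresis_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
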