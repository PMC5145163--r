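#' Sliding-window autocorrelation of the state sum
#'
#' Critical slowing down ahead of a tipping point shows up as rising
#' autocorrelation: near a transition each state closely resembles the
#' previous one. At every step t >= \code{window} this computes the
#' Pearson correlation between the window's D series and its lagged copy,
#' i.e. between \code{D[(t-w+1):(t-lag)]} and \code{D[(t-w+1+lag):t]}.
#' Windows with zero variance in either segment yield \code{NA}
#' (undefined, not zero).
#'
#' @param D integer vector of state sums (or a \code{sim_trace}, whose
#'   \code{D}, \code{t} and \code{stress} columns are used).
#' @param window window length in steps (default 100); must be at least
#'   \code{lag + 2} and no longer than the series.
#' @param lag autocorrelation lag (default 1, consecutive time points).
#' @param detrend if TRUE, each window is linearly detrended before the
#'   correlation is taken (off by default; the raw-state autocorrelation
#'   is the reported indicator).
#' @return an \code{ew_series}: data frame with columns \code{t},
#'   \code{stress}, \code{D}, \code{autocorrelation} (NA before the first
#'   full window and wherever undefined).
#' @export
sliding_autocorrelation <- function(D, window = 100, lag = 1,
                                    detrend = FALSE) {
  tr <- NULL
  if (inherits(D, "sim_trace")) { tr <- D; D <- tr$D }
  D <- as.numeric(D)
  n <- length(D)
  window <- as.integer(window); lag <- as.integer(lag)
  if (lag < 1) stop("`lag` must be >= 1", call. = FALSE)
  if (window < lag + 2)
    stop("`window` must be at least lag + 2", call. = FALSE)
  if (window > n)
    stop(sprintf("window (%d) longer than series (%d)", window, n),
         call. = FALSE)
  ac <- rep(NA_real_, n)
  for (t in window:n) {
    seg <- D[(t - window + 1L):t]
    if (detrend) seg <- stats::residuals(stats::lm.fit(
      cbind(1, seq_along(seg)), seg))
    a <- seg[seq_len(window - lag)]
    bb <- seg[(lag + 1L):window]
    if (stats::sd(a) == 0 || stats::sd(bb) == 0) next
    ac[t] <- stats::cor(a, bb)
  }
  out <- data.frame(
    t = if (is.null(tr)) seq_len(n) else tr$t,
    stress = if (is.null(tr)) rep(0, n) else tr$stress,
    D = D, autocorrelation = ac)
  structure(out, class = c("ew_series", "data.frame"),
            window = window, lag = lag)
}

#' Locate abrupt transitions of the state sum
#'
#' A transition is a crossing of D = J/2 that persists: the first step of
#' a run of at least \code{persist} consecutive steps on the far side.
#' Upward crossings mark tipping into the depressed state, downward
#' crossings tipping out of it.
#'
#' @param trace a \code{sim_trace} (or a numeric D vector, with \code{J}
#'   supplied).
#' @param J node count; taken from the trace when available.
#' @param persist minimum dwell (steps) on the far side (default 10).
#' @return data frame with columns \code{t} (first step beyond the
#'   midpoint) and \code{type} (\code{"up"}/\code{"down"}); zero rows if
#'   none.
#' @export
find_transitions <- function(trace, J = NULL, persist = 10) {
  if (inherits(trace, "sim_trace")) {
    D <- trace$D
    J <- length(attr(trace, "labels"))
  } else D <- as.numeric(trace)
  if (is.null(J)) stop("`J` required when not passing a trace",
                       call. = FALSE)
  mid <- J / 2
  high <- D > mid
  n <- length(D)
  res <- list()
  state <- high[1]
  i <- 2L
  while (i <= n) {
    if (high[i] != state) {
      run_end <- i
      while (run_end < n && high[run_end + 1L] == high[i]) run_end <-
          run_end + 1L
      if (run_end - i + 1L >= persist) {
        res[[length(res) + 1L]] <- data.frame(
          t = i, type = if (high[i]) "up" else "down")
        state <- high[i]
      }
      i <- run_end + 1L
    } else i <- i + 1L
  }
  if (length(res) == 0)
    return(data.frame(t = integer(0), type = character(0)))
  do.call(rbind, res)
}

#' Test whether the early-warning indicator rises before transitions
#'
#' For each transition, compares the mean autocorrelation in a short
#' window ending just before the transition against a distant baseline
#' window on the preceding plateau. The baseline window ends
#' \code{gap + pre_window} steps before the transition and extends
#' \code{baseline_window} steps further back (clipped at the series
#' start); because the indicator is undefined wherever a window of D has
#' zero variance -- the rule on a quiet plateau -- both means are taken
#' over defined values only. A rise (pre-transition mean exceeding the
#' baseline mean) is the critical-slowing-down signature.
#'
#' @param ew an \code{ew_series}.
#' @param transitions data frame from \code{\link{find_transitions}}, or
#'   an integer vector of transition steps.
#' @param pre_window length (steps) of the pre-transition window
#'   (default 200).
#' @param baseline_window length (steps) of the baseline window
#'   (default 2000).
#' @param gap steps separating the baseline window from the
#'   pre-transition window (default 100).
#' @param min_defined minimum defined indicator values each window must
#'   contain (default 20); transitions below it are dropped.
#' @param on_overlap what to do when another transition falls inside a
#'   transition's comparison windows: \code{"error"} (default) or
#'   \code{"skip"} that transition. Near a tipping point the state can
#'   recross the midline several times in quick succession, so
#'   \code{"skip"} keeps the cleanly separated switches.
#' @return data frame with one row per evaluable transition: \code{t},
#'   \code{type}, \code{pre_mean}, \code{baseline_mean}, \code{rise}
#'   (difference) and \code{rising} (logical). Transitions whose windows
#'   fall off the series are dropped; an empty input yields an empty
#'   result.
#' @export
detect_rising_indicator <- function(ew, transitions, pre_window = 200,
                                    baseline_window = 2000, gap = 100,
                                    min_defined = 20,
                                    on_overlap = c("error", "skip")) {
  stopifnot(inherits(ew, "ew_series"))
  on_overlap <- match.arg(on_overlap)
  if (is.data.frame(transitions)) {
    tt <- transitions$t
    ty <- as.character(transitions$type)
  } else {
    tt <- as.integer(transitions)
    ty <- rep(NA_character_, length(tt))
  }
  empty <- data.frame(t = integer(0), type = character(0),
                      pre_mean = numeric(0), baseline_mean = numeric(0),
                      rise = numeric(0), rising = logical(0))
  if (length(tt) == 0) return(empty)
  ac <- ew$autocorrelation
  n <- length(ac)
  rows <- list()
  for (k in seq_along(tt)) {
    tk <- tt[k]
    pre_idx <- (tk - pre_window):(tk - 1L)
    base_end <- tk - pre_window - gap
    base_idx <- max(1L, base_end - baseline_window + 1L):base_end
    if (min(pre_idx) < 1L || max(pre_idx) > n || base_end < 1L) next
    others <- tt[-k]
    span <- range(c(pre_idx, base_idx))
    hit <- others[others >= span[1] & others <= span[2]]
    if (length(hit)) {
      if (on_overlap == "error")
        stop("comparison windows overlap another transition at t = ",
             paste(hit, collapse = ", "), call. = FALSE)
      next
    }
    pre_vals <- ac[pre_idx][!is.na(ac[pre_idx])]
    base_vals <- ac[base_idx][!is.na(ac[base_idx])]
    if (length(pre_vals) < min_defined ||
        length(base_vals) < min_defined) next
    pm <- mean(pre_vals); bm <- mean(base_vals)
    rows[[length(rows) + 1L]] <- data.frame(
      t = tk, type = ty[k], pre_mean = pm, baseline_mean = bm,
      rise = pm - bm, rising = pm > bm)
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' Write an early-warning series to CSV
#'
#' @param ew an \code{ew_series}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_ew_csv <- function(ew, path) {
  utils::write.csv(as.data.frame(ew), path, row.names = FALSE)
  invisible(path)
}
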