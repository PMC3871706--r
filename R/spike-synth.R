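#' Generate synthetic per-trial spike trains
#'
#' Emulates single-unit floccular recordings during a learning block. Simple
#' spikes follow an inhomogeneous gamma renewal process (shape `isi_shape`;
#' shape 4 gives the regular-ish firing typical of Purkinje cells, shape 1 a
#' Poisson process) whose per-ms rate is `rate_profile`. Complex spikes are
#' sparse: an independent spontaneous Bernoulli draw per 100-ms bin, plus, on
#' off-direction trials, an evoked event placed uniformly in the 75-175 ms
#' window after the instruction with probability `p_evoked`. All times are in
#' ms relative to instruction onset; target motion begins 250 ms before the
#' instruction, so the default trial window is `[-250, 600)`.
#'
#' @param n_trials Number of trials.
#' @param rate_profile Per-ms simple-spike rate (spikes/s), starting at
#'   `t_start`. Default: constant 100 spikes/s over 850 ms.
#' @param t_start Trial start time (ms re instruction onset).
#' @param p_evoked Probability that an off-direction instruction evokes a CS.
#' @param spont_cs_prob Spontaneous CS probability per 100-ms bin.
#' @param cs_bin_width CS bin width (ms).
#' @param evoked_window Window (ms, half-open) in which evoked CS land.
#' @param isi_shape Gamma shape of the rescaled interspike intervals.
#' @param directions Optional per-trial `"off"`/`"on"` vector; sampled
#'   Bernoulli(`p_off`) when `NULL`.
#' @param p_off Probability of an off-direction instruction.
#' @param seed Optional RNG seed.
#' @return Tidy event tibble: `trial`, `direction`, `channel` (`"ss"`/`"cs"`),
#'   `time_ms`, sorted within trial and channel; attribute `n_trials`.
#' @examples
#' tr <- generate_spike_trains(5, seed = 1)
#' dplyr::count(tr, channel)
#' @export
generate_spike_trains <- function(n_trials,
                                  rate_profile = rep(100, 850),
                                  t_start = -250,
                                  p_evoked = 0.4,
                                  spont_cs_prob = 0.09,
                                  cs_bin_width = 100,
                                  evoked_window = c(75, 175),
                                  isi_shape = 4,
                                  directions = NULL,
                                  p_off = 0.5,
                                  seed = NULL) {
  if (any(rate_profile < 0)) abort("`rate_profile` must be non-negative.")
  stopifnot(n_trials >= 1, isi_shape > 0,
            spont_cs_prob >= 0, spont_cs_prob <= 1,
            p_evoked >= 0, p_evoked <= 1)
  if (!is.null(seed)) set.seed(seed)
  len <- length(rate_profile)
  if (is.null(directions)) {
    directions <- ifelse(runif(n_trials) < p_off, "off", "on")
  }
  stopifnot(length(directions) == n_trials,
            all(directions %in% c("off", "on")))
  # time rescaling: cumulative intensity at ms boundaries
  grid_t <- t_start + 0:len
  lambda <- c(0, cumsum(rate_profile) / 1000)
  n_bins <- floor(len / cs_bin_width)
  bin_lo <- t_start + (seq_len(n_bins) - 1) * cs_bin_width
  events <- purrr::map_dfr(seq_len(n_trials), function(tr) {
    # simple spikes: unit-mean gamma ISIs in rescaled time, inverted linearly
    total <- lambda[len + 1]
    n_max <- max(10, ceiling(total + 6 * sqrt(total / isi_shape)))
    iv <- rgamma(n_max, shape = isi_shape, rate = isi_shape)
    while (sum(iv) < total) {
      iv <- c(iv, rgamma(n_max, shape = isi_shape, rate = isi_shape))
    }
    resc <- cumsum(iv)
    resc <- resc[resc <= total]
    ss <- if (length(resc) > 0) {
      approx(lambda, grid_t, xout = resc, ties = "ordered")$y
    } else {
      numeric(0)
    }
    spont_hit <- runif(n_bins) < spont_cs_prob
    cs <- bin_lo[spont_hit] + runif(sum(spont_hit)) * cs_bin_width
    if (directions[tr] == "off" && runif(1) < p_evoked) {
      cs <- c(cs, evoked_window[1] +
                runif(1) * diff(evoked_window))
    }
    bind_rows(
      tibble(trial = tr, direction = directions[tr], channel = "ss",
             time_ms = sort(ss)),
      tibble(trial = tr, direction = directions[tr], channel = "cs",
             time_ms = sort(cs))
    )
  })
  attr(events, "n_trials") <- n_trials
  events
}

#' Reciprocal-interval firing rate
#'
#' Converts spike times to an instantaneous rate trace: at every grid point
#' inside an interspike interval `(t1, t2]` the rate is `1000 / (t2 - t1)`
#' spikes/s; outside the first and last spike the trace is 0. Intervals are
#' half-open so each grid point belongs to exactly one interval.
#'
#' @param spike_times Sorted spike times (ms).
#' @param grid Time points (ms) at which to evaluate the trace.
#' @return Tibble with `time_ms` and `rate`.
#' @examples
#' reciprocal_interval_rate(c(0, 5, 25), grid = c(2, 10, 30))
#' @export
reciprocal_interval_rate <- function(spike_times, grid) {
  if (is.unsorted(spike_times, strictly = TRUE)) {
    abort("`spike_times` must be strictly increasing.")
  }
  rate <- rep(0, length(grid))
  if (length(spike_times) >= 2) {
    idx <- findInterval(grid, spike_times, left.open = TRUE)
    inside <- idx >= 1 & idx < length(spike_times)
    isi <- diff(spike_times)
    rate[inside] <- 1000 / isi[idx[inside]]
  }
  tibble(time_ms = grid, rate = rate)
}

#' Analysis-window scalars for one trial
#'
#' Reduces a rate trace and a trial's CS times to the two quantities used by
#' the trial-level statistics: the mean simple-spike rate over the window
#' spanning 50 ms before to 50 ms after instruction onset, and a flag marking
#' whether any CS fell in the 75-175 ms post-instruction response window
#' (half-open, `[75, 175)`).
#'
#' @param rate_trace Tibble from [reciprocal_interval_rate()] (columns
#'   `time_ms`, `rate`).
#' @param cs_times CS event times (ms re instruction onset).
#' @param ss_window Closed window (ms) for the rate average.
#' @param cs_window Half-open window (ms) for CS detection.
#' @return List with `ss_value` (spikes/s) and `cs_flag` (logical).
#' @export
window_scalars <- function(rate_trace, cs_times,
                           ss_window = c(-50, 50),
                           cs_window = c(75, 175)) {
  t <- rate_trace$time_ms
  if (min(t) > ss_window[1] || max(t) < ss_window[2]) {
    abort("Rate trace does not cover the simple-spike analysis window.")
  }
  in_ss <- t >= ss_window[1] & t <= ss_window[2]
  list(
    ss_value = mean(rate_trace$rate[in_ss]),
    cs_flag = any(cs_times >= cs_window[1] & cs_times < cs_window[2])
  )
}

#' Complex-spike probability histogram
#'
#' Accumulates CS events across trials in fixed-width bins and converts the
#' counts to the probability of at least one CS per bin (the fraction of
#' trials with a CS in that bin), invariant to trial order.
#'
#' @param trains Event tibble from [generate_spike_trains()] (or any table
#'   with `trial`, `channel`, `time_ms`).
#' @param bin_width Bin width (ms).
#' @param t_start First bin edge (ms re instruction onset).
#' @param t_end Upper limit; bins are `[t_start + k*bin_width, ...)` up to the
#'   last full bin below `t_end`.
#' @param n_trials Number of trials; defaults to the `n_trials` attribute or
#'   `max(trial)`.
#' @return Tibble with `bin_start`, `bin_end` (ms) and `cs_prob`.
#' @export
cs_probability_histogram <- function(trains, bin_width = 100,
                                     t_start = -250, t_end = 600,
                                     n_trials = NULL) {
  if (is.null(n_trials)) {
    n_trials <- attr(trains, "n_trials") %||% max(trains$trial)
  }
  stopifnot(n_trials >= 1)
  edges <- seq(t_start, t_end, by = bin_width)
  if (length(edges) < 2) abort("Histogram range shorter than one bin.")
  cs <- trains[trains$channel == "cs", ]
  prob <- vapply(seq_len(length(edges) - 1), function(b) {
    hit <- cs$time_ms >= edges[b] & cs$time_ms < edges[b + 1]
    length(unique(cs$trial[hit])) / n_trials
  }, numeric(1))
  tibble(bin_start = edges[-length(edges)], bin_end = edges[-1],
         cs_prob = prob)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen a unit by its complex-spike responsiveness
#'
#' Classifies recorded units by comparing the instruction-evoked CS
#' probability with the spontaneous per-bin level: `"group1"` (analysable)
#' when the evoked probability exceeds three times the spontaneous level;
#' `"group2"` (excluded) when it is below 0.2 and never exceeds that
#' threshold. Units on the boundary (evoked at or above 0.2 without clearing
#' three times spontaneous) are retained as `"group1"`.
#'
#' @param spontaneous_prob Spontaneous CS probability per 100-ms bin.
#' @param evoked_prob CS probability in the evoked-response window.
#' @return Character vector of `"group1"`/`"group2"` labels.
#' @examples
#' screen_unit(0.09, c(0.30, 0.15, 0))
#' @export
screen_unit <- function(spontaneous_prob, evoked_prob) {
  stopifnot(all(spontaneous_prob >= 0 & spontaneous_prob <= 1),
            all(evoked_prob >= 0 & evoked_prob <= 1))
  ifelse(evoked_prob > 3 * spontaneous_prob, "group1",
         ifelse(evoked_prob < 0.2, "group2", "group1"))
}

#' Trial summaries from spike-level data
#'
#' The bridge from spike trains to the trial-level analyses: per trial,
#' estimates the rate trace with the reciprocal-interval algorithm and reduces
#' it to the analysis-window scalars, yielding rows directly consumable by
#' [tag_pairs()], [facilitation_terciles()] and friends.
#'
#' @param trains Event tibble from [generate_spike_trains()].
#' @param grid Evaluation grid (ms) for the rate trace; must cover the
#'   simple-spike window.
#' @inheritParams window_scalars
#' @return Tibble with `trial`, `direction`, `cs_flag`, `ss_value`.
#' @examples
#' tr <- generate_spike_trains(10, seed = 1)
#' spike_trial_summary(tr)
#' @export
spike_trial_summary <- function(trains, grid = seq(-250, 599),
                                ss_window = c(-50, 50),
                                cs_window = c(75, 175)) {
  n_trials <- attr(trains, "n_trials") %||% max(trains$trial)
  purrr::map_dfr(seq_len(n_trials), function(tr) {
    ev <- trains[trains$trial == tr, ]
    trace <- reciprocal_interval_rate(ev$time_ms[ev$channel == "ss"], grid)
    sc <- window_scalars(trace, ev$time_ms[ev$channel == "cs"],
                         ss_window, cs_window)
    tibble(trial = tr, direction = ev$direction[1],
           cs_flag = sc$cs_flag, ss_value = sc$ss_value)
  })
}
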