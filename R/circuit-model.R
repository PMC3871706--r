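#' Climbing-fiber map from olive neurons to Purkinje cells
#'
#' Each olive neuron `k` contacts the contiguous block of `divergence` Purkinje
#' cells `(k-1)*divergence + 1, ..., k*divergence`, i.e. PC `i` receives its
#' climbing fiber from olive neuron `ceiling(i / divergence)`.
#'
#' @param n_pc Number of Purkinje cells.
#' @param divergence Purkinje cells per olive neuron.
#' @return Integer vector of length `n_pc`: the olive index for each PC.
#' @export
climbing_fiber_map <- function(n_pc, divergence) {
  ceiling(seq_len(n_pc) / divergence)
}

#' Pool assignment from Purkinje cells to olive neurons
#'
#' Olive neuron `k` averages the simple-spike rates of a contiguous block of
#' `pool_size` Purkinje cells starting at PC `(k-1)*pool_size + 1`; blocks wrap
#' modulo `n_pc` when they would run past the population.
#'
#' @param n_pc Number of Purkinje cells.
#' @param n_io Number of olive neurons.
#' @param pool_size Fan-in per olive neuron.
#' @return Integer matrix `n_io x pool_size` of PC indices.
#' @export
pool_assignment <- function(n_pc, n_io, pool_size) {
  starts <- (seq_len(n_io) - 1L) * pool_size
  idx <- outer(starts, 0:(pool_size - 1L), "+") %% n_pc + 1L
  storage.mode(idx) <- "integer"
  idx
}

#' Draw one trial's population of simple-spike firing rates
#'
#' Implements the correlated-rate mixture: each PC's rate is
#' `(1 - r_nn) * alpha_i + r_nn * beta + offset_i`, where `alpha_i` are
#' independent `Normal(rate_mean, rate_sd)` draws, `beta` is a single shared
#' draw from the same distribution, and `offset_i` is the (non-positive)
#' plasticity offset carried over from previous trials. Rates are clipped at 0.
#'
#' @param config A [model_config()].
#' @param shared_draw Optional value of the shared component `beta`; drawn from
#'   the current RNG stream when `NULL`.
#' @param offsets Per-PC plasticity offsets (spikes/s, `<= 0`); scalar 0 for a
#'   naive population.
#' @return Numeric vector of `n_pc` rates with attribute `n_clipped`, the
#'   number of draws clipped at 0.
#' @export
draw_population_rates <- function(config, shared_draw = NULL, offsets = 0) {
  r <- if (config$enable_ss_corr) config$r_nn else 0
  alpha <- rnorm(config$n_pc, config$rate_mean, config$rate_sd)
  beta <- if (is.null(shared_draw)) {
    rnorm(1, config$rate_mean, config$rate_sd)
  } else {
    shared_draw
  }
  rates <- (1 - r) * alpha + r * beta
  if (config$renormalize_sd) {
    s <- sqrt((1 - r)^2 + r^2)
    rates <- config$rate_mean + (rates - config$rate_mean) / s
  }
  rates <- rates + offsets
  if (any(!is.finite(rates))) {
    abort("Non-finite rate draw; check rate_mean/rate_sd and the RNG state.")
  }
  clipped <- rates < 0
  rates[clipped] <- 0
  attr(rates, "n_clipped") <- sum(clipped)
  rates
}

#' Pooled simple-spike drive to each olive neuron
#'
#' The drive to olive neuron `k` is the arithmetic mean of the simple-spike
#' rates of its assigned pool of Purkinje cells.
#'
#' @param ss_rates Per-PC rates (spikes/s).
#' @param pool_size Fan-in per olive; ignored when `assignment` is given.
#' @param n_io Number of olive neurons; ignored when `assignment` is given.
#' @param assignment Optional precomputed [pool_assignment()] matrix.
#' @return Numeric vector of `n_io` pooled drives (spikes/s).
#' @export
olive_drive <- function(ss_rates, pool_size = NULL, n_io = NULL,
                        assignment = NULL) {
  if (is.null(assignment)) {
    assignment <- pool_assignment(length(ss_rates), n_io, pool_size)
  }
  rowMeans(matrix(ss_rates[assignment], nrow = nrow(assignment)))
}

#' Per-olive complex-spike response probability
#'
#' On off-direction instructions the probability that an olive neuron responds
#' is a sigmoid of its pooled simple-spike drive,
#' `P = base + amplitude / (1 + exp(-slope * (IN - midpoint)))`; on-direction
#' instructions never evoke a CS, so the probability is 0 for every olive
#' neuron. With the SS-to-olive feedback disabled the drive is replaced by the
#' constant `sigmoid_midpoint` upstream (see [run_trial()]).
#'
#' @param io_input Pooled drives (spikes/s), any length.
#' @param direction `"off"` or `"on"`.
#' @param config A [model_config()].
#' @return Probabilities, same length as `io_input`.
#' @export
cs_response_probability <- function(io_input, direction, config) {
  stopifnot(all(is.finite(io_input)))
  direction <- match.arg(direction, c("off", "on"))
  if (direction == "on") return(rep(0, length(io_input)))
  config$sigmoid_base + config$sigmoid_amplitude /
    (1 + exp(-config$sigmoid_slope * (io_input - config$sigmoid_midpoint)))
}

#' Sample synchronised complex-spike events
#'
#' One shared threshold gain `R_CS ~ Normal(1, rcs_sd)` (clipped at 0) is drawn
#' per trial; olive neuron `k` fires iff `R_CS * delta_k < P_k` with
#' independent `delta_k ~ Uniform(0, 1)`. Because `R_CS` is common to all
#' olive neurons it synchronises their responses; fixing `R_CS = 1`
#' (`enable_cs_corr = FALSE`) removes the synchrony while leaving each olive
#' neuron's marginal behaviour a plain Bernoulli(`P_k`). Each olive neuron's
#' response propagates identically to its block of `divergence` Purkinje cells.
#'
#' @param cs_prob Per-olive response probabilities.
#' @param config A [model_config()].
#' @return List with `fired` (per-olive logical), `cs` (per-PC logical) and
#'   `r_cs` (the shared gain used).
#' @export
sample_cs_events <- function(cs_prob, config) {
  stopifnot(all(cs_prob >= 0 & cs_prob <= 1))
  r_cs <- if (config$enable_cs_corr) {
    max(rnorm(1, 1, config$rcs_sd), 0)
  } else {
    1
  }
  delta <- runif(length(cs_prob))
  fired <- (r_cs * delta) < cs_prob
  cs <- fired[climbing_fiber_map(config$n_pc, config$divergence)]
  list(fired = fired, cs = cs, r_cs = r_cs)
}

#' Create an empty plasticity state
#'
#' The state stores, for each Purkinje cell, the depression already scheduled
#' for the next `length(plasticity_kernel(config))` trials.
#'
#' @param config A [model_config()].
#' @return A `"pc_plasticity_state"` list with the `pending` schedule matrix
#'   (kernel steps x PCs, values `<= 0`).
#' @export
new_plasticity_state <- function(config) {
  k <- plasticity_kernel(config)
  state <- list(
    pending = matrix(0, nrow = length(k), ncol = config$n_pc),
    kernel = k
  )
  class(state) <- "pc_plasticity_state"
  state
}

#' Advance the plasticity state after a trial's complex spikes
#'
#' A CS on the current trial schedules a depression of
#' `plasticity_amplitude` spikes/s on the next trial, decaying by
#' `plasticity_decay_step` on each following trial until exhausted. In
#' `"additive"` mode contributions from CS events on successive trials sum; in
#' `"reset"` mode a new CS restarts the kernel for that cell. A no-op when
#' plasticity is disabled.
#'
#' @param state A [new_plasticity_state()] object.
#' @param cs_events Per-PC logical CS occurrences on the current trial.
#' @param config A [model_config()].
#' @return The updated state.
#' @export
plasticity_update <- function(state, cs_events, config) {
  k <- state$kernel
  if (length(k) == 0 || !config$enable_plasticity) return(state)
  shifted <- rbind(state$pending[-1, , drop = FALSE],
                   matrix(0, 1, ncol(state$pending)))
  if (config$plasticity_mode == "additive") {
    state$pending <- shifted - k %o% as.numeric(cs_events)
  } else {
    state$pending <- shifted
    if (any(cs_events)) {
      state$pending[, cs_events] <- -k
    }
  }
  state
}

#' Current plasticity offsets
#'
#' @param state A `"pc_plasticity_state"`.
#' @return Per-PC offsets (spikes/s, `<= 0`) to apply to the upcoming trial.
#' @export
plasticity_offsets <- function(state) {
  if (nrow(state$pending) == 0) return(rep(0, ncol(state$pending)))
  state$pending[1, ]
}

#' Learned eye velocity from a population of rates
#'
#' The behavioural readout is the arbitrarily scaled depression of the
#' population-mean simple-spike rate below its baseline: depressed firing maps
#' to a positive learned velocity along the instruction direction.
#'
#' @param ss_rates Per-PC rates (spikes/s).
#' @param gain Scale factor (units per spike/s).
#' @param rate_mean Baseline rate (spikes/s).
#' @return Scalar learned eye velocity (arbitrary units).
#' @export
eye_velocity <- function(ss_rates, gain, rate_mean = 100) {
  gain * (rate_mean - mean(ss_rates))
}

#' Run a single trial of the circuit model
#'
#' Composes the per-trial pipeline: correlated rate draw (with pending
#' plasticity offsets), pooled olive drive (or the constant midpoint when
#' feedback is ablated), sigmoid CS probability, synchronised CS sampling,
#' behavioural readout, and the plasticity update for subsequent trials.
#' Uses the current RNG stream.
#'
#' @param state A `"pc_plasticity_state"`.
#' @param direction `"off"` or `"on"`.
#' @param config A [model_config()].
#' @param assignment Optional precomputed [pool_assignment()] matrix.
#' @return List with `record` (per-trial quantities: `direction`, `ss_rates`,
#'   `io_inputs`, `cs_prob`, `fired`, `cs_events`, `r_cs`, `eye_velocity`,
#'   `n_clipped`) and the advanced `state`.
#' @export
run_trial <- function(state, direction, config, assignment = NULL) {
  if (is.null(assignment)) {
    assignment <- pool_assignment(config$n_pc, config$n_io, config$pool_size)
  }
  rates <- draw_population_rates(config, offsets = plasticity_offsets(state))
  n_clipped <- attr(rates, "n_clipped")
  attr(rates, "n_clipped") <- NULL
  io_inputs <- if (config$enable_feedback) {
    olive_drive(rates, assignment = assignment)
  } else {
    rep(config$sigmoid_midpoint, config$n_io)
  }
  cs_prob <- cs_response_probability(io_inputs, direction, config)
  ev <- sample_cs_events(cs_prob, config)
  state <- plasticity_update(state, ev$cs, config)
  record <- list(
    direction = direction,
    ss_rates = rates,
    io_inputs = io_inputs,
    cs_prob = cs_prob,
    fired = ev$fired,
    cs_events = ev$cs,
    r_cs = if (direction == "off") ev$r_cs else NA_real_,
    eye_velocity = eye_velocity(rates, config$ev_gain, config$rate_mean),
    n_clipped = n_clipped
  )
  list(record = record, state = state)
}

#' Simulate a full session of learning trials
#'
#' Runs `n_trials` trials with independently Bernoulli(`p_off`) sampled
#' instruction directions, carrying CS-linked plasticity across trials.
#' Bit-exactly reproducible from `(config, seed)`.
#'
#' @param config A [model_config()].
#' @param seed Integer seed; falls back to `config$seed`, or to the current RNG
#'   stream when both are `NULL`.
#' @return A `"pc_session"` object: matrices `ss` (trials x PCs, spikes/s),
#'   `cs` (trials x PCs, logical), `cs_prob` (trials x olives), vectors
#'   `direction`, `eye_velocity` and `r_cs`, the `config`, `seed`, and the
#'   total count `n_clipped` of rate draws clipped at 0.
#' @examples
#' s <- run_session(model_config(n_pc = 50, n_io = 5, n_trials = 40), seed = 1)
#' glance(s)
#' @export
run_session <- function(config, seed = config$seed) {
  validate_model_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trials
  assignment <- pool_assignment(config$n_pc, config$n_io, config$pool_size)
  directions <- ifelse(runif(n) < config$p_off, "off", "on")
  ss <- matrix(NA_real_, n, config$n_pc)
  cs <- matrix(FALSE, n, config$n_pc)
  cs_prob <- matrix(NA_real_, n, config$n_io)
  ev <- numeric(n)
  r_cs <- rep(NA_real_, n)
  n_clipped <- 0L
  state <- new_plasticity_state(config)
  for (j in seq_len(n)) {
    step <- run_trial(state, directions[j], config, assignment)
    state <- step$state
    rec <- step$record
    ss[j, ] <- rec$ss_rates
    cs[j, ] <- rec$cs_events
    cs_prob[j, ] <- rec$cs_prob
    ev[j] <- rec$eye_velocity
    r_cs[j] <- rec$r_cs
    n_clipped <- n_clipped + rec$n_clipped
  }
  structure(
    list(ss = ss, cs = cs, cs_prob = cs_prob, direction = directions,
         eye_velocity = ev, r_cs = r_cs, config = config, seed = seed,
         n_clipped = n_clipped),
    class = "pc_session"
  )
}

#' @export
print.pc_session <- function(x, ...) {
  cat(sprintf("<pc_session> %d trials x %d PCs (seed %s)\n",
              nrow(x$ss), ncol(x$ss),
              if (is.null(x$seed)) "none" else x$seed))
  cat(sprintf("  off-direction trials: %d; CS-bearing PC-trials: %d; clipped rate draws: %d\n",
              sum(x$direction == "off"), sum(x$cs), x$n_clipped))
  invisible(x)
}

#' @describeIn run_session Per-trial tibble: `trial`, `direction`, `mean_rate`,
#'   `n_cs` (PCs with a CS), `eye_velocity`.
#' @param x A `"pc_session"`.
#' @param ... Unused.
#' @export
tidy.pc_session <- function(x, ...) {
  tibble(
    trial = seq_len(nrow(x$ss)),
    direction = x$direction,
    mean_rate = rowMeans(x$ss),
    n_cs = rowSums(x$cs),
    eye_velocity = x$eye_velocity
  )
}

#' @describeIn run_session One-row session summary.
#' @export
glance.pc_session <- function(x, ...) {
  off <- x$direction == "off"
  tibble(
    n_trials = nrow(x$ss),
    n_pc = ncol(x$ss),
    n_off = sum(off),
    mean_rate = mean(x$ss),
    cs_prob_off = if (any(off)) mean(x$cs[off, , drop = FALSE]) else NA_real_,
    n_clipped = x$n_clipped,
    seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed)
  )
}

#' Per-trial, per-cell summary table of a session
#'
#' Converts a simulated session into the tidy trial-summary format consumed by
#' the pair/trio/tercile/independence analyses: one row per (cell, trial) with
#' the cell's rate and CS flag and the session-wide behavioural scalar.
#'
#' @param session A `"pc_session"`.
#' @param cells Integer vector of PC indices (default: all).
#' @return Tibble with columns `cell`, `trial`, `direction`, `cs_flag`,
#'   `ss_value`, `behavior_value`.
#' @export
as_trial_summary <- function(session, cells = NULL) {
  stopifnot(inherits(session, "pc_session"))
  if (is.null(cells)) cells <- seq_len(ncol(session$ss))
  n <- nrow(session$ss)
  tibble(
    cell = rep(cells, each = n),
    trial = rep(seq_len(n), length(cells)),
    direction = rep(session$direction, length(cells)),
    cs_flag = as.vector(session$cs[, cells]),
    ss_value = as.vector(session$ss[, cells]),
    behavior_value = rep(session$eye_velocity, length(cells))
  )
}
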