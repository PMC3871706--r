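#' Configuration of the Purkinje-cell / inferior-olive circuit model
#'
#' Builds the full parameter set for [run_session()]. Defaults reproduce the
#' reference circuit: 1000 Purkinje cells (PCs), 100 inferior-olive (IO)
#' neurons, a 10:1 climbing-fiber divergence, weakly correlated simple-spike
#' firing (mixing weight `r_nn = 0.3` on a shared trial-wide draw), a sigmoid
#' mapping from pooled simple-spike drive to the per-olive probability of a
#' complex-spike (CS) response to an off-direction instruction, a shared
#' per-trial gain on the CS threshold that synchronises olive output, and a
#' CS-triggered single-trial depression of 5 spikes/s that decays by
#' 2.5 spikes/s on each of the next two trials.
#'
#' @param n_pc Number of model Purkinje cells.
#' @param n_io Number of inferior-olive neurons. Must satisfy
#'   `n_pc == n_io * divergence`.
#' @param divergence Purkinje cells contacted by each olive neuron's climbing
#'   fiber.
#' @param rate_mean,rate_sd Mean and standard deviation (spikes/s) of the
#'   normal distribution from which the independent and shared rate components
#'   are drawn.
#' @param r_nn Mixing weight in `[0, 1]` on the shared trial-wide component of
#'   simple-spike firing; the implied pairwise across-trial correlation is
#'   `r_nn^2 / ((1 - r_nn)^2 + r_nn^2)`.
#' @param pool_size Number of Purkinje cells whose rates are averaged to drive
#'   each olive neuron (the fan-in `N`). Blocks are contiguous and wrap modulo
#'   `n_pc` when `n_io * pool_size > n_pc`.
#' @param sigmoid_base,sigmoid_amplitude,sigmoid_slope,sigmoid_midpoint
#'   Constants of the sigmoid relating pooled drive `IN` to the per-olive CS
#'   probability on off-direction trials:
#'   `P = base + amplitude / (1 + exp(-slope * (IN - midpoint)))`.
#' @param rcs_sd Standard deviation of the shared per-trial threshold gain
#'   `R_CS ~ Normal(1, rcs_sd)` (clipped at 0) that synchronises CS responses
#'   across olive neurons.
#' @param plasticity_amplitude Depression (spikes/s) applied on the trial after
#'   a CS.
#' @param plasticity_decay_step Amount (spikes/s) by which the depression decays
#'   on each subsequent trial.
#' @param plasticity_mode `"additive"` sums overlapping kernels from CS events
#'   on successive trials; `"reset"` restarts the kernel at each new CS.
#' @param n_trials Trials per session.
#' @param p_off Probability that a trial delivers an off-direction instruction.
#' @param ev_gain Gain converting population-mean rate depression into the
#'   learned eye-velocity scalar (arbitrary units per spike/s).
#' @param enable_plasticity,enable_feedback,enable_ss_corr,enable_cs_corr
#'   Mechanism switches used by the ablation suite: CS-linked plasticity; the
#'   simple-spike -> olive feedback (when off, every olive sees constant drive
#'   `sigmoid_midpoint`); the shared simple-spike component (when off, `r_nn`
#'   is treated as 0); the shared CS gain (when off, `R_CS` is fixed at 1).
#' @param renormalize_sd If `TRUE`, rescale the rate mixture so the marginal
#'   standard deviation equals `rate_sd` exactly; the default `FALSE` keeps the
#'   mixture verbatim, with marginal sd `rate_sd * sqrt((1-r_nn)^2 + r_nn^2)`.
#' @param seed Optional default seed recorded in the config and used by
#'   [run_session()] when no seed is supplied there.
#'
#' @return A list of class `"pc_config"`.
#' @seealso [run_session()], [plasticity_kernel()], [make_variant_config()]
#' @examples
#' cfg <- model_config(n_pc = 100, n_io = 10, n_trials = 50)
#' plasticity_kernel(cfg)
#' @export
model_config <- function(n_pc = 1000,
                         n_io = 100,
                         divergence = 10,
                         rate_mean = 100,
                         rate_sd = 18,
                         r_nn = 0.3,
                         pool_size = 20,
                         sigmoid_base = 0.1,
                         sigmoid_amplitude = 0.5,
                         sigmoid_slope = 0.3,
                         sigmoid_midpoint = 100,
                         rcs_sd = 0.4,
                         plasticity_amplitude = 5,
                         plasticity_decay_step = 2.5,
                         plasticity_mode = c("additive", "reset"),
                         n_trials = 800,
                         p_off = 0.5,
                         ev_gain = 0.1,
                         enable_plasticity = TRUE,
                         enable_feedback = TRUE,
                         enable_ss_corr = TRUE,
                         enable_cs_corr = TRUE,
                         renormalize_sd = FALSE,
                         seed = NULL) {
  cfg <- list(
    n_pc = n_pc, n_io = n_io, divergence = divergence,
    rate_mean = rate_mean, rate_sd = rate_sd, r_nn = r_nn,
    pool_size = pool_size,
    sigmoid_base = sigmoid_base, sigmoid_amplitude = sigmoid_amplitude,
    sigmoid_slope = sigmoid_slope, sigmoid_midpoint = sigmoid_midpoint,
    rcs_sd = rcs_sd,
    plasticity_amplitude = plasticity_amplitude,
    plasticity_decay_step = plasticity_decay_step,
    plasticity_mode = match.arg(plasticity_mode),
    n_trials = n_trials, p_off = p_off, ev_gain = ev_gain,
    enable_plasticity = enable_plasticity,
    enable_feedback = enable_feedback,
    enable_ss_corr = enable_ss_corr,
    enable_cs_corr = enable_cs_corr,
    renormalize_sd = renormalize_sd,
    seed = seed
  )
  class(cfg) <- "pc_config"
  validate_model_config(cfg)
}

#' Validate a model configuration
#'
#' Checks every structural invariant of a [model_config()] object and returns
#' it invisibly unchanged, or aborts with a message naming the offending field.
#'
#' @param config A `"pc_config"` object (or bare list with the same fields).
#' @return The validated config, invisibly classed as `"pc_config"`.
#' @export
validate_model_config <- function(config) {
  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) abort(sprintf("Invalid `%s`: %s.", field, what))
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  cnt <- function(x) num1(x) && x >= 1 && x == floor(x)

  chk(cnt(config$n_pc), "n_pc", "must be a positive integer")
  chk(cnt(config$n_io), "n_io", "must be a positive integer")
  chk(cnt(config$divergence), "divergence", "must be a positive integer")
  chk(config$n_pc == config$n_io * config$divergence, "n_pc",
      sprintf("must equal n_io * divergence (%d * %d)",
              config$n_io, config$divergence))
  chk(num1(config$rate_mean), "rate_mean", "must be a finite number")
  chk(num1(config$rate_sd) && config$rate_sd >= 0, "rate_sd",
      "must be a non-negative number")
  chk(num1(config$r_nn) && config$r_nn >= 0 && config$r_nn <= 1, "r_nn",
      "must lie in [0, 1]")
  chk(cnt(config$pool_size) && config$pool_size <= config$n_pc, "pool_size",
      "must be an integer in [1, n_pc]")
  chk(num1(config$sigmoid_base) && config$sigmoid_base >= 0, "sigmoid_base",
      "must be a probability")
  chk(num1(config$sigmoid_amplitude) && config$sigmoid_amplitude >= 0,
      "sigmoid_amplitude", "must be non-negative")
  chk(config$sigmoid_base + config$sigmoid_amplitude <= 1, "sigmoid_amplitude",
      "sigmoid_base + sigmoid_amplitude must not exceed 1")
  chk(num1(config$sigmoid_slope), "sigmoid_slope", "must be a finite number")
  chk(num1(config$sigmoid_midpoint), "sigmoid_midpoint",
      "must be a finite number")
  chk(num1(config$rcs_sd) && config$rcs_sd >= 0, "rcs_sd",
      "must be non-negative")
  chk(num1(config$plasticity_amplitude) && config$plasticity_amplitude >= 0,
      "plasticity_amplitude", "must be non-negative")
  chk(num1(config$plasticity_decay_step) && config$plasticity_decay_step > 0,
      "plasticity_decay_step", "must be positive")
  chk(config$plasticity_mode %in% c("additive", "reset"), "plasticity_mode",
      "must be 'additive' or 'reset'")
  chk(cnt(config$n_trials), "n_trials", "must be a positive integer")
  chk(num1(config$p_off) && config$p_off >= 0 && config$p_off <= 1, "p_off",
      "must lie in [0, 1]")
  chk(num1(config$ev_gain), "ev_gain", "must be a finite number")
  for (f in c("enable_plasticity", "enable_feedback", "enable_ss_corr",
              "enable_cs_corr", "renormalize_sd")) {
    chk(is.logical(config[[f]]) && length(config[[f]]) == 1 &&
          !is.na(config[[f]]), f, "must be TRUE or FALSE")
  }
  if (!is.null(config$seed)) {
    chk(num1(config$seed) && config$seed == floor(config$seed), "seed",
        "must be an integer or NULL")
  }
  k <- plasticity_kernel(config)
  chk(all(k >= 0) && all(diff(k) <= 0), "plasticity_amplitude",
      "the implied kernel must be non-negative and non-increasing")
  class(config) <- "pc_config"
  invisible(config)
}

#' Plasticity kernel implied by a configuration
#'
#' The depression (spikes/s, positive values) applied on the trials following a
#' complex spike: `amplitude` on the next trial, decaying by `decay_step` per
#' trial until it reaches 0. Defaults give `c(5, 2.5)`: a CS on trial `t`
#' depresses trial `t + 1` by 5 spikes/s and trial `t + 2` by 2.5 spikes/s.
#'
#' @param config A [model_config()] object.
#' @return Numeric vector of per-trial depression magnitudes (possibly empty).
#' @export
plasticity_kernel <- function(config) {
  a <- config$plasticity_amplitude
  if (a <= 0) return(numeric(0))
  k <- seq(a, 0, by = -config$plasticity_decay_step)
  k[k > 0]
}

#' @export
print.pc_config <- function(x, ...) {
  cat("<pc_config>\n")
  cat(sprintf("  circuit : %d PCs, %d IO neurons (divergence %d), fan-in %d\n",
              x$n_pc, x$n_io, x$divergence, x$pool_size))
  cat(sprintf("  rates   : N(%g, %g) spikes/s, r_nn = %g%s\n",
              x$rate_mean, x$rate_sd, x$r_nn,
              if (x$renormalize_sd) " (marginal sd renormalized)" else ""))
  cat(sprintf("  CS      : P = %g + %g/(1+exp(-%g (IN - %g))), R_CS sd %g\n",
              x$sigmoid_base, x$sigmoid_amplitude, x$sigmoid_slope,
              x$sigmoid_midpoint, x$rcs_sd))
  cat(sprintf("  kernel  : -%s spikes/s (%s)\n",
              paste(plasticity_kernel(x), collapse = ", -"),
              x$plasticity_mode))
  cat(sprintf("  session : %d trials, p(off) = %g, ev gain %g\n",
              x$n_trials, x$p_off, x$ev_gain))
  flags <- c("plasticity", "feedback", "ss_corr", "cs_corr")
  on <- c(x$enable_plasticity, x$enable_feedback, x$enable_ss_corr,
          x$enable_cs_corr)
  cat(sprintf("  enabled : %s\n",
              paste(ifelse(on, flags, paste0("!", flags)), collapse = " ")))
  invisible(x)
}
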