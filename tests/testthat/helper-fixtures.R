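# Small circuit used throughout the unit tests: 60 PCs, 6 olive neurons,
# 10:1 divergence, fan-in 5.
small_config <- function(...) {
  defaults <- list(n_pc = 60, n_io = 6, divergence = 10, pool_size = 5,
                   n_trials = 120)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

# Hand-built four-trial summary: rates 100, 95, 100, 100, all off-direction,
# CS on trials 1 and 3.
four_trial_summary <- function() {
  tibble::tibble(
    trial = 1:4,
    direction = "off",
    cs_flag = c(TRUE, FALSE, TRUE, TRUE),
    ss_value = c(100, 95, 100, 100),
    behavior_value = c(0, 0.5, 0, 0)
  )
}

# Trial summary with i.i.d. Bernoulli CS flags (independence null).
bernoulli_summary <- function(n_trials, p, seed) {
  set.seed(seed)
  tibble::tibble(
    trial = seq_len(n_trials),
    direction = "off",
    cs_flag = stats::runif(n_trials) < p,
    ss_value = stats::rnorm(n_trials, 100, 10)
  )
}

# Configuration with every learning mechanism disabled (null model).
null_config <- function(...) {
  model_config(enable_plasticity = FALSE, enable_feedback = FALSE,
               enable_ss_corr = FALSE, enable_cs_corr = FALSE, r_nn = 0, ...)
}
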