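test_that("pairwise rate correlation follows the mixture closed form", {
  # closed-form oracle for the shared/private normal mixture:
  # corr = r^2 / ((1 - r)^2 + r^2)
  oracle <- function(r) r^2 / ((1 - r)^2 + r^2)
  for (r in c(0, 0.3, 0.5)) {
    cfg <- model_config(n_pc = 20, n_io = 2, n_trials = 1, r_nn = r,
                        enable_plasticity = FALSE)
    set.seed(42)
    rates <- t(replicate(4000, as.numeric(
      draw_population_rates(cfg, offsets = 0))))
    cm <- cor(rates)
    obs <- mean(cm[upper.tri(cm)])
    expect_equal(obs, oracle(r), tolerance = 0.04,
                 label = sprintf("mean pairwise correlation at r_nn = %g", r))
  }
  # degenerate mixture: every PC identical on every trial
  cfg1 <- model_config(n_pc = 20, n_io = 2, n_trials = 1, r_nn = 1)
  set.seed(1)
  x <- draw_population_rates(cfg1)
  expect_equal(sd(as.numeric(x)), 0)
})

test_that("marginal rate sd is rate_sd * sqrt((1-r)^2 + r^2), or rate_sd when renormalized", {
  cfg <- model_config(n_pc = 200, n_io = 20, n_trials = 400, p_off = 0,
                      enable_plasticity = FALSE)
  s <- run_session(cfg, seed = 5)
  expect_equal(sd(as.numeric(s$ss)), 18 * sqrt(0.7^2 + 0.3^2),
               tolerance = 0.02)
  cfg_rn <- model_config(n_pc = 200, n_io = 20, n_trials = 400, p_off = 0,
                         enable_plasticity = FALSE, renormalize_sd = TRUE)
  s_rn <- run_session(cfg_rn, seed = 5)
  expect_equal(sd(as.numeric(s_rn$ss)), 18, tolerance = 0.02)
})

test_that("olive drive is the pool mean, with wrapped contiguous blocks", {
  expect_equal(olive_drive(c(90, 110), pool_size = 2, n_io = 1), 100)
  rates <- c(80, 90, 100, 110)
  expect_equal(olive_drive(rates, pool_size = 1, n_io = 4), rates)
  expect_equal(olive_drive(rep(100, 50), pool_size = 10, n_io = 5),
               rep(100, 5))
  # wrap: 4 olives x pool 3 over 4 PCs reuses PCs modulo n_pc
  a <- pool_assignment(n_pc = 4, n_io = 4, pool_size = 3)
  expect_equal(dim(a), c(4, 3))
  expect_equal(a[1, ], c(1, 2, 3))
  expect_equal(a[2, ], c(4, 1, 2))
  expect_true(all(a >= 1 & a <= 4))
})

test_that("CS probability is the bounded sigmoid off-direction and 0 on-direction", {
  cfg <- model_config()
  expect_equal(cs_response_probability(100, "off", cfg), 0.35)
  expect_equal(cs_response_probability(-1e6, "off", cfg), 0.1,
               tolerance = 1e-12)
  expect_equal(cs_response_probability(1e6, "off", cfg), 0.6,
               tolerance = 1e-12)
  expect_equal(cs_response_probability(c(80, 100, 120), "on", cfg),
               c(0, 0, 0))
  p <- cs_response_probability(seq(40, 160, by = 1), "off", cfg)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p > 0.1 & p < 0.6))
})

test_that("CS events are identical within each olive neuron's divergence block", {
  expect_equal(climbing_fiber_map(20, 10), rep(1:2, each = 10))
  cfg <- small_config()
  s <- run_session(cfg, seed = 11)
  cf <- climbing_fiber_map(cfg$n_pc, cfg$divergence)
  for (k in seq_len(cfg$n_io)) {
    block <- s$cs[, cf == k, drop = FALSE]
    expect_true(all(block == block[, 1]))
  }
  expect_true(all(!s$cs[s$direction == "on", ]))
})

test_that("plasticity kernel applies -5 then -2.5 then 0, summing across CS", {
  cfg <- model_config(n_pc = 10, n_io = 1, n_trials = 1, pool_size = 5)
  st <- new_plasticity_state(cfg)
  cs <- c(TRUE, rep(FALSE, 9))
  st1 <- plasticity_update(st, cs, cfg)
  expect_equal(plasticity_offsets(st1)[1], -5)
  st2 <- plasticity_update(st1, rep(FALSE, 10), cfg)
  expect_equal(plasticity_offsets(st2)[1], -2.5)
  st3 <- plasticity_update(st2, rep(FALSE, 10), cfg)
  expect_identical(plasticity_offsets(st3)[1], 0)   # exactly zero
  expect_true(all(plasticity_offsets(st3) == 0))
  # CS on two consecutive trials: offsets add (-5 + -2.5 = -7.5)
  stA <- plasticity_update(st, cs, cfg)
  stA <- plasticity_update(stA, cs, cfg)
  expect_equal(plasticity_offsets(stA)[1], -7.5)
  # reset mode restarts the kernel instead
  cfg_r <- model_config(n_pc = 10, n_io = 1, pool_size = 5, plasticity_mode = "reset")
  stB <- plasticity_update(new_plasticity_state(cfg_r), cs, cfg_r)
  stB <- plasticity_update(stB, cs, cfg_r)
  expect_equal(plasticity_offsets(stB)[1], -5)
  # disabled plasticity is a no-op
  cfg_off <- model_config(n_pc = 10, n_io = 1, pool_size = 5, enable_plasticity = FALSE)
  stC <- plasticity_update(new_plasticity_state(cfg_off), cs, cfg_off)
  expect_true(all(plasticity_offsets(stC) == 0))
})

test_that("sessions are bit-exactly reproducible from (config, seed)", {
  cfg <- small_config()
  s1 <- run_session(cfg, seed = 99)
  s2 <- run_session(cfg, seed = 99)
  expect_identical(s1$ss, s2$ss)
  expect_identical(s1$cs, s2$cs)
  expect_identical(s1$eye_velocity, s2$eye_velocity)
  s3 <- run_session(cfg, seed = 100)
  expect_false(identical(s1$ss, s3$ss))
})

test_that("session invariants hold: trial count, CS probability bounds, direction gating", {
  cfg <- small_config(n_trials = 200)
  s <- run_session(cfg, seed = 3)
  expect_equal(nrow(s$ss), 200)
  off <- s$direction == "off"
  expect_true(all(s$cs_prob[off, ] > 0.1 & s$cs_prob[off, ] < 0.6))
  expect_true(all(s$cs_prob[!off, ] == 0))
  expect_true(all(!s$cs[!off, ]))
  # off-direction count within the binomial 99% interval
  expect_true(abs(sum(off) - 100) < qnorm(0.995) * sqrt(200 * 0.25))
})

test_that("with no CS events, plasticity-on and plasticity-off sessions coincide", {
  # forcing zero CS via a flat-zero sigmoid isolates the plasticity pathway
  base <- list(n_pc = 60, n_io = 6, divergence = 10, pool_size = 5,
               n_trials = 150, sigmoid_base = 0, sigmoid_amplitude = 0)
  s_on <- run_session(do.call(model_config, base), seed = 8)
  s_off <- run_session(do.call(model_config,
                               c(base, enable_plasticity = FALSE)), seed = 8)
  expect_identical(s_on$ss, s_off$ss)
  expect_equal(sum(s_on$cs), 0)
})

test_that("plasticity depresses firing on trials following a CS", {
  cfg <- small_config(n_trials = 600, p_off = 1)
  s <- run_session(cfg, seed = 21)
  after_cs <- s$cs[-nrow(s$cs), 1]
  next_rates <- s$ss[-1, 1]
  expect_gt(mean(next_rates[!after_cs]) - mean(next_rates[after_cs]), 2)
})

test_that("eye velocity is the scaled depression of the population mean", {
  expect_equal(eye_velocity(rep(100, 10), gain = 0.1), 0)
  expect_equal(eye_velocity(rep(95, 10), gain = 0.1), 0.5)
  expect_equal(eye_velocity(rnorm(10, 80), gain = 0), 0)
  # depressed firing maps to positive learned velocity
  expect_gt(eye_velocity(rep(90, 10), gain = 0.1), 0)
})

test_that("ablating the feedback fixes every olive neuron at the midpoint probability", {
  cfg <- small_config(enable_feedback = FALSE)
  s <- run_session(cfg, seed = 13)
  off <- s$direction == "off"
  expect_true(all(s$cs_prob[off, ] == 0.35))
})
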