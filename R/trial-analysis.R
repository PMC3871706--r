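#' Tag consecutive trial pairs by complex-spike occurrence
#'
#' Walks the stream of learning trials (per cell, when a `cell` column is
#' present) and tags every consecutive pair whose first ("instruction") trial
#' delivered an off-direction instruction with a two-character binary code: the
#' code `"1-0"`, for example, means the instruction trial contained a CS and
#' the test trial did not. Pairs overlap (a sliding window), and only pairs of
#' trials with consecutive `trial` indices are formed.
#'
#' @param data Data frame with columns `trial`, `direction` (`"off"`/`"on"`),
#'   `cs_flag` (logical), `ss_value` (spikes/s), optional `behavior_value` and
#'   optional `cell`.
#' @param require_test_off Additionally require the test trial to be
#'   off-direction (needed for the CS independence test).
#' @return Tibble with `cell` (if supplied), `instruction_trial`, `test_trial`,
#'   `code`, `d_ss` (test - instruction rate) and `d_behavior`.
#' @export
tag_pairs <- function(data, require_test_off = FALSE) {
  data <- check_trial_summary(data)
  has_cell <- attr(data, "has_cell")
  out <- data %>%
    group_by(.data$cell) %>%
    arrange(.data$trial, .by_group = TRUE) %>%
    mutate(
      nxt_trial = lead(.data$trial),
      nxt_dir = lead(.data$direction),
      nxt_cs = lead(.data$cs_flag),
      nxt_ss = lead(.data$ss_value),
      nxt_beh = lead(.data$behavior_value)
    ) %>%
    ungroup() %>%
    filter(
      !is.na(.data$nxt_trial),
      .data$nxt_trial == .data$trial + 1,
      .data$direction == "off",
      !require_test_off | .data$nxt_dir == "off"
    )
  out <- tibble(
    cell = out$cell,
    instruction_trial = out$trial,
    test_trial = out$nxt_trial,
    code = paste0(as.integer(out$cs_flag), "-", as.integer(out$nxt_cs)),
    d_ss = out$nxt_ss - out$ss_value,
    d_behavior = out$nxt_beh - out$behavior_value
  )
  if (nrow(out) == 0) warn("No eligible consecutive pairs found.")
  if (!has_cell) out$cell <- NULL
  out
}

# Coerce and validate a trial-summary table; adds `cell`/`behavior_value`
# placeholders when absent and records whether `cell` was supplied.
check_trial_summary <- function(data) {
  data <- as_tibble(data)
  needed <- c("trial", "direction", "cs_flag", "ss_value")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Trial summary is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!all(data$direction %in% c("off", "on"))) {
    abort("`direction` must be 'off' or 'on'.")
  }
  has_cell <- "cell" %in% names(data)
  if (!has_cell) data$cell <- 1L
  if (!"behavior_value" %in% names(data)) data$behavior_value <- NA_real_
  data$cs_flag <- as.logical(data$cs_flag)
  attr(data, "has_cell") <- has_cell
  data
}

pair_codes <- c("0-0", "0-1", "1-0", "1-1")

#' Trial-over-trial differences by pair code
#'
#' Summarises the trial-over-trial change in simple-spike rate (and behaviour)
#' for each CS pair code, averaging within cells first and then across cells,
#' with seeded bootstrap confidence intervals and one-sample t / Wilcoxon tests
#' per code. The plasticity estimate is `mean d('0-0') - mean d('1-1')`: since
#' both trials of a pair share the same CS status in those codes, same-trial
#' facilitation is nulled and the difference isolates the CS-linked
#' single-trial depression.
#'
#' @param data A trial-summary data frame (see [tag_pairs()]) or a
#'   `"pc_session"`, for which a fast matrix path is used.
#' @param require_test_off Restrict to pairs whose test trial is off-direction.
#' @param n_boot Bootstrap resamples for the CIs (0 skips the bootstrap). The
#'   resampling unit is the cell when several cells are present, otherwise the
#'   individual pair.
#' @param conf_level Confidence level for the bootstrap percentile intervals.
#' @param boot_seed Seed for the bootstrap (the global RNG state is restored
#'   afterwards); `NULL` uses the current stream.
#' @param ... Passed between methods.
#' @return A `"pc_pair_stats"` object; see [tidy.pc_pair_stats()].
#' @examples
#' s <- run_session(model_config(n_pc = 50, n_io = 5, n_trials = 60), seed = 2)
#' pd <- pair_differences(s, n_boot = 100)
#' tidy(pd)
#' glance(pd)
#' @export
pair_differences <- function(data, ...) UseMethod("pair_differences")

#' @rdname pair_differences
#' @export
pair_differences.data.frame <- function(data, require_test_off = FALSE,
                                        n_boot = 1000, conf_level = 0.95,
                                        boot_seed = 1, ...) {
  pairs <- tag_pairs(data, require_test_off)
  if (!"cell" %in% names(pairs)) pairs$cell <- 1L
  cell_means <- pairs %>%
    group_by(.data$cell, .data$code) %>%
    summarise(n = n(), m_ss = mean(.data$d_ss),
              m_beh = mean(.data$d_behavior), .groups = "drop")
  new_pair_stats(cell_means, pairs, require_test_off, n_boot, conf_level,
                 boot_seed)
}

#' @rdname pair_differences
#' @export
pair_differences.pc_session <- function(data, require_test_off = FALSE,
                                        n_boot = 1000, conf_level = 0.95,
                                        boot_seed = 1, ...) {
  cm <- session_pair_cell_means(data, require_test_off)
  new_pair_stats(cm$cell_means, cm$pairs_flat, require_test_off, n_boot,
                 conf_level, boot_seed)
}

# Matrix fast path: per-cell, per-code counts and mean differences.
session_pair_cell_means <- function(session, require_test_off) {
  n <- nrow(session$ss)
  D <- session$ss[-1, , drop = FALSE] - session$ss[-n, , drop = FALSE]
  Db <- session$eye_velocity[-1] - session$eye_velocity[-n]
  el <- session$direction[-n] == "off"
  if (require_test_off) el <- el & (session$direction[-1] == "off")
  c1 <- session$cs[-n, , drop = FALSE]
  c2 <- session$cs[-1, , drop = FALSE]
  masks <- list(
    "0-0" = el & !c1 & !c2, "0-1" = el & !c1 & c2,
    "1-0" = el & c1 & !c2, "1-1" = el & c1 & c2
  )
  cell_means <- purrr::map2_dfr(masks, names(masks), function(m, code) {
    cnt <- colSums(m)
    keep <- cnt > 0
    tibble(
      cell = which(keep), code = code, n = cnt[keep],
      m_ss = (colSums(D * m) / cnt)[keep],
      m_beh = (colSums(Db * m) / cnt)[keep]
    )
  }) %>% arrange(.data$cell, .data$code)
  list(cell_means = cell_means, pairs_flat = NULL)
}

new_pair_stats <- function(cell_means, pairs, require_test_off, n_boot,
                           conf_level, boot_seed) {
  multi_cell <- length(unique(cell_means$cell)) > 1
  boot_ci <- function(v) {
    if (n_boot <= 0 || length(v) < 2) return(c(NA_real_, NA_real_))
    bm <- vapply(seq_len(n_boot),
                 function(i) mean(sample(v, replace = TRUE)), numeric(1))
    unname(stats::quantile(bm, c((1 - conf_level) / 2,
                                 1 - (1 - conf_level) / 2)))
  }
  test_p <- function(v, f) {
    if (length(v) < 2 || sd(v) == 0) return(NA_real_)
    suppressWarnings(f(v)$p.value)
  }
  stats <- with_boot_seed(boot_seed, {
    purrr::map_dfr(pair_codes, function(cd) {
      cm <- cell_means[cell_means$code == cd, ]
      if (nrow(cm) == 0) {
        return(tibble(code = cd, n_pairs = 0L, n_cells = 0L,
                      mean_d_ss = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                      mean_d_behavior = NA_real_, p_t = NA_real_,
                      p_wilcoxon = NA_real_))
      }
      # unit of analysis: per-cell means across cells, or raw pairs for a
      # single unit
      v <- if (multi_cell || is.null(pairs)) {
        cm$m_ss
      } else {
        pairs$d_ss[pairs$code == cd]
      }
      ci <- boot_ci(v)
      tibble(
        code = cd,
        n_pairs = sum(cm$n),
        n_cells = nrow(cm),
        mean_d_ss = mean(cm$m_ss),
        ci_lo = ci[1], ci_hi = ci[2],
        mean_d_behavior = mean(cm$m_beh),
        p_t = test_p(v, t.test),
        p_wilcoxon = test_p(v, wilcox.test)
      )
    })
  })
  est <- stats$mean_d_ss[stats$code == "0-0"] -
    stats$mean_d_ss[stats$code == "1-1"]
  structure(
    list(stats = stats, cell_means = cell_means,
         plasticity_estimate = est,
         require_test_off = require_test_off,
         n_boot = n_boot, conf_level = conf_level),
    class = "pc_pair_stats"
  )
}

# Run `expr` under a temporary seed, restoring the global RNG state.
with_boot_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

#' @export
print.pc_pair_stats <- function(x, ...) {
  cat("<pc_pair_stats> trial-over-trial differences by CS pair code\n")
  print(as.data.frame(x$stats), row.names = FALSE, digits = 3)
  cat(sprintf("plasticity estimate (d '0-0' - d '1-1'): %s spikes/s\n",
              format(x$plasticity_estimate, digits = 3)))
  invisible(x)
}

#' Tidy a pair-difference result
#'
#' @param x A `"pc_pair_stats"` object.
#' @param ... Unused.
#' @return Per-code tibble: `code`, `n_pairs`, `n_cells`, `mean_d_ss`,
#'   bootstrap `ci_lo`/`ci_hi`, `mean_d_behavior`, `p_t`, `p_wilcoxon`. Codes
#'   with no pairs appear with `n_pairs = 0` and `NA` statistics.
#' @export
tidy.pc_pair_stats <- function(x, ...) x$stats

#' @describeIn tidy.pc_pair_stats One-row summary with the plasticity
#'   estimate.
#' @export
glance.pc_pair_stats <- function(x, ...) {
  tibble(
    plasticity_estimate = x$plasticity_estimate,
    n_pairs = sum(x$stats$n_pairs),
    n_codes_present = sum(x$stats$n_pairs > 0),
    n_cells = max(x$stats$n_cells),
    require_test_off = x$require_test_off
  )
}

#' Tag consecutive trial trios by complex-spike occurrence
#'
#' Forms all trios of consecutive trials whose first two trials delivered
#' off-direction instructions and tags each with a three-character binary code
#' of CS occurrence (e.g. `"0-0-1"`).
#'
#' @inheritParams tag_pairs
#' @return Tibble with `cell` (if supplied), trial indices `t1`-`t3`, `code`,
#'   and the three rates `ss1`-`ss3`.
#' @export
tag_trios <- function(data) {
  data <- check_trial_summary(data)
  has_cell <- attr(data, "has_cell")
  out <- data %>%
    group_by(.data$cell) %>%
    arrange(.data$trial, .by_group = TRUE) %>%
    mutate(
      t2 = lead(.data$trial), t3 = lead(.data$trial, 2),
      d2 = lead(.data$direction),
      c2 = lead(.data$cs_flag), c3 = lead(.data$cs_flag, 2),
      s2 = lead(.data$ss_value), s3 = lead(.data$ss_value, 2)
    ) %>%
    ungroup() %>%
    filter(
      !is.na(.data$t3),
      .data$t2 == .data$trial + 1, .data$t3 == .data$trial + 2,
      .data$direction == "off", .data$d2 == "off"
    )
  res <- tibble(
    cell = out$cell, t1 = out$trial, t2 = out$t2, t3 = out$t3,
    code = paste(as.integer(out$cs_flag), as.integer(out$c2),
                 as.integer(out$c3), sep = "-"),
    ss1 = out$ss_value, ss2 = out$s2, ss3 = out$s3
  )
  if (!has_cell) res$cell <- NULL
  res
}

#' Mean firing rate by position within CS-coded trial trios
#'
#' For each trio code of interest, computes the mean simple-spike rate on the
#' first, second and third trial (within cells first, then across cells), and
#' contrasts third-trial rates between codes with matched CS history
#' (`"0-0-1"` vs `"0-0-0"` and `"1-0-1"` vs `"1-0-0"`): a higher third-trial
#' rate when the third trial carries a CS is the signature of same-trial
#' facilitation.
#'
#' @inheritParams tag_pairs
#' @param codes Trio codes to summarise.
#' @param min_count Minimum trios per (cell, code) for that cell to contribute.
#' @return A `"pc_trios"` object; `tidy()` gives per-(code, position) means,
#'   `glance()` the matched-history contrasts.
#' @export
trio_position_means <- function(data,
                                codes = c("0-0-0", "0-0-1", "1-0-0", "1-0-1"),
                                min_count = 3) {
  trios <- tag_trios(data)
  if (!"cell" %in% names(trios)) trios$cell <- 1L
  cellwise <- trios %>%
    filter(.data$code %in% codes) %>%
    group_by(.data$cell, .data$code) %>%
    summarise(n = n(), m1 = mean(.data$ss1), m2 = mean(.data$ss2),
              m3 = mean(.data$ss3), .groups = "drop") %>%
    filter(.data$n >= min_count)
  means <- cellwise %>%
    group_by(.data$code) %>%
    summarise(
      n_trios = sum(.data$n), n_cells = n(),
      across(c("m1", "m2", "m3"), mean), .groups = "drop"
    ) %>%
    tidyr::pivot_longer(c("m1", "m2", "m3"), names_to = "position",
                        values_to = "mean_ss") %>%
    mutate(position = as.integer(sub("m", "", .data$position)))
  contrast <- function(code_a, code_b) {
    wide <- cellwise %>%
      filter(.data$code %in% c(code_a, code_b)) %>%
      select("cell", "code", "m3") %>%
      tidyr::pivot_wider(names_from = "code", values_from = "m3") %>%
      tidyr::drop_na()
    if (nrow(wide) == 0) {
      return(tibble(comparison = paste(code_a, "vs", code_b),
                    estimate = NA_real_, p_value = NA_real_, n_cells = 0L))
    }
    d <- wide[[code_a]] - wide[[code_b]]
    p <- if (length(d) >= 2 && sd(d) > 0) t.test(d)$p.value else NA_real_
    tibble(comparison = paste(code_a, "vs", code_b),
           estimate = mean(d), p_value = p, n_cells = length(d))
  }
  contrasts <- bind_rows(contrast("0-0-1", "0-0-0"),
                         contrast("1-0-1", "1-0-0"))
  structure(list(means = means, contrasts = contrasts, cellwise = cellwise,
                 min_count = min_count),
            class = "pc_trios")
}

#' @export
print.pc_trios <- function(x, ...) {
  cat("<pc_trios> mean rate by trio code and position\n")
  print(as.data.frame(x$means), row.names = FALSE, digits = 4)
  cat("third-trial contrasts (matched CS history):\n")
  print(as.data.frame(x$contrasts), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
tidy.pc_trios <- function(x, ...) x$means

#' @export
glance.pc_trios <- function(x, ...) {
  est <- stats::setNames(x$contrasts$estimate, x$contrasts$comparison)
  tibble(
    facilitation_001_000 = est[["0-0-1 vs 0-0-0"]],
    p_001_000 = x$contrasts$p_value[1],
    facilitation_101_100 = est[["1-0-1 vs 1-0-0"]],
    p_101_100 = x$contrasts$p_value[2],
    n_cells = max(x$contrasts$n_cells)
  )
}

#' Same-trial facilitation by firing-rate terciles
#'
#' Per cell, trisects the distribution of trial rates at the mean plus/minus
#' `z` standard deviations (the default `z = 0.44` makes the three segments
#' equally occupied for a normal distribution), computes the CS probability in
#' each segment, and fits a line through the three (mean rate, CS probability)
#' points. The slope measures how strongly the trial's firing rate at
#' instruction time predicts a CS response later in the same trial.
#'
#' @inheritParams pair_differences
#' @param off_direction_only Use only off-direction trials (CS responses are
#'   only evoked there).
#' @param z Trisection half-width in standard deviations.
#' @param min_trials Minimum eligible trials per cell; cells below the floor
#'   are dropped with a warning.
#' @return A `"pc_terciles"` object; `tidy()` gives per-(cell, segment) rows,
#'   `glance()` the mean slope and the pooled point correlation.
#' @examples
#' s <- run_session(model_config(n_pc = 50, n_io = 5, n_trials = 200), seed = 3)
#' glance(facilitation_terciles(s))
#' @export
facilitation_terciles <- function(data, ...) UseMethod("facilitation_terciles")

#' @rdname facilitation_terciles
#' @export
facilitation_terciles.data.frame <- function(data, off_direction_only = TRUE,
                                             z = 0.44, min_trials = 30, ...) {
  data <- check_trial_summary(data)
  if (off_direction_only) data <- filter(data, .data$direction == "off")
  counts <- count(data, .data$cell)
  low <- counts$cell[counts$n < min_trials]
  if (length(low) > 0) {
    warn(sprintf("Dropping %d cell(s) with fewer than %d eligible trials.",
                 length(low), min_trials))
    data <- filter(data, !.data$cell %in% low)
  }
  if (nrow(data) == 0) abort("No cells with enough eligible trials.")
  zero_sd <- data %>%
    group_by(.data$cell) %>%
    summarise(s = sd(.data$ss_value), .groups = "drop")
  if (any(zero_sd$s == 0)) {
    abort(sprintf("Degenerate rate distribution (sd = 0) for cell(s): %s.",
                  paste(zero_sd$cell[zero_sd$s == 0], collapse = ", ")))
  }
  segments <- data %>%
    group_by(.data$cell) %>%
    mutate(segment = cut(.data$ss_value,
                         c(-Inf, mean(.data$ss_value) - z * sd(.data$ss_value),
                           mean(.data$ss_value) + z * sd(.data$ss_value), Inf),
                         labels = c("low", "mid", "high"))) %>%
    group_by(.data$cell, .data$segment) %>%
    summarise(n = n(), mean_ss = mean(.data$ss_value),
              cs_prob = mean(.data$cs_flag), .groups = "drop")
  new_terciles(segments, z)
}

#' @rdname facilitation_terciles
#' @export
facilitation_terciles.pc_session <- function(data, off_direction_only = TRUE,
                                             z = 0.44, min_trials = 30, ...) {
  keep <- if (off_direction_only) data$direction == "off" else
    rep(TRUE, length(data$direction))
  if (sum(keep) < min_trials) abort("No cells with enough eligible trials.")
  R <- data$ss[keep, , drop = FALSE]
  C <- data$cs[keep, , drop = FALSE] * 1
  mu <- colMeans(R)
  sdv <- apply(R, 2, sd)
  if (any(sdv == 0)) {
    abort(sprintf("Degenerate rate distribution (sd = 0) for cell(s): %s.",
                  paste(which(sdv == 0), collapse = ", ")))
  }
  lo <- matrix(mu - z * sdv, nrow(R), ncol(R), byrow = TRUE)
  hi <- matrix(mu + z * sdv, nrow(R), ncol(R), byrow = TRUE)
  segs <- list(low = R < lo, mid = R >= lo & R <= hi, high = R > hi)
  segments <- purrr::map2_dfr(segs, names(segs), function(m, lab) {
    cnt <- colSums(m)
    tibble(cell = seq_len(ncol(R)), segment = lab, n = cnt,
           mean_ss = colSums(R * m) / cnt, cs_prob = colSums(C * m) / cnt)
  }) %>%
    mutate(segment = factor(.data$segment, c("low", "mid", "high"))) %>%
    arrange(.data$cell, .data$segment)
  new_terciles(segments, z)
}

new_terciles <- function(segments, z) {
  slopes <- segments %>%
    group_by(.data$cell) %>%
    summarise(
      slope = {
        x <- .data$mean_ss - mean(.data$mean_ss)
        y <- .data$cs_prob - mean(.data$cs_prob)
        sum(x * y) / sum(x^2)
      },
      .groups = "drop"
    )
  structure(
    list(segments = segments, slopes = slopes, z = z,
         mean_slope = mean(slopes$slope),
         point_correlation = cor(segments$mean_ss, segments$cs_prob)),
    class = "pc_terciles"
  )
}

#' @export
print.pc_terciles <- function(x, ...) {
  cat(sprintf(
    "<pc_terciles> %d cell(s), trisection at mean +/- %g sd\n",
    nrow(x$slopes), x$z))
  occ <- x$segments %>%
    group_by(.data$segment) %>%
    summarise(mean_ss = mean(.data$mean_ss), cs_prob = mean(.data$cs_prob),
              frac = sum(.data$n), .groups = "drop") %>%
    mutate(frac = .data$frac / sum(.data$frac))
  print(as.data.frame(occ), row.names = FALSE, digits = 3)
  cat(sprintf("mean slope: %s CS probability per spike/s; point r = %s\n",
              format(x$mean_slope, digits = 3),
              format(x$point_correlation, digits = 3)))
  invisible(x)
}

#' @export
tidy.pc_terciles <- function(x, ...) x$segments

#' @export
glance.pc_terciles <- function(x, ...) {
  tibble(
    n_cells = nrow(x$slopes),
    mean_slope = x$mean_slope,
    median_slope = stats::median(x$slopes$slope),
    point_correlation = x$point_correlation,
    z = x$z
  )
}

#' Test whether complex spikes on consecutive trials occur independently
#'
#' Restricts to pairs of consecutive off-direction instructions and compares,
#' per cell, the observed probability of `"1-1"` pairs with the prediction
#' under independence (the squared marginal CS probability on off-direction
#' trials), and likewise `"1-0"` against `p * (1 - p)`. A paired two-tailed
#' t-test across cells (or runs) assesses the deficit: trial-over-trial
#' depression after a CS lowers the next trial's CS probability, so the
#' observed `"1-1"` rate falls below the independent prediction.
#'
#' @inheritParams pair_differences
#' @return A `"pc_independence"` object; `tidy()` gives per-cell rows,
#'   `glance()` pooled means and test p-values.
#' @export
independence_test <- function(data, ...) UseMethod("independence_test")

#' @rdname independence_test
#' @export
independence_test.data.frame <- function(data, ...) {
  data <- check_trial_summary(data)
  pairs <- tag_pairs(data, require_test_off = TRUE)
  if (!"cell" %in% names(pairs)) pairs$cell <- 1L
  marg <- data %>%
    filter(.data$direction == "off") %>%
    group_by(.data$cell) %>%
    summarise(p_cs = mean(.data$cs_flag), .groups = "drop")
  per_cell <- pairs %>%
    group_by(.data$cell) %>%
    summarise(
      n_pairs = n(),
      obs_11 = mean(.data$code == "1-1"),
      obs_10 = mean(.data$code == "1-0"),
      .groups = "drop"
    ) %>%
    left_join(marg, by = "cell") %>%
    mutate(pred_11 = .data$p_cs^2,
           pred_10 = .data$p_cs * (1 - .data$p_cs))
  new_independence(per_cell)
}

#' @rdname independence_test
#' @export
independence_test.pc_session <- function(data, ...) {
  n <- nrow(data$ss)
  el <- data$direction[-n] == "off" & data$direction[-1] == "off"
  if (!any(el)) abort("No consecutive off-off trial pairs in the session.")
  c1 <- data$cs[-n, , drop = FALSE][el, , drop = FALSE]
  c2 <- data$cs[-1, , drop = FALSE][el, , drop = FALSE]
  off <- data$direction == "off"
  p_cs <- colMeans(data$cs[off, , drop = FALSE])
  per_cell <- tibble(
    cell = seq_len(ncol(data$ss)),
    n_pairs = sum(el),
    obs_11 = colMeans(c1 & c2),
    obs_10 = colMeans(c1 & !c2),
    p_cs = p_cs,
    pred_11 = p_cs^2,
    pred_10 = p_cs * (1 - p_cs)
  )
  new_independence(per_cell)
}

new_independence <- function(per_cell) {
  paired_p <- function(a, b) {
    if (nrow(per_cell) < 2) return(NA_real_)
    d <- a - b
    if (sd(d) == 0) return(NA_real_)
    t.test(a, b, paired = TRUE)$p.value
  }
  structure(
    list(
      per_cell = per_cell,
      observed_11 = mean(per_cell$obs_11),
      predicted_11 = mean(per_cell$pred_11),
      observed_10 = mean(per_cell$obs_10),
      predicted_10 = mean(per_cell$pred_10),
      p_value_11 = paired_p(per_cell$obs_11, per_cell$pred_11),
      p_value_10 = paired_p(per_cell$obs_10, per_cell$pred_10),
      n_units = nrow(per_cell)
    ),
    class = "pc_independence"
  )
}

#' @export
print.pc_independence <- function(x, ...) {
  cat(sprintf("<pc_independence> %d unit(s), %d off-off pairs each (max)\n",
              x$n_units, max(x$per_cell$n_pairs)))
  cat(sprintf("  '1-1': observed %.4f vs independent %.4f (p = %s)\n",
              x$observed_11, x$predicted_11, format(x$p_value_11, digits = 3)))
  cat(sprintf("  '1-0': observed %.4f vs independent %.4f (p = %s)\n",
              x$observed_10, x$predicted_10, format(x$p_value_10, digits = 3)))
  invisible(x)
}

#' @export
tidy.pc_independence <- function(x, ...) x$per_cell

#' @export
glance.pc_independence <- function(x, ...) {
  tibble(
    observed_11 = x$observed_11, predicted_11 = x$predicted_11,
    observed_10 = x$observed_10, predicted_10 = x$predicted_10,
    p_value_11 = x$p_value_11, p_value_10 = x$p_value_10,
    n_units = x$n_units
  )
}
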