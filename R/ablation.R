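#' Named ablation variants of the circuit model
#'
#' The sensitivity suite removes one mechanism at a time from the full model:
#' \describe{
#'   \item{FULL}{the unmodified configuration;}
#'   \item{NO_plast}{no CS-linked trial-over-trial plasticity;}
#'   \item{NO_SStoCS}{no simple-spike -> olive feedback (every olive neuron
#'     sees the constant midpoint drive);}
#'   \item{SS_r0}{no neuron-neuron correlation in simple-spike firing
#'     (`r_nn = 0`);}
#'   \item{CS_r0}{no synchrony across olive neurons (`R_CS` fixed at 1);}
#'   \item{SSCS_r0}{both correlations removed;}
#'   \item{F1, F20, F1000}{olive fan-in of 1, 20, or the whole population
#'     (capped at `n_pc` for smaller circuits).}
#' }
#'
#' @return Character vector of variant names.
#' @export
ablation_variants <- function() {
  c("FULL", "NO_plast", "NO_SStoCS", "SSCS_r0", "SS_r0", "CS_r0",
    "F1", "F20", "F1000")
}

#' Build the configuration for a named ablation variant
#'
#' @param base A [model_config()] used as the FULL reference.
#' @param name One of [ablation_variants()].
#' @return The transformed `"pc_config"`.
#' @examples
#' make_variant_config(model_config(), "SS_r0")$r_nn
#' @export
make_variant_config <- function(base, name) {
  if (!name %in% ablation_variants()) {
    abort(sprintf("Unknown variant '%s'. Valid names: %s.", name,
                  paste(ablation_variants(), collapse = ", ")))
  }
  cfg <- base
  switch(
    name,
    FULL = {},
    NO_plast = cfg$enable_plasticity <- FALSE,
    NO_SStoCS = cfg$enable_feedback <- FALSE,
    SS_r0 = {
      cfg$r_nn <- 0
      cfg$enable_ss_corr <- FALSE
    },
    CS_r0 = cfg$enable_cs_corr <- FALSE,
    SSCS_r0 = {
      cfg$r_nn <- 0
      cfg$enable_ss_corr <- FALSE
      cfg$enable_cs_corr <- FALSE
    },
    F1 = cfg$pool_size <- 1L,
    F20 = cfg$pool_size <- min(20L, cfg$n_pc),
    F1000 = cfg$pool_size <- min(1000L, cfg$n_pc)
  )
  validate_model_config(cfg)
}

#' Run the model-ablation sensitivity suite
#'
#' Runs each requested variant `n_runs` times with deterministically derived
#' child seeds, and collects the per-pair-code trial-over-trial amplitudes of
#' simple-spike firing (`d_ss`, averaged within cells then across cells) and
#' eye velocity (`d_behavior`) from every run.
#'
#' @param base_config The FULL-model [model_config()].
#' @param n_runs Runs per variant.
#' @param variants Subset of [ablation_variants()] to run.
#' @param seed Master seed from which per-(variant, run) child seeds are drawn.
#' @return A `"pc_ablation"` object; `tidy()` gives the long per-run table
#'   (`variant`, `run`, `seed`, `code`, `n_pairs`, `d_ss`, `d_behavior`),
#'   `summary()`/`glance()` per-variant aggregates.
#' @examples
#' \donttest{
#' ab <- run_ablation_suite(model_config(n_pc = 100, n_io = 10, n_trials = 200),
#'                          n_runs = 2, variants = c("FULL", "NO_plast"),
#'                          seed = 1)
#' tidy(ab)
#' }
#' @export
run_ablation_suite <- function(base_config = model_config(), n_runs = 20,
                               variants = ablation_variants(), seed = 1) {
  variants <- vapply(variants, function(v) {
    if (!v %in% ablation_variants()) {
      abort(sprintf("Unknown variant '%s'. Valid names: %s.", v,
                    paste(ablation_variants(), collapse = ", ")))
    }
    v
  }, character(1), USE.NAMES = FALSE)
  set.seed(seed)
  child_seeds <- matrix(
    sample.int(.Machine$integer.max, length(variants) * n_runs),
    nrow = length(variants), dimnames = list(variants, NULL)
  )
  results <- purrr::map_dfr(variants, function(v) {
    cfg <- make_variant_config(base_config, v)
    purrr::map_dfr(seq_len(n_runs), function(r) {
      s <- run_session(cfg, seed = child_seeds[v, r])
      pd <- pair_differences(s, n_boot = 0)
      st <- tidy(pd)
      tibble(variant = v, run = r, seed = child_seeds[v, r],
             code = st$code, n_pairs = st$n_pairs,
             d_ss = st$mean_d_ss, d_behavior = st$mean_d_behavior)
    })
  })
  structure(
    list(results = results, n_runs = n_runs, master_seed = seed,
         child_seeds = child_seeds, base_config = base_config),
    class = "pc_ablation"
  )
}

#' @export
print.pc_ablation <- function(x, ...) {
  cat(sprintf("<pc_ablation> %d variant(s) x %d run(s), master seed %d\n",
              nrow(x$child_seeds), x$n_runs, x$master_seed))
  print(as.data.frame(summary(x)), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
tidy.pc_ablation <- function(x, ...) x$results

#' Per-variant aggregates of an ablation suite
#'
#' @param object A `"pc_ablation"`.
#' @param ... Unused.
#' @return Tibble per (variant, code): across-run mean and sd of `d_ss` and
#'   `d_behavior`, and the across-run mean plasticity estimate
#'   (`d('0-0') - d('1-1')`) per variant.
#' @export
summary.pc_ablation <- function(object, ...) {
  per_run <- object$results %>%
    filter(.data$code %in% c("0-0", "1-1")) %>%
    select("variant", "run", "code", "d_ss") %>%
    tidyr::pivot_wider(names_from = "code", values_from = "d_ss") %>%
    mutate(plasticity_estimate = .data$`0-0` - .data$`1-1`) %>%
    group_by(.data$variant) %>%
    summarise(plasticity_estimate = mean(.data$plasticity_estimate,
                                         na.rm = TRUE),
              .groups = "drop")
  object$results %>%
    group_by(.data$variant, .data$code) %>%
    summarise(
      n_runs = n(),
      mean_d_ss = mean(.data$d_ss, na.rm = TRUE),
      sd_d_ss = sd(.data$d_ss, na.rm = TRUE),
      mean_d_behavior = mean(.data$d_behavior, na.rm = TRUE),
      sd_d_behavior = sd(.data$d_behavior, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    left_join(per_run, by = "variant")
}

#' @export
glance.pc_ablation <- function(x, ...) {
  tibble(
    n_variants = nrow(x$child_seeds),
    n_runs = x$n_runs,
    master_seed = x$master_seed,
    n_rows = nrow(x$results)
  )
}
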