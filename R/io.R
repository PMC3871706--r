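#' Load a model configuration from YAML
#'
#' Reads a YAML file of [model_config()] fields, fills unspecified fields with
#' the defaults, and validates the result. Unknown keys are rejected with a
#' message naming them; an empty file yields the default configuration.
#'
#' @param path Path to a YAML file.
#' @return A validated `"pc_config"`.
#' @seealso [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(model_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config key(s): %s.", paste(unknown, collapse = ", ")))
  }
  do.call(model_config, vals)
}

#' Write a model configuration to YAML
#'
#' @param config A `"pc_config"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_model_config(config)
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Write a per-trial summary table to CSV
#'
#' One row per trial (and per cell, when present): `trial`, `direction`,
#' `cs_flag`, `ss_value`, `behavior_value` in long/tidy form, UTF-8, `.`
#' decimal.
#'
#' @param data A trial-summary data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_summary <- function(data, path) {
  data <- check_trial_summary(data)
  if (!attr(data, "has_cell")) data$cell <- NULL
  readr::write_csv(as_tibble(data), path)
  invisible(path)
}

#' Read a per-trial summary table from CSV
#'
#' @param path Path to a CSV written by [write_trial_summary()] or with the
#'   same columns.
#' @return Validated trial-summary tibble.
#' @export
read_trial_summary <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  data <- check_trial_summary(data)
  if (!attr(data, "has_cell")) data$cell <- NULL
  attr(data, "has_cell") <- NULL
  as_tibble(data)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-exactly: the package
#' version, the configuration snapshot, the master seed and any child seeds,
#' and an inventory of the run's output files with MD5 checksums. Missing
#' files are flagged rather than silently skipped.
#'
#' @param path Manifest destination (JSON).
#' @param config The `"pc_config"` used.
#' @param seed Master seed of the run.
#' @param files Character vector of output file paths to inventory.
#' @param child_seeds Optional named vector/list of derived seeds.
#' @return The manifest as a list, invisibly.
#' @seealso [read_run_manifest()]
#' @export
write_run_manifest <- function(path, config, seed, files = character(),
                               child_seeds = NULL) {
  validate_model_config(config)
  inventory <- lapply(files, function(f) {
    ok <- file.exists(f)
    list(
      path = f,
      exists = ok,
      md5 = if (ok) unname(tools::md5sum(f)) else NA_character_
    )
  })
  manifest <- list(
    package = "cerelearn",
    version = as.character(utils::packageVersion("cerelearn")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    child_seeds = child_seeds,
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    files = inventory
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}

#' Read a run manifest
#'
#' @param path Path to a manifest written by [write_run_manifest()].
#' @return List with the manifest contents; `config` is re-validated into a
#'   `"pc_config"`.
#' @export
read_run_manifest <- function(path) {
  m <- jsonlite::read_json(path)
  m$config <- do.call(model_config, m$config)
  m
}
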