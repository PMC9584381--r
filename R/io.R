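#' Read and write long-format trial tables
#'
#' The on-disk dialect is plain CSV, one row per trial, with the columns
#' produced by [simulate_subject()] (`subject_id`, `stage`, `block`,
#' `trial`, `instrumental_stimulus`, `pavlovian_stimulus`, `cs_left`,
#' `cs_right`, `action`, `keypresses`, `feedback`, `rewarded`, optionally
#' `group`). Missing entries are empty fields.
#'
#' @param trials A trial tibble.
#' @param path File path.
#' @return `read_trials()` returns a tibble; `write_trials()` returns the
#'   path invisibly.
#' @export
write_trials <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  df$block <- as.integer(df$block)
  df$keypresses <- as.integer(df$keypresses)
  df$feedback <- as.integer(df$feedback)
  if ("rewarded" %in% names(df)) df$rewarded <- as.logical(df$rewarded)
  tibble::as_tibble(df)
}

#' Read and write a task configuration as YAML
#'
#' @param config A [task_config()].
#' @param path File path.
#' @return `read_task_config()` returns a validated `pit_task_config`.
#' @export
write_task_config <- function(config, path) {
  validate_task_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_task_config
#' @export
read_task_config <- function(path) {
  do.call(task_config, yaml::read_yaml(path))
}

#' Tidy per-subject parameter table from a fit
#'
#' @param fit A [em_fit()] result.
#' @return Tibble with columns `subject_id`, `model`, `parameter`,
#'   `unconstrained`, `natural`.
#' @export
parameter_table <- function(fit) {
  spec <- fit$spec
  dplyr::bind_rows(lapply(names(fit$subject_fits), function(id) {
    th <- fit$subject_fits[[id]]$theta_map
    tibble::tibble(subject_id = id, model = spec$id,
                   parameter = spec$parameters,
                   unconstrained = unname(th),
                   natural = unname(to_natural(th, spec)))
  }))
}

#' Serialize a fit to JSON
#'
#' Writes the group prior, per-subject MAP estimates in both spaces, and
#' fitting diagnostics (log-likelihood, log-posterior, convergence flags,
#' EM trace) to a JSON file.
#'
#' @param fit A [em_fit()] result.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_fit <- function(fit, path) {
  spec <- fit$spec
  payload <- list(
    model = spec$id,
    parameters = spec$parameters,
    group_prior = list(mean = as.list(fit$group_prior$mean),
                       variance = as.list(fit$group_prior$variance)),
    em_iterations = fit$em_iterations,
    em_trace = fit$em_trace,
    converged = fit$converged,
    subjects = lapply(fit$subject_fits, function(f) {
      list(theta_unconstrained = as.list(f$theta_map),
           theta_natural = as.list(to_natural(f$theta_map, spec)),
           log_likelihood = f$log_likelihood,
           log_posterior = f$log_posterior,
           converged = f$converged,
           hessian_jitter = f$hessian_jitter)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
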