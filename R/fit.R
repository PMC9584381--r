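#' Group-level Gaussian prior
#'
#' Independent per-parameter Gaussians on the unconstrained scale (the
#' diagonal covariance matches the evidence penalty of one mean and one
#' variance per parameter).
#'
#' @param mean,variance Numeric vectors, one entry per model parameter.
#' @param parameters Optional parameter names.
#' @return List of class `pit_group_prior`.
#' @export
group_prior <- function(mean, variance, parameters = names(mean)) {
  if (length(mean) != length(variance)) stop("mean and variance lengths differ", call. = FALSE)
  if (any(!is.finite(mean)) || any(!is.finite(variance)) || any(variance <= 0)) {
    stop("prior variances must be positive and finite", call. = FALSE)
  }
  structure(list(mean = stats::setNames(as.numeric(mean), parameters),
                 variance = stats::setNames(as.numeric(variance), parameters)),
            class = "pit_group_prior")
}

#' Wide initial group prior for a model
#'
#' The uninformed starting prior of the hierarchical fit: every parameter is
#' N(0, 10) on the unconstrained scale, wide enough to leave the first MAP
#' pass essentially likelihood-driven.
#'
#' @param spec A [model_spec()].
#' @param mean,variance Scalars recycled over the model's parameters.
#' @return A [group_prior()].
#' @export
default_group_prior <- function(spec, mean = 0, variance = 10) {
  group_prior(rep(mean, spec$d), rep(variance, spec$d), spec$parameters)
}

# Negative log-posterior closure over one subject's encoded data.
make_nlp <- function(spec, trials, prior, carryover) {
  if (spec$stage == "instrumental") {
    enc <- encode_instrumental(trials)
    loglik <- function(theta) {
      nat <- to_natural(theta, spec)
      instr_replay_cpp(canonical_instrumental(spec, nat),
                       enc$stim, enc$action, enc$feedback)$loglik
    }
  } else if (spec$stage == "joint") {
    instr <- trials[trials$stage == "instrumental", , drop = FALSE]
    pit <- trials[trials$stage == "pit", , drop = FALSE]
    enc <- encode_instrumental(instr)
    encp <- encode_pit(pit)
    loglik <- function(theta) {
      nat <- to_natural(theta, spec)
      can <- canonical_instrumental(spec, nat)
      rep <- instr_replay_cpp(can, enc$stim, enc$action, enc$feedback)
      tr <- canonical_transfer(spec, nat)
      rep$loglik + pit_loglik_cpp(tr[1:3], tr[["alpha"]], tr[5:6], rep$Q,
                                  can[["b"]], encp$stim, encp$cue, encp$action)
    }
  } else {
    if (is.null(carryover)) stop("transfer fits need carryover values", call. = FALSE)
    enc <- encode_pit(trials)
    Q <- carryover$Q
    bias <- carryover$bias
    loglik <- function(theta) {
      tr <- canonical_transfer(spec, to_natural(theta, spec))
      pit_loglik_cpp(tr[1:3], tr[["alpha"]], tr[5:6], Q, bias,
                     enc$stim, enc$cue, enc$action)
    }
  }
  m <- prior$mean
  sdv <- sqrt(prior$variance)
  list(
    loglik = loglik,
    nlp = function(theta) {
      -loglik(theta) - sum(dnorm(theta, m, sdv, log = TRUE))
    }
  )
}

# Symmetrize and, if needed, jitter a Hessian to positive definiteness.
regularize_hessian <- function(H) {
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  jitter <- 0
  if (min(ev) <= 1e-8) {
    jitter <- abs(min(ev)) + 1e-6
    H <- H + diag(jitter, nrow(H))
  }
  attr(H, "jitter") <- jitter
  H
}

#' Maximum a posteriori fit for one subject
#'
#' Maximizes choice log-likelihood plus Gaussian log-prior over the
#' unconstrained parameters with a derivative-based quasi-Newton optimizer
#' (BFGS, finite-difference gradients), keeping the best of several
#' restarts: the first restart starts at the prior mean, the rest are drawn
#' from the prior. The Hessian of the negative log-posterior at the optimum
#' is computed by central finite differences and regularized to positive
#' definiteness by minimal diagonal jitter when necessary.
#'
#' @param trials One subject's trial table (rows of the model's stage).
#' @param spec A [model_spec()].
#' @param prior A [group_prior()] (defaults to the wide N(0, 10) prior).
#' @param carryover For two-stage transfer models, the frozen end-of-training
#'   values from [carryover_values()].
#' @param n_restarts Number of optimizer restarts.
#' @param maxit Iteration cap per restart.
#' @param start Optional warm-start point used in place of the prior mean
#'   for the first restart (the EM loop passes the previous iteration's
#'   estimate).
#' @return List of class `pit_subject_fit`: `theta_map`, `hessian` (of the
#'   negative log-posterior, regularized), `log_posterior`,
#'   `log_likelihood`, `n_restarts_used`, `converged`, `hessian_jitter`.
#' @export
map_fit <- function(trials, spec, prior = default_group_prior(spec),
                    carryover = NULL, n_restarts = 10, maxit = 500,
                    start = NULL) {
  obj <- make_nlp(spec, trials, prior, carryover)
  d <- spec$d
  best <- NULL
  any_conv <- FALSE
  for (k in seq_len(max(1L, n_restarts))) {
    p0 <- if (k == 1L) {
      if (is.null(start)) prior$mean else start
    } else {
      rnorm(d, prior$mean, sqrt(prior$variance))
    }
    res <- tryCatch(
      optim(p0, obj$nlp, method = "BFGS", control = list(maxit = maxit)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    any_conv <- any_conv || res$convergence == 0L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    warning("optimization failed on every restart; subject flagged and excluded from group updates")
    return(structure(list(
      theta_map = stats::setNames(prior$mean, spec$parameters),
      hessian = diag(1 / prior$variance, d),
      log_posterior = NA_real_, log_likelihood = NA_real_,
      n_restarts_used = max(1L, n_restarts), converged = FALSE,
      hessian_jitter = 0
    ), class = "pit_subject_fit"))
  }
  theta <- stats::setNames(best$par, spec$parameters)
  H <- regularize_hessian(pracma::hessian(obj$nlp, theta))
  dimnames(H) <- list(spec$parameters, spec$parameters)
  structure(list(
    theta_map = theta,
    hessian = H,
    log_posterior = -best$value,
    log_likelihood = obj$loglik(theta),
    n_restarts_used = max(1L, n_restarts),
    converged = any_conv,
    hessian_jitter = attr(H, "jitter")
  ), class = "pit_subject_fit")
}

#' EM update of the group prior
#'
#' Laplace/EM moment update with the subject parameters as latent variables:
#' the new group mean is the average MAP estimate; the new variance is the
#' average second moment (squared MAP estimate plus the corresponding
#' diagonal of the inverse Hessian, the Laplace posterior variance) minus
#' the squared mean, floored at `var_floor`.
#'
#' @param fits List of [map_fit()] results (>= 2 usable subjects).
#' @param var_floor Lower bound on the updated variances.
#' @return A [group_prior()].
#' @export
em_update_group <- function(fits, var_floor = 1e-6) {
  fits <- Filter(function(f) isTRUE(is.finite(f$log_posterior)), fits)
  if (length(fits) < 2) stop("need at least two usable subject fits", call. = FALSE)
  th <- do.call(rbind, lapply(fits, `[[`, "theta_map"))
  hinv <- do.call(rbind, lapply(fits, function(f) {
    diag(solve(f$hessian))
  }))
  m <- colMeans(th)
  v <- pmax(colMeans(th^2 + hinv) - m^2, var_floor)
  group_prior(m, v, colnames(th))
}

#' Hierarchical MAP/EM fit of a cohort
#'
#' Alternates per-subject MAP estimation (under the current group prior)
#' with the EM update of the group mean and variance, starting from the wide
#' N(0, 10) prior, until the relative change in the summed log-posterior
#' falls below `tol` or `max_iter` is reached. All subjects — regardless of
#' any group labels in the data — share the single uninformed prior, so
#' between-group parameter contrasts downstream are not biased by separate
#' shrinkage targets. With `max_iter = 0` the subjects are fit once under
#' the initial prior and no update happens.
#'
#' @param trials Long trial table with a `subject_id` column; only rows of
#'   the model's stage are used.
#' @param spec A [model_spec()].
#' @param carryover For two-stage transfer models: a named list (by subject
#'   id) of [carryover_values()].
#' @param init_prior Initial [group_prior()]; default N(0, 10).
#' @param tol Relative-change convergence tolerance on the total
#'   log-posterior.
#' @param max_iter Maximum EM iterations.
#' @param n_restarts Optimizer restarts per subject per iteration.
#' @return List of class `pit_fit`: `spec`, `subject_fits` (named list),
#'   `group_prior` (converged), `em_iterations`, `em_trace` (total
#'   log-posterior per pass), `converged`, `n_subjects`.
#' @export
em_fit <- function(trials, spec, carryover = NULL, init_prior = NULL,
                   tol = 1e-3, max_iter = 100, n_restarts = 10) {
  if (is.null(init_prior)) init_prior <- default_group_prior(spec)
  keep <- if (spec$stage == "joint") c("instrumental", "pit") else spec$stage
  trials <- trials[trials$stage %in% keep, , drop = FALSE]
  split_trials <- split(trials, trials$subject_id)
  ids <- names(split_trials)
  if (length(ids) < 2) stop("need at least two subjects", call. = FALSE)
  if (spec$stage == "pit") {
    if (is.null(carryover) || !all(ids %in% names(carryover))) {
      stop("carryover must be a named list covering every subject", call. = FALSE)
    }
  }

  fit_all <- function(prior, warm = NULL) {
    lapply(seq_along(ids), function(i) {
      map_fit(split_trials[[ids[i]]], spec, prior,
              carryover = if (spec$stage == "pit") carryover[[ids[i]]] else NULL,
              n_restarts = n_restarts,
              start = if (is.null(warm)) NULL else warm[[i]]$theta_map)
    })
  }
  total_lp <- function(fits) sum(vapply(fits, `[[`, 0, "log_posterior"), na.rm = TRUE)
  prior <- init_prior
  fits <- fit_all(prior)
  obj <- total_lp(fits)
  trace <- obj
  converged <- max_iter == 0
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    prior <- em_update_group(fits)
    fits <- fit_all(prior, warm = fits)
    new_obj <- total_lp(fits)
    trace <- c(trace, new_obj)
    if (abs(new_obj - obj) / (abs(obj) + 1e-8) < tol) {
      converged <- TRUE
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  names(fits) <- ids
  structure(list(
    spec = spec, subject_fits = fits, group_prior = prior,
    em_iterations = iter, em_trace = trace, converged = converged,
    n_subjects = length(ids)
  ), class = "pit_fit")
}

#' @export
print.pit_fit <- function(x, ...) {
  cat(sprintf("<pit_fit %s> %d subjects, %d EM iteration(s)%s\n",
              x$spec$id, x$n_subjects, x$em_iterations,
              if (x$converged) "" else " (not converged)"))
  tab <- rbind(mean = x$group_prior$mean, variance = x$group_prior$variance)
  print(round(tab, 3))
  invisible(x)
}

#' Fit an instrumental model to a cohort
#'
#' Convenience wrapper: subsets the instrumental trials and runs [em_fit()].
#'
#' @inheritParams em_fit
#' @param model Model id or [model_spec()].
#' @param ... Passed to [em_fit()].
#' @return A `pit_fit`.
#' @export
fit_instrumental <- function(trials, model = "M4", ...) {
  spec <- if (is.character(model)) model_spec(model) else model
  em_fit(trials, spec, ...)
}

#' Fit a transfer model to a cohort
#'
#' Two-stage estimation (the default): the instrumental model is fit first
#' on the training trials, each subject's end-of-training action values and
#' bias are frozen, and only the transfer parameters are free when scoring
#' the extinction trials. With `joint = TRUE` the instrumental and transfer
#' parameters are instead estimated together on both stages.
#'
#' @inheritParams em_fit
#' @param model Transfer model id (`"M4+M7"`, `"M4+M8"`, `"M4+M9"`).
#' @param instrumental_model Instrumental model supplying the carryover
#'   (default the winning four-parameter model).
#' @param instrumental_fit Optionally a precomputed `pit_fit` of
#'   `instrumental_model` on the same subjects, to avoid refitting.
#' @param joint Use joint instead of two-stage estimation.
#' @param ... Passed to [em_fit()].
#' @return List with `transfer` (`pit_fit` of the transfer model),
#'   `instrumental` (`pit_fit` used for carryover, or `NULL` for joint
#'   fits) and `carryover` (per-subject list, two-stage only).
#' @export
fit_transfer <- function(trials, model = "M4+M9", instrumental_model = "M4",
                         instrumental_fit = NULL, joint = FALSE, ...) {
  if (isTRUE(joint)) {
    spec <- model_spec(if (is.character(model)) model else model$id, joint = TRUE)
    return(list(transfer = em_fit(trials, spec, ...), instrumental = NULL,
                carryover = NULL))
  }
  ispec <- if (is.character(instrumental_model)) model_spec(instrumental_model) else instrumental_model
  if (is.null(instrumental_fit)) {
    instrumental_fit <- em_fit(trials, ispec, ...)
  }
  instr <- trials[trials$stage == "instrumental", , drop = FALSE]
  co <- lapply(names(instrumental_fit$subject_fits), function(id) {
    carryover_values(ispec, instrumental_fit$subject_fits[[id]]$theta_map,
                     instr[instr$subject_id == id, , drop = FALSE])
  })
  names(co) <- names(instrumental_fit$subject_fits)
  tspec <- if (is.character(model)) model_spec(model) else model
  list(transfer = em_fit(trials, tspec, carryover = co, ...),
       instrumental = instrumental_fit, carryover = co)
}
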