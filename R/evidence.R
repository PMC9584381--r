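#' Laplace-approximated log-model evidence
#'
#' Approximate marginal likelihood of one model over a cohort,
#' \deqn{LME = \sum_n \log P(D_n \mid \theta_n) + \sum_n \log
#'   N(\theta_n \mid \Theta, \Sigma) + \tfrac12 d N \log 2\pi -
#'   \tfrac12 \sum_n \log |H_n| - d \log N,}
#' where \eqn{\theta_n} are the per-subject MAP estimates, \eqn{\Theta},
#' \eqn{\Sigma} the converged (diagonal) group mean and variance, \eqn{H_n}
#' the (regularized) Hessian of the negative log-posterior at the optimum,
#' \eqn{d} the number of free parameters and \eqn{N} the number of subjects.
#' The final term penalizes the 2d group hyperparameters (one mean and one
#' variance per parameter). `group_penalty = FALSE` drops that term, giving
#' the plain per-subject Laplace sum.
#'
#' @param fit A [em_fit()] result.
#' @param group_penalty Include the `- d log N` group-complexity term.
#' @return The log-model evidence (scalar).
#' @export
lme <- function(fit, group_penalty = TRUE) {
  fits <- Filter(function(f) is.finite(f$log_posterior), fit$subject_fits)
  N <- length(fits)
  d <- fit$spec$d
  m <- fit$group_prior$mean
  v <- fit$group_prior$variance
  ll <- sum(vapply(fits, `[[`, 0, "log_likelihood"))
  lp <- sum(vapply(fits, function(f) sum(dnorm(f$theta_map, m, sqrt(v), log = TRUE)), 0))
  ldet <- sum(vapply(fits, function(f) {
    as.numeric(determinant(f$hessian, logarithm = TRUE)$modulus)
  }, 0))
  out <- ll + lp + 0.5 * d * N * log(2 * pi) - 0.5 * ldet
  if (group_penalty) out <- out - d * log(N)
  out
}

#' Compare models by log-model evidence
#'
#' Produces the standard comparison table: one row per fitted model with its
#' parameter count, LME, and LME relative to the best model (0 for the
#' winner, negative otherwise). Models must be fitted on the same subjects
#' and belong to the same stage block — instrumental models are compared
#' among themselves and transfer models among themselves.
#'
#' @param fits List of [em_fit()] results (optionally named).
#' @param group_penalty Passed to [lme()].
#' @return A tibble of class `pit_evidence` with columns `model`, `d`,
#'   `lme`, `relative_lme`; the winning model id is in attribute `winner`.
#' @export
compare_models <- function(fits, group_penalty = TRUE) {
  if (!length(fits)) stop("no fits to compare", call. = FALSE)
  subj <- lapply(fits, function(f) sort(names(f$subject_fits)))
  if (!all(vapply(subj, identical, TRUE, subj[[1]]))) {
    stop("all fits must cover the same subjects", call. = FALSE)
  }
  stages <- vapply(fits, function(f) f$spec$stage, "")
  if (length(unique(stages)) != 1) {
    stop("compare models within one stage block (instrumental or transfer)",
         call. = FALSE)
  }
  vals <- vapply(fits, lme, 0, group_penalty = group_penalty)
  out <- tibble::tibble(
    model = vapply(fits, function(f) f$spec$id, ""),
    d = vapply(fits, function(f) f$spec$d, 0L),
    lme = vals,
    relative_lme = vals - max(vals)
  )
  attr(out, "winner") <- out$model[which.max(out$lme)]
  attr(out, "n_subjects") <- length(subj[[1]])
  class(out) <- c("pit_evidence", class(out))
  out
}

#' @export
print.pit_evidence <- function(x, ...) {
  cat(sprintf("Model comparison (N = %d subjects); winner: %s\n",
              attr(x, "n_subjects"), attr(x, "winner")))
  df <- as.data.frame(x)
  df$lme <- round(df$lme, 3)
  df$relative_lme <- round(df$relative_lme, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
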