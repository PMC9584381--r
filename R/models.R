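#' The nine-model Rescorla-Wagner model space
#'
#' Six instrumental-stage models and three transfer-stage extensions of the
#' instrumental winner:
#' \describe{
#'   \item{M1}{single learning rate `eps`, single sensitivity `rho`}
#'   \item{M2}{M1 plus a collect bias `b`}
#'   \item{M3}{separate `eps_rew` / `eps_pun`, single `rho`}
#'   \item{M4}{M3 plus a collect bias `b`}
#'   \item{M5}{single `eps`, separate `rho_rew` / `rho_pun`}
#'   \item{M6}{M5 plus a collect bias `b`}
#'   \item{M4+M7}{Pavlovian factors `f_plus`, `f_zero`, `f_minus` added to
#'     the collect weight; instrumental values transfer without loss}
#'   \item{M4+M8}{M7 plus an exponential decay rate `alpha` applied to the
#'     carried-over instrumental values after every transfer trial}
#'   \item{M4+M9}{M7 plus per-category generalization noise `eta_good`,
#'     `eta_bad` on the collect weight}
#' }
#' The bias, the Pavlovian factors and the noise terms apply to the collect
#' action only; their refrain counterparts are structurally zero.
#'
#' Group-level Gaussians live on an unconstrained scale, so each parameter
#' carries a transform to its natural space: learning rates and the decay
#' rate map through the logistic sigmoid to (0,1), sensitivities through the
#' exponential to (0, Inf), and biases/factors/noise are unconstrained.
#'
#' @param id One of `"M1"`..`"M6"`, `"M4+M7"`, `"M4+M8"`, `"M4+M9"`.
#' @param joint For transfer models only: if `TRUE`, the specification also
#'   carries the four M4 instrumental parameters as free parameters and its
#'   likelihood scores instrumental and transfer trials jointly, instead of
#'   conditioning on frozen carryover values (the default two-stage scheme).
#' @return A list of class `pit_model`: `id`, `stage` (`"instrumental"`,
#'   `"pit"` or `"joint"`), `parameters`, `transforms`, `d`.
#' @export
#' @examples
#' model_spec("M4")$parameters
#' model_spec("M4+M9")$d
model_spec <- function(id, joint = FALSE) {
  instr <- list(
    M1 = c("eps", "rho"),
    M2 = c("eps", "rho", "b"),
    M3 = c("eps_rew", "eps_pun", "rho"),
    M4 = c("eps_rew", "eps_pun", "rho", "b"),
    M5 = c("eps", "rho_rew", "rho_pun"),
    M6 = c("eps", "rho_rew", "rho_pun", "b")
  )
  transfer <- list(
    "M4+M7" = c("f_plus", "f_zero", "f_minus"),
    "M4+M8" = c("f_plus", "f_zero", "f_minus", "alpha"),
    "M4+M9" = c("f_plus", "f_zero", "f_minus", "eta_good", "eta_bad")
  )
  if (id %in% names(instr)) {
    if (isTRUE(joint)) stop("joint fitting applies to transfer models only", call. = FALSE)
    pars <- instr[[id]]
    stage <- "instrumental"
  } else if (id %in% names(transfer)) {
    pars <- transfer[[id]]
    stage <- "pit"
    if (isTRUE(joint)) {
      pars <- c(instr$M4, pars)
      stage <- "joint"
    }
  } else {
    stop("unknown model id: ", id, call. = FALSE)
  }
  spec <- list(
    id = id,
    stage = stage,
    parameters = pars,
    transforms = parameter_transforms(pars),
    d = length(pars)
  )
  class(spec) <- "pit_model"
  spec
}

parameter_transforms <- function(pars) {
  tr <- ifelse(grepl("^eps", pars) | pars == "alpha", "unit_interval",
               ifelse(grepl("^rho", pars), "positive", "identity"))
  names(tr) <- pars
  tr
}

#' List the model identifiers in the model space
#'
#' @param stage Optionally restrict to `"instrumental"` or `"pit"` models.
#' @return Character vector of model ids.
#' @export
list_models <- function(stage = NULL) {
  ids <- c("M1", "M2", "M3", "M4", "M5", "M6", "M4+M7", "M4+M8", "M4+M9")
  if (is.null(stage)) return(ids)
  stage <- match.arg(stage, c("instrumental", "pit"))
  if (stage == "instrumental") ids[1:6] else ids[7:9]
}

#' @export
print.pit_model <- function(x, ...) {
  cat(sprintf("<pit_model %s> stage: %s, d = %d\n", x$id, x$stage, x$d))
  cat("  parameters:", paste(sprintf("%s [%s]", x$parameters, x$transforms),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Subject parameters for one model
#'
#' Bundles a model specification with one subject's parameter vector. The
#' vector is stored in unconstrained space by default (the space the group
#' Gaussian prior lives on).
#'
#' @param spec A [model_spec()].
#' @param theta Numeric vector, one value per model parameter. Named vectors
#'   are matched by name.
#' @param space `"unconstrained"` (default) or `"natural"`; natural input is
#'   converted.
#' @return List of class `pit_subject_parameters` with `spec` and `theta`
#'   (unconstrained).
#' @export
subject_parameters <- function(spec, theta, space = c("unconstrained", "natural")) {
  space <- match.arg(space)
  theta <- check_theta(spec, theta)
  if (space == "natural") theta <- to_unconstrained(theta, spec)
  structure(list(spec = spec, theta = theta), class = "pit_subject_parameters")
}

check_theta <- function(spec, theta) {
  if (length(theta) != spec$d) {
    stop(sprintf("expected %d parameters for %s, got %d",
                 spec$d, spec$id, length(theta)), call. = FALSE)
  }
  if (!is.null(names(theta))) theta <- theta[spec$parameters]
  if (any(!is.finite(theta))) stop("parameters must be finite", call. = FALSE)
  names(theta) <- spec$parameters
  theta
}

#' Map parameters between unconstrained and natural space
#'
#' `unit_interval` parameters pass through the logistic sigmoid, `positive`
#' parameters through the exponential, `identity` parameters are unchanged.
#' The two functions are exact inverses.
#'
#' @param theta Named or ordered numeric vector in unconstrained space
#'   (`to_natural`) or natural space (`to_unconstrained`).
#' @param spec A [model_spec()] supplying the per-parameter transforms.
#' @return Named numeric vector in the other space.
#' @export
#' @examples
#' sp <- model_spec("M4")
#' to_natural(c(0, 0, 0, 0), sp)   # eps -> 0.5, rho -> 1, b -> 0
to_natural <- function(theta, spec) {
  theta <- check_theta(spec, theta)
  tr <- spec$transforms
  out <- theta
  out[tr == "unit_interval"] <- stats::plogis(theta[tr == "unit_interval"])
  out[tr == "positive"] <- exp(theta[tr == "positive"])
  out
}

#' @rdname to_natural
#' @export
to_unconstrained <- function(theta, spec) {
  theta <- check_theta(spec, theta)
  tr <- spec$transforms
  if (any(theta[tr == "unit_interval"] <= 0 | theta[tr == "unit_interval"] >= 1)) {
    stop("unit-interval parameters must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(theta[tr == "positive"] <= 0)) {
    stop("positive parameters must be > 0", call. = FALSE)
  }
  out <- theta
  out[tr == "unit_interval"] <- stats::qlogis(theta[tr == "unit_interval"])
  out[tr == "positive"] <- log(theta[tr == "positive"])
  out
}

# Expand a model's natural parameter vector to the canonical instrumental
# parameterization (eps_rew, eps_pun, rho_rew, rho_pun, b): single-rate /
# single-sensitivity models duplicate their shared value; absent biases are 0.
canonical_instrumental <- function(spec, natural) {
  g <- function(nm, default = NA_real_) {
    if (nm %in% names(natural)) unname(natural[[nm]]) else default
  }
  eps_rew <- if (is.na(g("eps_rew"))) g("eps") else g("eps_rew")
  eps_pun <- if (is.na(g("eps_pun"))) g("eps") else g("eps_pun")
  rho_rew <- if (is.na(g("rho_rew"))) g("rho") else g("rho_rew")
  rho_pun <- if (is.na(g("rho_pun"))) g("rho") else g("rho_pun")
  b <- g("b", 0)
  c(eps_rew = eps_rew, eps_pun = eps_pun, rho_rew = rho_rew,
    rho_pun = rho_pun, b = b)
}

# Canonical transfer parameterization (f x3, alpha, eta x2).
canonical_transfer <- function(spec, natural) {
  g <- function(nm, default) if (nm %in% names(natural)) unname(natural[[nm]]) else default
  c(f_plus = g("f_plus", 0), f_zero = g("f_zero", 0), f_minus = g("f_minus", 0),
    alpha = g("alpha", 1), eta_good = g("eta_good", 0), eta_bad = g("eta_bad", 0))
}

#' Initialize an action-value table
#'
#' Expected instrumental values Q(stimulus category, action), initialized to
#' zero: with a symmetric softmax and zero-mean priors this makes the first
#' choice unbiased.
#'
#' @param good_collect,good_refrain,bad_collect,bad_refrain Initial values.
#' @return A 2 x 2 numeric matrix with rows `good`/`bad` and columns
#'   `collect`/`refrain`.
#' @export
action_value_table <- function(good_collect = 0, good_refrain = 0,
                               bad_collect = 0, bad_refrain = 0) {
  matrix(c(good_collect, bad_collect, good_refrain, bad_refrain), nrow = 2,
         dimnames = list(STIMULUS_CATEGORIES, ACTIONS))
}

#' Instrumental action weights
#'
#' The weight of each action is its expected value plus the response bias;
#' the bias applies to the collect action only (the refrain bias is
#' structurally zero, which keeps the parameters identifiable under the
#' softmax).
#'
#' @param Q An [action_value_table()].
#' @param bias Collect bias `b`.
#' @param s Stimulus category, `"good"` or `"bad"`.
#' @return Named numeric vector `c(collect = , refrain = )`.
#' @export
instrumental_weight <- function(Q, bias, s) {
  s <- match.arg(s, STIMULUS_CATEGORIES)
  stopifnot(is.finite(bias), all(is.finite(Q)))
  c(collect = unname(Q[s, "collect"] + bias), refrain = unname(Q[s, "refrain"]))
}

#' Softmax probability of collecting
#'
#' Two-action softmax; only the weight difference matters. Numerically
#' stable for large differences.
#'
#' @param w_collect,w_refrain Action weights.
#' @return Probability of the collect action.
#' @export
#' @examples
#' choice_prob(log(3), 0)  # 0.75
choice_prob <- function(w_collect, w_refrain) {
  stopifnot(all(is.finite(w_collect)), all(is.finite(w_refrain)))
  stats::plogis(w_collect - w_refrain)
}

#' Rescorla-Wagner value update
#'
#' Updates a single (stimulus, action) entry after feedback r in {-1, +1}:
#' `Q <- Q + eps(r) * (rho(r) * r - Q)`, where the learning rate and
#' sensitivity select their reward or punishment variant according to the
#' sign of r (models with a single rate/sensitivity pass equal values).
#'
#' @param Q An [action_value_table()].
#' @param s Stimulus category.
#' @param a Action, `"collect"` or `"refrain"`.
#' @param r Feedback, +1 or -1.
#' @param params Named numeric vector with `eps_rew`, `eps_pun`, `rho_rew`,
#'   `rho_pun` (natural space), e.g. from [canonical parameters][model_spec].
#' @return The updated table.
#' @export
update_q <- function(Q, s, a, r, params) {
  s <- match.arg(s, STIMULUS_CATEGORIES)
  a <- match.arg(a, ACTIONS)
  if (!is.finite(r) || !(r %in% c(-1, 1))) {
    stop("feedback must be +1 or -1 (no value learning in extinction)", call. = FALSE)
  }
  eps <- if (r > 0) params[["eps_rew"]] else params[["eps_pun"]]
  rho <- if (r > 0) params[["rho_rew"]] else params[["rho_pun"]]
  Q[s, a] <- Q[s, a] + eps * (rho * r - Q[s, a])
  Q
}

#' Exponential decay of instrumental values
#'
#' Multiplies every table entry by the decay rate `alpha` (applied once per
#' transfer trial under the decay model M4+M8).
#'
#' @param Q An [action_value_table()].
#' @param alpha Decay rate in \[0, 1\].
#' @return The decayed table.
#' @export
decay_q <- function(Q, alpha) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must lie in [0, 1]", call. = FALSE)
  }
  Q * alpha
}

#' Transfer-stage action weights
#'
#' Adds the Pavlovian factor of the presented cue and (for the noisy
#' generalization model) the per-category noise term to the carried-over
#' collect weight; the refrain weight transfers unchanged.
#'
#' @param W_T Named numeric vector `c(collect = , refrain = )` of carried-over
#'   instrumental weights for the presented stimulus category.
#' @param f Named numeric vector of Pavlovian factors for `CS+`, `CS0`, `CS-`
#'   (names `f_plus`, `f_zero`, `f_minus`).
#' @param eta Named numeric vector of per-category noise (`eta_good`,
#'   `eta_bad`), or zeros for models without it.
#' @param cue Pavlovian cue on this trial.
#' @param s Stimulus category on this trial.
#' @return Named numeric vector `c(collect = , refrain = )`.
#' @export
pit_weight <- function(W_T, f, eta, cue, s) {
  cue <- match.arg(cue, PAVLOVIAN_CUES)
  s <- match.arg(s, STIMULUS_CATEGORIES)
  f_cue <- unname(f[[c("CS+" = "f_plus", "CS0" = "f_zero", "CS-" = "f_minus")[[cue]]]])
  eta_s <- unname(eta[[paste0("eta_", s)]])
  stopifnot(is.finite(f_cue), is.finite(eta_s), all(is.finite(W_T)))
  c(collect = unname(W_T[["collect"]]) + f_cue + eta_s,
    refrain = unname(W_T[["refrain"]]))
}
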