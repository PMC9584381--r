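# Compact integer encodings of a trial table for the compiled likelihood.
encode_instrumental <- function(trials) {
  if (nrow(trials) && !all(trials$stage == "instrumental")) {
    stop("expected instrumental-stage trials only", call. = FALSE)
  }
  fb <- trials$feedback
  if (any(is.na(fb)) || any(!fb %in% c(-1, 1))) {
    stop("instrumental trials must carry feedback +1 or -1", call. = FALSE)
  }
  act <- trials$action
  if (any(is.na(act)) || any(!act %in% ACTIONS)) {
    stop("instrumental trials must carry an action", call. = FALSE)
  }
  list(
    stim = as.integer(stimulus_category(trials$instrumental_stimulus) == "bad"),
    action = as.integer(act == "collect"),
    feedback = as.integer(fb)
  )
}

encode_pit <- function(trials) {
  if (nrow(trials) && !all(trials$stage == "pit")) {
    stop("expected transfer-stage trials only", call. = FALSE)
  }
  if (any(!is.na(trials$feedback))) {
    stop("transfer trials run in extinction and must carry no feedback", call. = FALSE)
  }
  act <- trials$action
  if (any(is.na(act)) || any(!act %in% ACTIONS)) {
    stop("transfer trials must carry an action", call. = FALSE)
  }
  cue <- match(trials$pavlovian_stimulus, PAVLOVIAN_CUES)
  if (any(is.na(cue))) stop("transfer trials must carry a Pavlovian cue", call. = FALSE)
  list(
    stim = as.integer(stimulus_category(trials$instrumental_stimulus) == "bad"),
    cue = cue - 1L,
    action = as.integer(act == "collect")
  )
}

#' Choice log-likelihood of a trial sequence
#'
#' Scores a subject's observed choices under one model: instrumental models
#' replay the Rescorla-Wagner update after every trial using the observed
#' feedback; transfer models score extinction trials from carried-over
#' end-of-training action weights plus the Pavlovian factors (and, depending
#' on the model, per-trial value decay or per-category noise), with no
#' learning. A joint specification scores both stages with shared
#' instrumental parameters.
#'
#' @param spec A [model_spec()].
#' @param theta Parameter vector (unconstrained space unless `space =
#'   "natural"`).
#' @param trials Trial table (rows of the stage(s) the model scores).
#' @param carryover For two-stage transfer models: a list with `Q` (2 x 2
#'   end-of-training [action_value_table()]) and `bias` (frozen collect
#'   bias), e.g. from [carryover_values()]. Must be `NULL` for instrumental
#'   and joint models.
#' @param space Space `theta` is given in.
#' @return The summed log-likelihood of the observed actions (0 for an empty
#'   trial table).
#' @export
sequence_loglik <- function(spec, theta, trials, carryover = NULL,
                            space = c("unconstrained", "natural")) {
  space <- match.arg(space)
  natural <- if (space == "natural") check_theta(spec, theta) else to_natural(theta, spec)
  if (spec$stage == "instrumental") {
    if (!is.null(carryover)) stop("carryover applies to transfer models only", call. = FALSE)
    enc <- encode_instrumental(trials)
    return(instr_replay_cpp(canonical_instrumental(spec, natural),
                            enc$stim, enc$action, enc$feedback)$loglik)
  }
  if (spec$stage == "joint") {
    if (!is.null(carryover)) {
      stop("joint models derive carryover internally; pass carryover = NULL", call. = FALSE)
    }
    instr <- trials[trials$stage == "instrumental", , drop = FALSE]
    pit <- trials[trials$stage == "pit", , drop = FALSE]
    can <- canonical_instrumental(spec, natural)
    enc <- encode_instrumental(instr)
    rep <- instr_replay_cpp(can, enc$stim, enc$action, enc$feedback)
    tr <- canonical_transfer(spec, natural)
    encp <- encode_pit(pit)
    return(rep$loglik +
             pit_loglik_cpp(tr[1:3], tr[["alpha"]], tr[5:6], rep$Q,
                            can[["b"]], encp$stim, encp$cue, encp$action))
  }
  # two-stage transfer model
  if (is.null(carryover)) {
    stop("transfer models need carryover (end-of-training Q and bias)", call. = FALSE)
  }
  stopifnot(is.matrix(carryover$Q), all(dim(carryover$Q) == 2),
            is.finite(carryover$bias))
  tr <- canonical_transfer(spec, natural)
  enc <- encode_pit(trials)
  pit_loglik_cpp(tr[1:3], tr[["alpha"]], tr[5:6], carryover$Q,
                 carryover$bias, enc$stim, enc$cue, enc$action)
}

#' End-of-training carryover values
#'
#' Replays a subject's instrumental trials under an instrumental model and
#' returns the final expected-value table together with the model's collect
#' bias — the quantities the two-stage transfer models condition on.
#'
#' @param spec An instrumental [model_spec()] (M1..M6).
#' @param theta Parameter vector for `spec`.
#' @param trials The subject's instrumental trials.
#' @inheritParams sequence_loglik
#' @return List with `Q` (2 x 2 matrix, rows good/bad, columns
#'   collect/refrain) and `bias`.
#' @export
carryover_values <- function(spec, theta, trials,
                             space = c("unconstrained", "natural")) {
  space <- match.arg(space)
  if (spec$stage != "instrumental") {
    stop("carryover_values needs an instrumental model", call. = FALSE)
  }
  natural <- if (space == "natural") check_theta(spec, theta) else to_natural(theta, spec)
  can <- canonical_instrumental(spec, natural)
  enc <- encode_instrumental(trials)
  rep <- instr_replay_cpp(can, enc$stim, enc$action, enc$feedback)
  Q <- rep$Q
  dimnames(Q) <- list(STIMULUS_CATEGORIES, ACTIONS)
  list(Q = Q, bias = unname(can[["b"]]))
}
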