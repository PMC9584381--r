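#' Draw instrumental feedback
#'
#' Collecting a good shell or refraining from a bad shell (the
#' contingency-congruent actions) is rewarded with probability
#' `reward_prob_congruent`; the incongruent actions with
#' `reward_prob_incongruent`. Every non-rewarded instrumental trial is
#' punished, so feedback is always +1 or -1.
#'
#' @param s Stimulus category vector (`"good"` / `"bad"`).
#' @param a Action vector (`"collect"` / `"refrain"`).
#' @param config A [task_config()].
#' @return Integer vector of +1 / -1 feedback. Uses the session RNG.
#' @export
simulate_feedback <- function(s, a, config = task_config()) {
  congruent <- (s == "good") == (a == "collect")
  p <- ifelse(congruent, config$reward_prob_congruent, config$reward_prob_incongruent)
  ifelse(rbinom(length(p), 1L, p) == 1L, 1L, -1L)
}

#' Emit a keypress count for an action
#'
#' The models are defined over the binary collect/refrain choice, but the
#' behavioral measures use keypress counts; this maps the chosen action to a
#' count consistent with the collection threshold: collect trials emit
#' `collect_threshold_presses` plus a Poisson(1) overshoot, refrain trials a
#' Poisson(1) count truncated below the threshold. Thresholding the emitted
#' count therefore recovers the action exactly.
#'
#' @param a Action vector.
#' @inheritParams simulate_feedback
#' @return Integer vector of keypress counts.
#' @export
emit_keypresses <- function(a, config = task_config()) {
  n <- length(a)
  extra <- rpois(n, 1)
  low <- rpois(n, 1)
  # truncate refrain counts below the threshold (P(X >= 6) for Poisson(1) is
  # ~5e-4, so redraws are rare)
  bad <- low >= config$collect_threshold_presses
  while (any(bad)) {
    low[bad] <- rpois(sum(bad), 1)
    bad <- low >= config$collect_threshold_presses
  }
  as.integer(ifelse(a == "collect", config$collect_threshold_presses + extra, low))
}

blank_trials <- function(n, subject_id, stage) {
  tibble::tibble(
    subject_id = rep(subject_id, n), stage = rep(stage, n),
    block = rep(NA_integer_, n), trial = seq_len(n),
    instrumental_stimulus = rep(NA_character_, n),
    pavlovian_stimulus = rep(NA_character_, n),
    cs_left = rep(NA_character_, n), cs_right = rep(NA_character_, n),
    action = rep(NA_character_, n), keypresses = rep(NA_integer_, n),
    feedback = rep(NA_integer_, n), rewarded = rep(NA, n)
  )
}

#' Simulate one subject through all four task stages
#'
#' Generates a complete behavioral record in the generative direction of the
#' model equations. Instrumental trials are chosen by the softmax over the
#' current action weights and update the value table with the sampled
#' feedback; block 3 stops at the first trial (evaluated from the
#' `criterion_window`-th block-3 trial onward) where accuracy over the last
#' `criterion_window` block-3 trials reaches `criterion_accuracy`. The
#' Pavlovian stage is passive (deterministic CS-US pairings; no behavior).
#' Transfer trials are chosen from the carried-over end-of-training weights
#' plus the transfer model's Pavlovian factors / decay / noise, in
#' extinction. Forced-choice trials pick the higher-valence cue with
#' probability `1 - forced_choice_lapse`.
#'
#' @param instr_params [subject_parameters()] for an instrumental model.
#' @param transfer_params [subject_parameters()] for a transfer model, or
#'   `NULL` for pure instrumental transfer (all Pavlovian factors zero).
#' @param config A [task_config()].
#' @param subject_id Identifier written into every row.
#' @param seed Optional seed (falls back to `config$seed`; `NULL` uses the
#'   session RNG stream).
#' @return A tibble of trial records across the four stages.
#' @export
simulate_subject <- function(instr_params, transfer_params = NULL,
                             config = task_config(), subject_id = "s01",
                             seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  if (is.null(transfer_params)) {
    transfer_params <- subject_parameters(model_spec("M4+M7"), c(0, 0, 0))
  }
  ispec <- instr_params$spec
  if (ispec$stage != "instrumental") stop("instr_params must use an instrumental model", call. = FALSE)
  tspec <- transfer_params$spec
  if (tspec$stage != "pit") stop("transfer_params must use a two-stage transfer model", call. = FALSE)
  can <- canonical_instrumental(ispec, to_natural(instr_params$theta, ispec))
  tr <- canonical_transfer(tspec, to_natural(transfer_params$theta, tspec))

  sched <- build_task_schedule(config)

  ## instrumental stage
  isch <- sched$instrumental
  Q <- action_value_table()
  n12 <- config$block1_trials + config$block2_trials
  rows <- list()
  b3_correct <- logical(0)
  for (i in seq_len(nrow(isch))) {
    s <- stimulus_category(isch$instrumental_stimulus[i])
    p <- choice_prob(Q[s, "collect"] + can[["b"]], Q[s, "refrain"])
    a <- if (runif(1) < p) "collect" else "refrain"
    r <- simulate_feedback(s, a, config)
    eps <- if (r > 0) can[["eps_rew"]] else can[["eps_pun"]]
    rho <- if (r > 0) can[["rho_rew"]] else can[["rho_pun"]]
    Q[s, a] <- Q[s, a] + eps * (rho * r - Q[s, a])
    rows[[i]] <- list(action = a, feedback = r)
    if (isch$block[i] == 3L) {
      b3_correct <- c(b3_correct, (s == "good") == (a == "collect"))
      k <- length(b3_correct)
      if (k >= config$criterion_window) {
        win <- b3_correct[(k - config$criterion_window + 1L):k]
        if (mean(win) >= config$criterion_accuracy) break
      }
    }
  }
  ni <- length(rows)
  instr <- blank_trials(ni, subject_id, "instrumental")
  instr$block <- isch$block[seq_len(ni)]
  instr$instrumental_stimulus <- isch$instrumental_stimulus[seq_len(ni)]
  instr$action <- vapply(rows, `[[`, "", "action")
  instr$feedback <- vapply(rows, function(x) as.integer(x$feedback), 1L)
  instr$keypresses <- emit_keypresses(instr$action, config)
  instr$rewarded <- instr$feedback == 1L

  ## pavlovian stage: passive observation
  pav <- blank_trials(nrow(sched$pavlovian), subject_id, "pavlovian")
  pav$pavlovian_stimulus <- sched$pavlovian$pavlovian_stimulus

  ## transfer stage: extinction, carryover from end-of-training values
  psch <- sched$pit
  np <- nrow(psch)
  Wq <- Q  # end-of-training table
  f <- tr[c("f_plus", "f_zero", "f_minus")]
  eta <- tr[c("eta_good", "eta_bad")]
  pit <- blank_trials(np, subject_id, "pit")
  pit$instrumental_stimulus <- psch$instrumental_stimulus
  pit$pavlovian_stimulus <- psch$pavlovian_stimulus
  act <- character(np)
  for (i in seq_len(np)) {
    s <- stimulus_category(psch$instrumental_stimulus[i])
    w <- pit_weight(c(collect = Wq[s, "collect"] + can[["b"]],
                      refrain = Wq[s, "refrain"]),
                    f, eta, psch$pavlovian_stimulus[i], s)
    act[i] <- if (runif(1) < choice_prob(w[["collect"]], w[["refrain"]])) "collect" else "refrain"
    Wq <- Wq * tr[["alpha"]]
  }
  pit$action <- act
  pit$keypresses <- emit_keypresses(act, config)

  ## forced choice: valence-ordering chooser with a small lapse rate
  fsch <- sched$forced_choice
  fc <- blank_trials(nrow(fsch), subject_id, "forced_choice")
  if (nrow(fsch)) {
    fc$cs_left <- fsch$cs_left
    fc$cs_right <- fsch$cs_right
    better <- ifelse(CUE_VALENCE[fsch$cs_left] > CUE_VALENCE[fsch$cs_right],
                     fsch$cs_left, fsch$cs_right)
    worse <- ifelse(better == fsch$cs_left, fsch$cs_right, fsch$cs_left)
    lapse <- runif(nrow(fsch)) < config$forced_choice_lapse
    fc$action <- ifelse(lapse, worse, better)
  }

  dplyr::bind_rows(instr, pav, pit, fc)
}

#' Reference generating parameters for synthetic cohorts
#'
#' Group-level means and standard deviations (unconstrained space) used as
#' the package's canonical study conditions for simulation-based tests and
#' recovery experiments. The instrumental values put the reward learning
#' rate well above the punishment learning rate with a moderate positive
#' sensitivity and a small collect bias; the transfer values order the
#' Pavlovian factors CS+ > CS0 > CS- symmetrically about zero. Between-
#' subject spread is of order one on the unconstrained scale.
#'
#' @param id A model id (see [list_models()]).
#' @return List with unconstrained `mean` and `sd` vectors, named by
#'   parameter.
#' @export
reference_cohort_parameters <- function(id) {
  spec <- model_spec(id)
  means <- c(eps = -0.5, eps_rew = 0.5, eps_pun = -1.5, rho = 0.7,
             rho_rew = 0.7, rho_pun = 0.7, b = 0.3,
             f_plus = 1.5, f_zero = 0, f_minus = -1.5, alpha = 1.5,
             eta_good = 0, eta_bad = 0)
  sds <- c(eps = 1, eps_rew = 1, eps_pun = 1, rho = 0.5,
           rho_rew = 0.5, rho_pun = 0.5, b = 0.5,
           f_plus = 1, f_zero = 0.75, f_minus = 1, alpha = 0.75,
           eta_good = 1, eta_bad = 1)
  list(mean = means[spec$parameters], sd = sds[spec$parameters])
}

#' Simulate a cohort with known ground truth
#'
#' Draws each subject's unconstrained parameters from independent Gaussians
#' and simulates every subject through the four task stages. The returned
#' truth table records the generating parameters in both spaces, alongside
#' the group-level means and SDs and the seed, so recovery can be scored.
#'
#' @param n_subjects Number of subjects.
#' @param instr_model Instrumental [model_spec()] (or id string).
#' @param instr_mean,instr_sd Unconstrained group means / SDs for the
#'   instrumental parameters (defaults: [reference_cohort_parameters()]).
#' @param transfer_model Transfer [model_spec()] (or id), or `NULL` to
#'   simulate transfer with zero Pavlovian factors.
#' @param transfer_mean,transfer_sd Group means / SDs for the transfer
#'   parameters.
#' @param config A [task_config()].
#' @param group Optional vector of group labels (length 1 or `n_subjects`),
#'   recorded in the trial table; labels never influence generation.
#' @param seed Optional seed.
#' @return List with `trials` (long tibble over all subjects) and `truth`
#'   (tidy tibble: subject, model, parameter, unconstrained, natural; group
#'   means/SDs and the seed as attributes).
#' @export
simulate_cohort <- function(n_subjects, instr_model = "M4",
                            instr_mean = NULL, instr_sd = NULL,
                            transfer_model = NULL,
                            transfer_mean = NULL, transfer_sd = NULL,
                            config = task_config(), group = NULL,
                            seed = NULL) {
  stopifnot(n_subjects >= 1)
  if (!is.null(seed)) set.seed(seed)
  ispec <- if (is.character(instr_model)) model_spec(instr_model) else instr_model
  iref <- reference_cohort_parameters(ispec$id)
  if (is.null(instr_mean)) instr_mean <- iref$mean
  if (is.null(instr_sd)) instr_sd <- iref$sd
  instr_mean <- check_theta(ispec, instr_mean)
  instr_sd <- check_theta(ispec, instr_sd)
  if (any(instr_sd < 0)) stop("group SDs must be >= 0", call. = FALSE)

  tspec <- NULL
  if (!is.null(transfer_model)) {
    tspec <- if (is.character(transfer_model)) model_spec(transfer_model) else transfer_model
    tref <- reference_cohort_parameters(tspec$id)
    if (is.null(transfer_mean)) transfer_mean <- tref$mean
    if (is.null(transfer_sd)) transfer_sd <- tref$sd
    transfer_mean <- check_theta(tspec, transfer_mean)
    transfer_sd <- check_theta(tspec, transfer_sd)
    if (any(transfer_sd < 0)) stop("group SDs must be >= 0", call. = FALSE)
  }
  if (!is.null(group)) group <- rep_len(as.character(group), n_subjects)

  ids <- sprintf("s%02d", seq_len(n_subjects))
  trials <- vector("list", n_subjects)
  truth <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    th_i <- rnorm(ispec$d, instr_mean, instr_sd)
    names(th_i) <- ispec$parameters
    tp <- NULL
    th_t <- NULL
    if (!is.null(tspec)) {
      th_t <- rnorm(tspec$d, transfer_mean, transfer_sd)
      names(th_t) <- tspec$parameters
      tp <- subject_parameters(tspec, th_t)
    }
    dat <- simulate_subject(subject_parameters(ispec, th_i), tp,
                            config = config, subject_id = ids[i], seed = NULL)
    if (!is.null(group)) dat$group <- group[i]
    trials[[i]] <- dat
    tt <- tibble::tibble(
      subject_id = ids[i],
      model = c(rep(ispec$id, ispec$d), if (!is.null(tspec)) rep(tspec$id, tspec$d)),
      parameter = c(ispec$parameters, if (!is.null(tspec)) tspec$parameters),
      unconstrained = c(th_i, th_t),
      natural = c(to_natural(th_i, ispec),
                  if (!is.null(tspec)) to_natural(th_t, tspec))
    )
    truth[[i]] <- tt
  }
  truth <- dplyr::bind_rows(truth)
  attr(truth, "group_mean") <- c(instr_mean, if (!is.null(tspec)) transfer_mean)
  attr(truth, "group_sd") <- c(instr_sd, if (!is.null(tspec)) transfer_sd)
  attr(truth, "seed") <- seed
  list(trials = dplyr::bind_rows(trials), truth = truth)
}
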