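#' Trials to the instrumental learning criterion
#'
#' Total instrumental trials a subject completed before block 3 ended:
#' the fixed blocks 1-2 (40 trials under the default design) plus however
#' many block-3 trials were run before the sliding-window accuracy criterion
#' truncated the block (or its maximum length was reached). A correct trial
#' is collecting a good shell or refraining from a bad one.
#'
#' @param trials One subject's trial table (instrumental rows with `block`).
#' @return Integer count.
#' @export
trials_to_criterion <- function(trials) {
  instr <- trials[trials$stage == "instrumental", , drop = FALSE]
  if (!nrow(instr)) stop("no instrumental trials", call. = FALSE)
  if (any(is.na(instr$block))) stop("instrumental trials must carry block labels", call. = FALSE)
  nrow(instr)
}

#' Instrumental accuracy by stimulus category
#'
#' @param trials One subject's trial table.
#' @return Named numeric vector `c(good = , bad = )`: proportion correct
#'   (collect good / refrain bad) across all instrumental trials.
#' @export
instrumental_accuracy <- function(trials) {
  instr <- trials[trials$stage == "instrumental", , drop = FALSE]
  s <- stimulus_category(instr$instrumental_stimulus)
  correct <- (s == "good") == (instr$action == "collect")
  c(good = mean(correct[s == "good"]), bad = mean(correct[s == "bad"]))
}

#' Win-stay / lose-switch probabilities
#'
#' For each stimulus category, the probability of repeating the action taken
#' on that category's previous presentation given that it was rewarded
#' (stay after reward), and of changing action given that it was punished
#' (switch after punishment). Conditioning is on the previous presentation
#' of the same category — not the previous trial of any category — because
#' the measure is crossed with stimulus in the downstream analyses. Cells
#' with no qualifying transitions are `NA`.
#'
#' @param trials One subject's trial table (>= 2 instrumental trials).
#' @return Tibble with columns `category`, `p_stay_after_reward`,
#'   `p_switch_after_punish`.
#' @export
winstay_loseswitch <- function(trials) {
  instr <- trials[trials$stage == "instrumental", , drop = FALSE]
  if (nrow(instr) < 2) stop("need at least two instrumental trials", call. = FALSE)
  instr$category <- stimulus_category(instr$instrumental_stimulus)
  out <- lapply(STIMULUS_CATEGORIES, function(cat) {
    sub <- instr[instr$category == cat, , drop = FALSE]
    n <- nrow(sub)
    if (n < 2) {
      return(tibble::tibble(category = cat, p_stay_after_reward = NA_real_,
                            p_switch_after_punish = NA_real_))
    }
    prev_r <- sub$feedback[-n]
    stay <- sub$action[-1] == sub$action[-n]
    p_stay <- if (any(prev_r == 1)) mean(stay[prev_r == 1]) else NA_real_
    p_switch <- if (any(prev_r == -1)) mean(!stay[prev_r == -1]) else NA_real_
    tibble::tibble(category = cat, p_stay_after_reward = p_stay,
                   p_switch_after_punish = p_switch)
  })
  dplyr::bind_rows(out)
}

#' Mean keypresses per Pavlovian cue in the transfer stage
#'
#' @param trials One subject's trial table.
#' @return Named numeric vector over `CS+`, `CS0`, `CS-` (averaged over
#'   trials within cue, pooling good and bad shells).
#' @export
mean_keypresses <- function(trials) {
  pit <- trials[trials$stage == "pit", , drop = FALSE]
  if (!nrow(pit)) stop("no transfer trials", call. = FALSE)
  vapply(PAVLOVIAN_CUES, function(cue) {
    mean(pit$keypresses[pit$pavlovian_stimulus == cue])
  }, 0)
}

#' Per-subject PIT regression slope
#'
#' Ordinary least-squares slope of the per-cue mean keypress counts on the
#' cue code (CS+ = 1, CS0 = 0, CS- = -1); with three equally spaced codes
#' this equals (mean under CS+ minus mean under CS-) / 2. Positive slopes
#' indicate the canonical transfer signature (more vigour under
#' reward-predictive cues).
#'
#' @param trials One subject's trial table (all three cues present).
#' @return The slope (scalar).
#' @export
pit_slope <- function(trials) {
  m <- mean_keypresses(trials)
  if (any(is.na(m))) stop("all three Pavlovian cues must be present", call. = FALSE)
  unname(coef(lm(m ~ CUE_VALENCE[names(m)]))[2])
}

#' Collection probability per Pavlovian cue
#'
#' Fraction of transfer trials on which the subject pressed at least the
#' collection threshold, per cue, pooled across good and bad shells.
#'
#' @param trials One subject's trial table.
#' @param config A [task_config()] supplying the threshold.
#' @return Named numeric vector over `CS+`, `CS0`, `CS-`.
#' @export
collect_prob <- function(trials, config = task_config()) {
  pit <- trials[trials$stage == "pit", , drop = FALSE]
  if (!nrow(pit)) stop("no transfer trials", call. = FALSE)
  vapply(PAVLOVIAN_CUES, function(cue) {
    k <- pit$keypresses[pit$pavlovian_stimulus == cue]
    mean(k >= config$collect_threshold_presses)
  }, 0)
}

#' Forced-choice accuracy
#'
#' Fraction of forced-choice trials on which the chosen cue has the higher
#' valence (CS+ > CS0 > CS-).
#'
#' @param trials One subject's trial table.
#' @return Proportion correct.
#' @export
forced_choice_accuracy <- function(trials) {
  fc <- trials[trials$stage == "forced_choice", , drop = FALSE]
  if (!nrow(fc)) stop("no forced-choice trials", call. = FALSE)
  other <- ifelse(fc$action == fc$cs_left, fc$cs_right, fc$cs_left)
  mean(CUE_VALENCE[fc$action] > CUE_VALENCE[other])
}

#' Per-subject behavioral summary
#'
#' One row of model-free measures for a single subject: trials to criterion,
#' accuracy by stimulus category, win-stay/lose-switch by category, per-cue
#' mean keypresses and collection probabilities, the PIT regression slope,
#' and forced-choice accuracy.
#'
#' @param trials One subject's trial table.
#' @param config A [task_config()].
#' @return A one-row tibble.
#' @export
subject_summary <- function(trials, config = task_config()) {
  acc <- instrumental_accuracy(trials)
  wsls <- winstay_loseswitch(trials)
  mk <- mean_keypresses(trials)
  cp <- collect_prob(trials, config)
  tibble::tibble(
    subject_id = trials$subject_id[1],
    trials_to_criterion = trials_to_criterion(trials),
    accuracy_good = acc[["good"]],
    accuracy_bad = acc[["bad"]],
    p_stay_reward_good = wsls$p_stay_after_reward[wsls$category == "good"],
    p_stay_reward_bad = wsls$p_stay_after_reward[wsls$category == "bad"],
    p_switch_punish_good = wsls$p_switch_after_punish[wsls$category == "good"],
    p_switch_punish_bad = wsls$p_switch_after_punish[wsls$category == "bad"],
    keypresses_cs_plus = mk[["CS+"]],
    keypresses_cs_zero = mk[["CS0"]],
    keypresses_cs_minus = mk[["CS-"]],
    collect_prob_cs_plus = cp[["CS+"]],
    collect_prob_cs_zero = cp[["CS0"]],
    collect_prob_cs_minus = cp[["CS-"]],
    pit_slope = pit_slope(trials),
    forced_choice_accuracy = forced_choice_accuracy(trials)
  )
}

#' Cohort-level behavioral summary
#'
#' Applies [subject_summary()] to every subject and aggregates: per-group
#' (or overall) means and SDs of each measure.
#'
#' @param trials Long trial table with `subject_id` (and optionally a
#'   `group` column of labels).
#' @param config A [task_config()].
#' @return List with `subjects` (one row per subject, with `group` if
#'   labeled) and `groups` (mean and SD of every measure per group).
#' @export
cohort_summary <- function(trials, config = task_config()) {
  per <- dplyr::bind_rows(lapply(split(trials, trials$subject_id),
                                 subject_summary, config = config))
  if ("group" %in% names(trials)) {
    labels <- trials |>
      dplyr::distinct(.data$subject_id, .data$group)
    per <- dplyr::left_join(per, labels, by = "subject_id")
  } else {
    per$group <- "all"
  }
  groups <- per |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric),
                                   list(mean = ~mean(.x, na.rm = TRUE),
                                        sd = ~stats::sd(.x, na.rm = TRUE))),
                     n = dplyr::n(), .groups = "drop")
  list(subjects = per, groups = groups)
}
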