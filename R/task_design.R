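#' Task configuration for the four-stage PIT paradigm
#'
#' Encodes the design constants of the Pavlovian-instrumental transfer task:
#' probabilistic instrumental training (three blocks, the third terminated by
#' a sliding-window accuracy criterion), deterministic Pavlovian conditioning,
#' a transfer stage run in extinction with crossed instrumental x Pavlovian
#' stimuli, and a forced-choice test over cue pairs. Defaults reproduce the
#' published design: 80%/20% reward contingencies, 20/20/40 instrumental
#' trials with an 80%-over-10-trials criterion in block 3, 8 presentations
#' per CS-US pair, 6 repetitions of each of the 12 IS-CS combinations, and
#' 3 repetitions of each unordered CS pair.
#'
#' @param reward_prob_congruent Probability that the contingency-congruent
#'   action (collect a good shell, refrain from a bad shell) is rewarded.
#' @param reward_prob_incongruent Probability that the incongruent action is
#'   rewarded. Non-rewarded instrumental trials are punished (feedback -1).
#' @param block1_trials,block2_trials Trials in instrumental blocks 1 and 2
#'   (two stimuli each: G1/B1, then G2/B2).
#' @param block3_max_trials Maximum trials in instrumental block 3 (all four
#'   stimuli); truncated early once the criterion is met.
#' @param criterion_accuracy,criterion_window Learning criterion: accuracy
#'   over the last `criterion_window` block-3 trials that ends block 3.
#' @param pavlovian_trials_per_pair Presentations of each CS-US pair.
#' @param pit_reps_per_combo Repetitions of each of the 12 IS-CS combinations
#'   in the transfer stage.
#' @param forced_choice_reps Repetitions of each unordered CS pair in the
#'   forced-choice test (0 allowed; yields an empty schedule).
#' @param collect_threshold_presses Keypress count at or above which a trial
#'   counts as a collect action.
#' @param forced_choice_lapse Probability that a simulated subject picks the
#'   lower-valence cue in the forced-choice test.
#' @param seed Optional integer seed stored with the configuration and used
#'   by the simulators when no explicit seed is given.
#'
#' @return A validated list of class `pit_task_config`.
#' @export
#' @examples
#' cfg <- task_config()
#' cfg$block3_max_trials
task_config <- function(reward_prob_congruent = 0.80,
                        reward_prob_incongruent = 0.20,
                        block1_trials = 20L,
                        block2_trials = 20L,
                        block3_max_trials = 40L,
                        criterion_accuracy = 0.80,
                        criterion_window = 10L,
                        pavlovian_trials_per_pair = 8L,
                        pit_reps_per_combo = 6L,
                        forced_choice_reps = 3L,
                        collect_threshold_presses = 6L,
                        forced_choice_lapse = 0.02,
                        seed = NULL) {
  cfg <- list(
    reward_prob_congruent = reward_prob_congruent,
    reward_prob_incongruent = reward_prob_incongruent,
    block1_trials = as.integer(block1_trials),
    block2_trials = as.integer(block2_trials),
    block3_max_trials = as.integer(block3_max_trials),
    criterion_accuracy = criterion_accuracy,
    criterion_window = as.integer(criterion_window),
    pavlovian_trials_per_pair = as.integer(pavlovian_trials_per_pair),
    pit_reps_per_combo = as.integer(pit_reps_per_combo),
    forced_choice_reps = as.integer(forced_choice_reps),
    collect_threshold_presses = as.integer(collect_threshold_presses),
    forced_choice_lapse = forced_choice_lapse,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "pit_task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  probs <- c(cfg$reward_prob_congruent, cfg$reward_prob_incongruent,
             cfg$criterion_accuracy, cfg$forced_choice_lapse)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  counts <- c(cfg$block1_trials, cfg$block2_trials, cfg$block3_max_trials,
              cfg$criterion_window, cfg$pavlovian_trials_per_pair,
              cfg$pit_reps_per_combo, cfg$collect_threshold_presses)
  if (any(is.na(counts)) || any(counts < 1L)) {
    stop("all trial counts must be >= 1", call. = FALSE)
  }
  if (is.na(cfg$forced_choice_reps) || cfg$forced_choice_reps < 0L) {
    stop("forced_choice_reps must be >= 0", call. = FALSE)
  }
  if (cfg$criterion_window > cfg$block3_max_trials) {
    stop("criterion_window must not exceed block3_max_trials", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.pit_task_config <- function(x, ...) {
  cat("PIT task configuration\n")
  cat(sprintf("  instrumental: %d + %d + <=%d trials, criterion %.0f%% over %d\n",
              x$block1_trials, x$block2_trials, x$block3_max_trials,
              100 * x$criterion_accuracy, x$criterion_window))
  cat(sprintf("  contingencies: congruent %.2f / incongruent %.2f\n",
              x$reward_prob_congruent, x$reward_prob_incongruent))
  cat(sprintf("  pavlovian: 3 x %d trials; pit: 12 x %d; forced choice: 3 x %d\n",
              x$pavlovian_trials_per_pair, x$pit_reps_per_combo,
              x$forced_choice_reps))
  invisible(x)
}

#' Map instrumental stimuli to their category
#'
#' G1 and G2 are "good" shells, B1 and B2 "bad" shells. The two stimuli of a
#' category are treated as identical by every model, so all modelling code
#' collapses identities to categories through this map.
#'
#' @param stimulus Character vector of stimulus identities (`G1`, `G2`, `B1`,
#'   `B2`).
#' @return Character vector of `"good"` / `"bad"`.
#' @export
#' @examples
#' stimulus_category(c("G1", "B2"))
stimulus_category <- function(stimulus) {
  out <- ifelse(substr(stimulus, 1, 1) == "G", "good",
                ifelse(substr(stimulus, 1, 1) == "B", "bad", NA_character_))
  if (any(is.na(out) & !is.na(stimulus))) {
    stop("unknown instrumental stimulus; expected G1/G2/B1/B2", call. = FALSE)
  }
  out
}

empty_slot_tbl <- function(n) {
  tibble::tibble(
    stage = character(n), block = rep(NA_integer_, n), trial = integer(n),
    instrumental_stimulus = rep(NA_character_, n),
    pavlovian_stimulus = rep(NA_character_, n),
    cs_left = rep(NA_character_, n), cs_right = rep(NA_character_, n),
    side = rep(NA_character_, n)
  )
}

# Shuffle `items` into `n` slots with per-item counts differing by at most 1.
balanced_shuffle <- function(items, n) {
  sample(rep_len(items, n), n)
}

#' Build the instrumental-training schedule
#'
#' Block 1 presents G1 and B1, block 2 presents G2 and B2 (20 trials each by
#' default, equal counts per stimulus); block 3 presents all four stimuli in
#' randomized order with near-equal counts. The block-3 schedule always has
#' its full length: truncation by the learning criterion happens at
#' simulation time, so schedules stay replayable.
#'
#' @param config A [task_config()].
#' @return A tibble with one row per trial slot (`stage`, `block`, `trial`,
#'   `instrumental_stimulus`, `side`). Uses the session RNG; call
#'   [set.seed()] beforehand for reproducibility.
#' @export
build_instrumental_schedule <- function(config = task_config()) {
  validate_task_config(config)
  stims <- c(
    balanced_shuffle(c("G1", "B1"), config$block1_trials),
    balanced_shuffle(c("G2", "B2"), config$block2_trials),
    balanced_shuffle(INSTRUMENTAL_STIMULI, config$block3_max_trials)
  )
  n <- length(stims)
  out <- empty_slot_tbl(n)
  out$stage <- "instrumental"
  out$block <- rep(1:3, c(config$block1_trials, config$block2_trials,
                          config$block3_max_trials))
  out$trial <- seq_len(n)
  out$instrumental_stimulus <- stims
  out$side <- sample(c("left", "right"), n, replace = TRUE)
  out
}

#' Build the Pavlovian-training schedule
#'
#' Each of CS+, CS0 and CS- is presented `pavlovian_trials_per_pair` times
#' (8 by default, 24 trials total) in randomized order; the CS-US pairing is
#' deterministic, so no outcome column is needed.
#'
#' @inheritParams build_instrumental_schedule
#' @return A tibble of trial slots with `pavlovian_stimulus` filled in.
#' @export
build_pavlovian_schedule <- function(config = task_config()) {
  validate_task_config(config)
  cues <- sample(rep(PAVLOVIAN_CUES, each = config$pavlovian_trials_per_pair))
  n <- length(cues)
  out <- empty_slot_tbl(n)
  out$stage <- "pavlovian"
  out$trial <- seq_len(n)
  out$pavlovian_stimulus <- cues
  out$side <- sample(c("left", "right"), n, replace = TRUE)
  out
}

#' Build the transfer-stage (PIT) schedule
#'
#' Crosses the four instrumental stimuli with the three Pavlovian cues; each
#' of the 12 combinations appears exactly `pit_reps_per_combo` times (72
#' trials by default), in randomized order. The stage runs in extinction, so
#' slots carry no outcome.
#'
#' @inheritParams build_instrumental_schedule
#' @return A tibble of trial slots with both stimulus columns filled in.
#' @export
build_pit_schedule <- function(config = task_config()) {
  validate_task_config(config)
  combos <- expand.grid(instrumental_stimulus = INSTRUMENTAL_STIMULI,
                        pavlovian_stimulus = PAVLOVIAN_CUES,
                        rep = seq_len(config$pit_reps_per_combo),
                        stringsAsFactors = FALSE)
  combos <- combos[sample(nrow(combos)), , drop = FALSE]
  n <- nrow(combos)
  out <- empty_slot_tbl(n)
  out$stage <- "pit"
  out$trial <- seq_len(n)
  out$instrumental_stimulus <- combos$instrumental_stimulus
  out$pavlovian_stimulus <- combos$pavlovian_stimulus
  out$side <- sample(c("left", "right"), n, replace = TRUE)
  out
}

#' Build the forced-choice schedule
#'
#' Each of the three unordered CS pairs appears `forced_choice_reps` times
#' (9 trials by default) in randomized order, with random left/right
#' placement. Screen side carries no model semantics.
#'
#' @inheritParams build_instrumental_schedule
#' @return A tibble of trial slots with `cs_left` / `cs_right` filled in.
#' @export
build_forced_choice_schedule <- function(config = task_config()) {
  validate_task_config(config)
  pairs <- utils::combn(PAVLOVIAN_CUES, 2)
  idx <- rep(seq_len(ncol(pairs)), config$forced_choice_reps)
  idx <- if (length(idx)) sample(idx) else integer(0)
  n <- length(idx)
  out <- empty_slot_tbl(n)
  if (n == 0L) {
    out$stage <- character(0)
    return(out)
  }
  flip <- runif(n) < 0.5
  a <- pairs[1, idx]
  b <- pairs[2, idx]
  out$stage <- "forced_choice"
  out$trial <- seq_len(n)
  out$cs_left <- ifelse(flip, b, a)
  out$cs_right <- ifelse(flip, a, b)
  out
}

#' Build all four stage schedules at once
#'
#' @inheritParams build_instrumental_schedule
#' @return A named list of tibbles: `instrumental`, `pavlovian`, `pit`,
#'   `forced_choice`.
#' @export
build_task_schedule <- function(config = task_config()) {
  list(
    instrumental = build_instrumental_schedule(config),
    pavlovian = build_pavlovian_schedule(config),
    pit = build_pit_schedule(config),
    forced_choice = build_forced_choice_schedule(config)
  )
}
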