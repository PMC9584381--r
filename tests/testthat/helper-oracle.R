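# Independent trial-by-trial replay of the learning-model arithmetic, written
# directly from the equations (sigmoid choice rule, delta-rule update, additive
# transfer weights) without using the package's likelihood path. Serves as the
# oracle the compiled likelihood is checked against.

# canonical instrumental parameters: named c(eps_rew, eps_pun, rho_rew,
# rho_pun, b) in natural space
oracle_instr_replay <- function(can, trials) {
  Q <- matrix(0, 2, 2, dimnames = list(c("good", "bad"), c("collect", "refrain")))
  ll <- 0
  for (i in seq_len(nrow(trials))) {
    s <- if (substr(trials$instrumental_stimulus[i], 1, 1) == "G") "good" else "bad"
    p <- 1 / (1 + exp(-((Q[s, "collect"] + can[["b"]]) - Q[s, "refrain"])))
    a <- trials$action[i]
    ll <- ll + log(if (a == "collect") p else 1 - p)
    r <- trials$feedback[i]
    eps <- if (r > 0) can[["eps_rew"]] else can[["eps_pun"]]
    rho <- if (r > 0) can[["rho_rew"]] else can[["rho_pun"]]
    Q[s, a] <- Q[s, a] + eps * (rho * r - Q[s, a])
  }
  list(loglik = ll, Q = Q)
}

# canonical transfer parameters: named c(f_plus, f_zero, f_minus, alpha,
# eta_good, eta_bad); Q/bias are the carried-over end-of-training values
oracle_pit_loglik <- function(tr, Q, bias, trials) {
  fmap <- c("CS+" = "f_plus", "CS0" = "f_zero", "CS-" = "f_minus")
  ll <- 0
  for (i in seq_len(nrow(trials))) {
    s <- if (substr(trials$instrumental_stimulus[i], 1, 1) == "G") "good" else "bad"
    wc <- Q[s, "collect"] + bias + tr[[fmap[[trials$pavlovian_stimulus[i]]]]] +
      tr[[paste0("eta_", s)]]
    wr <- Q[s, "refrain"]
    p <- 1 / (1 + exp(-(wc - wr)))
    a <- trials$action[i]
    ll <- ll + log(if (a == "collect") p else 1 - p)
    Q <- Q * tr[["alpha"]]
  }
  ll
}

# Map a model's natural parameter vector to the canonical instrumental /
# transfer parameterizations (re-derived here, independently of the package).
oracle_canonical_instr <- function(natural) {
  g <- function(nm, alt = NULL, default = 0) {
    if (nm %in% names(natural)) natural[[nm]]
    else if (!is.null(alt) && alt %in% names(natural)) natural[[alt]]
    else default
  }
  c(eps_rew = g("eps_rew", "eps"), eps_pun = g("eps_pun", "eps"),
    rho_rew = g("rho_rew", "rho"), rho_pun = g("rho_pun", "rho"),
    b = g("b"))
}

oracle_canonical_transfer <- function(natural) {
  g <- function(nm, default) if (nm %in% names(natural)) natural[[nm]] else default
  c(f_plus = g("f_plus", 0), f_zero = g("f_zero", 0), f_minus = g("f_minus", 0),
    alpha = g("alpha", 1), eta_good = g("eta_good", 0), eta_bad = g("eta_bad", 0))
}

# Exhaustively enumerate every action path of an instrumental scenario in
# which feedback is a fixed function of (trial, action): returns one row per
# path with its probability under the model.
oracle_enumerate_instr <- function(can, stims, feedback_tbl) {
  n <- length(stims)
  grid <- expand.grid(rep(list(c("collect", "refrain")), n),
                      stringsAsFactors = FALSE)
  probs <- apply(grid, 1, function(acts) {
    fb <- vapply(seq_len(n), function(t) feedback_tbl[t, acts[t]], 0)
    trials <- make_instr_trials(stims, unname(acts), fb)
    exp(oracle_instr_replay(can, trials)$loglik)
  })
  list(paths = grid, prob = probs)
}

# Minimal trial-table constructors for fixtures.
make_instr_trials <- function(stim, action, feedback, block = 3L,
                              subject_id = "s01") {
  n <- length(stim)
  tibble::tibble(
    subject_id = subject_id, stage = "instrumental",
    block = rep_len(block, n), trial = seq_len(n),
    instrumental_stimulus = stim, pavlovian_stimulus = NA_character_,
    cs_left = NA_character_, cs_right = NA_character_,
    action = action, keypresses = ifelse(action == "collect", 7L, 1L),
    feedback = as.integer(feedback), rewarded = feedback == 1
  )
}

make_pit_trials <- function(stim, cue, action, keypresses = NULL,
                            subject_id = "s01") {
  n <- length(stim)
  if (is.null(keypresses)) keypresses <- ifelse(action == "collect", 7L, 1L)
  tibble::tibble(
    subject_id = subject_id, stage = "pit",
    block = NA_integer_, trial = seq_len(n),
    instrumental_stimulus = stim, pavlovian_stimulus = cue,
    cs_left = NA_character_, cs_right = NA_character_,
    action = action, keypresses = as.integer(keypresses),
    feedback = NA_integer_, rewarded = NA
  )
}

make_fc_trials <- function(cs_left, cs_right, chosen, subject_id = "s01") {
  n <- length(cs_left)
  tibble::tibble(
    subject_id = subject_id, stage = "forced_choice",
    block = NA_integer_, trial = seq_len(n),
    instrumental_stimulus = NA_character_, pavlovian_stimulus = NA_character_,
    cs_left = cs_left, cs_right = cs_right,
    action = chosen, keypresses = NA_integer_,
    feedback = NA_integer_, rewarded = NA
  )
}

# Hand-built subject fit (for moment-update and evidence oracles).
make_subject_fit <- function(theta, hessian, log_posterior = 0,
                             log_likelihood = 0) {
  structure(list(theta_map = theta, hessian = hessian,
                 log_posterior = log_posterior,
                 log_likelihood = log_likelihood,
                 n_restarts_used = 1L, converged = TRUE, hessian_jitter = 0),
            class = "pit_subject_fit")
}

# random natural parameter draw for any model (used by property loops)
random_natural <- function(spec) {
  vals <- vapply(spec$transforms, function(tr) {
    switch(tr,
           unit_interval = runif(1, 0.05, 0.95),
           positive = exp(runif(1, -0.5, 1)),
           identity = runif(1, -1.5, 1.5))
  }, 0)
  names(vals) <- spec$parameters
  vals
}

random_instr_trials <- function(n) {
  make_instr_trials(sample(c("G1", "G2", "B1", "B2"), n, replace = TRUE),
                    sample(c("collect", "refrain"), n, replace = TRUE),
                    sample(c(-1L, 1L), n, replace = TRUE))
}

random_pit_trials <- function(n) {
  make_pit_trials(sample(c("G1", "G2", "B1", "B2"), n, replace = TRUE),
                  sample(c("CS+", "CS0", "CS-"), n, replace = TRUE),
                  sample(c("collect", "refrain"), n, replace = TRUE))
}
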