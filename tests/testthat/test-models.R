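test_that("model registry exposes the nine-model space with the right layouts", {
  expect_equal(length(list_models()), 9L)
  expect_equal(model_spec("M1")$parameters, c("eps", "rho"))
  expect_equal(model_spec("M4")$parameters, c("eps_rew", "eps_pun", "rho", "b"))
  expect_equal(model_spec("M6")$parameters, c("eps", "rho_rew", "rho_pun", "b"))
  expect_equal(model_spec("M4+M9")$parameters,
               c("f_plus", "f_zero", "f_minus", "eta_good", "eta_bad"))
  expect_equal(model_spec("M4+M8")$d, 4L)
  for (id in list_models()) expect_equal(model_spec(id)$d,
                                         length(model_spec(id)$parameters))
  joint <- model_spec("M4+M9", joint = TRUE)
  expect_equal(joint$d, 9L)
  expect_equal(joint$stage, "joint")
  expect_error(model_spec("M10"), "unknown")
})

test_that("parameter transforms map correctly and invert to 1e-10", {
  sp <- model_spec("M4")
  nat <- to_natural(c(0, 0, 0, 0), sp)
  expect_equal(unname(nat), c(0.5, 0.5, 1, 0))
  set.seed(21)
  for (id in list_models()) {
    spec <- model_spec(id)
    th <- rnorm(spec$d, 0, 2)
    expect_equal(unname(to_unconstrained(to_natural(th, spec), spec)),
                 th, tolerance = 1e-10)
    n <- to_natural(th, spec)
    tr <- spec$transforms
    expect_true(all(n[tr == "unit_interval"] > 0 & n[tr == "unit_interval"] < 1))
    expect_true(all(n[tr == "positive"] > 0))
  }
  expect_error(to_natural(c(0, NA, 0, 0), sp), "finite")
})

test_that("instrumental weights add the bias to the collect action only", {
  Q <- action_value_table()
  expect_equal(instrumental_weight(Q, 0, "good"), c(collect = 0, refrain = 0))
  Q2 <- action_value_table(good_collect = 1, good_refrain = -1)
  expect_equal(instrumental_weight(Q2, 0.5, "good"),
               c(collect = 1.5, refrain = -1))
  expect_equal(instrumental_weight(Q2, 0.5, "good")[["refrain"]],
               Q2["good", "refrain"])
})

test_that("softmax choice probability has the logistic closed form", {
  expect_equal(choice_prob(2, 2), 0.5)
  expect_equal(choice_prob(log(3), 0), 0.75)
  d <- seq(-3, 3, by = 0.5)
  p <- choice_prob(d, 0)
  expect_true(all(diff(p) > 0))
  expect_equal(choice_prob(800, 0), 1)
  expect_equal(choice_prob(-800, 0), 0)
})

test_that("value updates follow the delta rule with signed rate/sensitivity selection", {
  pars <- c(eps_rew = 0.5, eps_pun = 0.25, rho_rew = 2, rho_pun = 1)
  Q <- action_value_table()
  Q1 <- update_q(Q, "good", "collect", 1, pars)
  expect_equal(Q1["good", "collect"], 1.0)  # 0 + 0.5*(2*1 - 0)
  expect_equal(Q1["bad", "collect"], 0)
  expect_equal(Q1["good", "refrain"], 0)
  Q2 <- action_value_table(good_collect = 1)
  Q3 <- update_q(Q2, "good", "collect", -1, pars)
  expect_equal(Q3["good", "collect"], 0.5)  # 1 + 0.25*(-1 - 1)
  # fixed point: repeated reward drives Q to rho_rew * r
  Qi <- action_value_table()
  for (i in 1:200) Qi <- update_q(Qi, "bad", "refrain", 1, pars)
  expect_equal(Qi["bad", "refrain"], 2, tolerance = 1e-10)
  expect_error(update_q(Q, "good", "collect", NA, pars), "feedback")
  expect_error(update_q(Q, "good", "collect", 0, pars), "feedback")
})

test_that("value decay is geometric and bounded", {
  Q <- action_value_table(2, 2, 2, 2)
  expect_equal(decay_q(Q, 1), Q)
  expect_true(all(decay_q(Q, 0) == 0))
  expect_equal(decay_q(decay_q(Q, 0.5), 0.5)["good", "collect"], 0.5)
  expect_error(decay_q(Q, 1.5), "alpha")
})

test_that("transfer weights add cue factors and category noise to collect only", {
  f <- c(f_plus = 1, f_zero = 0, f_minus = -2)
  eta0 <- c(eta_good = 0, eta_bad = 0)
  W <- c(collect = 1, refrain = 0)
  expect_equal(pit_weight(W, c(f_plus = 0, f_zero = 0, f_minus = 0), eta0,
                          "CS0", "good"), W)
  expect_equal(pit_weight(W, f, eta0, "CS-", "good"),
               c(collect = -1, refrain = 0))
  eta <- c(eta_good = 0.4, eta_bad = -0.2)
  w <- pit_weight(W, f, eta, "CS+", "bad")
  expect_equal(w[["collect"]], 1 + 1 - 0.2)
  expect_equal(w[["refrain"]], 0)
})

test_that("sequence log-likelihood matches the independent replay oracle on every model", {
  set.seed(31)
  for (id in list_models()) {
    spec <- model_spec(id)
    for (rep in 1:5) {
      nat <- random_natural(spec)
      if (spec$stage == "instrumental") {
        trials <- random_instr_trials(4)
        got <- sequence_loglik(spec, nat, trials, space = "natural")
        want <- oracle_instr_replay(oracle_canonical_instr(nat), trials)$loglik
      } else {
        co <- list(Q = action_value_table(1.2, 0.1, -0.3, 0.9), bias = 0.4)
        trials <- random_pit_trials(4)
        got <- sequence_loglik(spec, nat, trials, carryover = co, space = "natural")
        want <- oracle_pit_loglik(oracle_canonical_transfer(nat), co$Q, co$bias,
                                  trials)
      }
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("likelihood normalizes: path probabilities sum to one under enumeration", {
  set.seed(32)
  can <- c(eps_rew = 0.4, eps_pun = 0.15, rho_rew = 1.5, rho_pun = 0.8, b = 0.3)
  stims <- c("G1", "B1", "G1")
  fb <- matrix(c(1, -1, -1, 1, 1, -1), nrow = 3,
               dimnames = list(NULL, c("collect", "refrain")))
  enum <- oracle_enumerate_instr(can, stims, fb)
  expect_equal(sum(enum$prob), 1, tolerance = 1e-10)
  # each enumerated path probability equals the package likelihood of that path
  spec <- model_spec("M4")
  nat <- c(eps_rew = 0.4, eps_pun = 0.15, rho = 1.5, b = 0.3)
  can_m4 <- c(eps_rew = 0.4, eps_pun = 0.15, rho_rew = 1.5, rho_pun = 1.5, b = 0.3)
  enum4 <- oracle_enumerate_instr(can_m4, stims, fb)
  for (i in seq_along(enum4$prob)) {
    acts <- unlist(enum4$paths[i, ])
    fbs <- vapply(1:3, function(t) fb[t, acts[t]], 0)
    trials <- make_instr_trials(stims, unname(acts), fbs)
    expect_equal(sequence_loglik(spec, nat, trials, space = "natural"),
                 log(enum4$prob[i]), tolerance = 1e-10)
  }
})

test_that("single symmetric trial has log-likelihood log(1/2)", {
  spec <- model_spec("M1")
  trials <- make_instr_trials("G1", "collect", 1)
  expect_equal(sequence_loglik(spec, c(0, 0), trials), log(0.5))
  # the two possible actions exhaust probability
  t2 <- make_instr_trials("G1", "refrain", 1)
  ll <- sequence_loglik(spec, c(0.3, -0.2), trials) |> exp()
  ll2 <- sequence_loglik(spec, c(0.3, -0.2), t2) |> exp()
  expect_equal(ll + ll2, 1, tolerance = 1e-12)
})

test_that("nested models agree exactly on the shared manifold", {
  set.seed(33)
  trials <- random_instr_trials(30)
  eps <- 0.35; rho <- 1.7
  ll1 <- sequence_loglik(model_spec("M1"), c(eps = eps, rho = rho), trials,
                         space = "natural")
  ll3 <- sequence_loglik(model_spec("M3"),
                         c(eps_rew = eps, eps_pun = eps, rho = rho), trials,
                         space = "natural")
  ll5 <- sequence_loglik(model_spec("M5"),
                         c(eps = eps, rho_rew = rho, rho_pun = rho), trials,
                         space = "natural")
  expect_identical(ll1, ll3)
  expect_identical(ll1, ll5)

  co <- list(Q = action_value_table(1.1, 0.2, -0.4, 0.8), bias = 0.25)
  pit <- random_pit_trials(30)
  f <- c(f_plus = 0.9, f_zero = 0.1, f_minus = -1.2)
  ll7 <- sequence_loglik(model_spec("M4+M7"), f, pit, carryover = co,
                         space = "natural")
  ll8 <- sequence_loglik(model_spec("M4+M8"), c(f, alpha = 1), pit,
                         carryover = co, space = "natural")
  ll9 <- sequence_loglik(model_spec("M4+M9"),
                         c(f, eta_good = 0, eta_bad = 0), pit,
                         carryover = co, space = "natural")
  expect_identical(ll7, ll8)
  expect_identical(ll7, ll9)
})

test_that("likelihood is invariant to relabeling shells within a category", {
  set.seed(34)
  trials <- random_instr_trials(25)
  swapped <- trials
  swapped$instrumental_stimulus <- c(G1 = "G2", G2 = "G1", B1 = "B2",
                                     B2 = "B1")[trials$instrumental_stimulus]
  th <- c(0.4, -1, 0.6, 0.2)
  expect_identical(sequence_loglik(model_spec("M4"), th, trials),
                   sequence_loglik(model_spec("M4"), th, swapped))
})

test_that("malformed trial sequences are rejected", {
  spec <- model_spec("M4")
  instr <- make_instr_trials("G1", "collect", 1)
  no_fb <- instr; no_fb$feedback <- NA_integer_
  expect_error(sequence_loglik(spec, c(0, 0, 0, 0), no_fb), "feedback")
  pit <- make_pit_trials("G1", "CS+", "collect")
  with_fb <- pit; with_fb$feedback <- 1L
  co <- list(Q = action_value_table(), bias = 0)
  expect_error(sequence_loglik(model_spec("M4+M7"), c(0, 0, 0), with_fb,
                               carryover = co), "extinction")
  expect_error(sequence_loglik(model_spec("M4+M7"), c(0, 0, 0), pit), "carryover")
  expect_error(sequence_loglik(spec, c(0, 0, 0, 0), pit), "instrumental")
})

test_that("joint specifications score both stages with shared parameters", {
  set.seed(35)
  instr <- random_instr_trials(20)
  pit <- random_pit_trials(15)
  both <- rbind(instr, pit)
  jspec <- model_spec("M4+M9", joint = TRUE)
  th <- rnorm(jspec$d, 0, 0.5)
  got <- sequence_loglik(jspec, th, both)
  # equals instrumental likelihood plus transfer likelihood at the implied carryover
  ispec <- model_spec("M4")
  th_i <- th[1:4]
  ll_i <- sequence_loglik(ispec, th_i, instr)
  co <- carryover_values(ispec, th_i, instr)
  ll_p <- sequence_loglik(model_spec("M4+M9"), th[5:9], pit, carryover = co)
  expect_equal(got, ll_i + ll_p, tolerance = 1e-12)
})

test_that("end-of-training carryover matches the oracle replay", {
  set.seed(36)
  trials <- random_instr_trials(15)
  nat <- c(eps_rew = 0.5, eps_pun = 0.2, rho = 1.4, b = 0.3)
  co <- carryover_values(model_spec("M4"), nat, trials, space = "natural")
  want <- oracle_instr_replay(oracle_canonical_instr(nat), trials)$Q
  expect_equal(co$Q, want, tolerance = 1e-12)
  expect_equal(co$bias, 0.3)
})
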