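test_that("with no data the MAP estimate is the prior mean", {
  sp <- model_spec("M1")
  empty <- make_instr_trials(character(0), character(0), integer(0))
  pr <- group_prior(c(0, 0), c(1, 1), sp$parameters)
  fit <- map_fit(empty, sp, pr, n_restarts = 1)
  expect_equal(unname(fit$theta_map), c(0, 0), tolerance = 1e-6)
  expect_equal(fit$log_likelihood, 0)
  # prior-only posterior: Hessian is the prior precision
  expect_equal(unname(diag(fit$hessian)), c(1, 1), tolerance = 1e-4)
})

test_that("a diffuse prior recovers a long subject's generating parameters", {
  # consistency of the MAP estimator: with ~6000 trials and an essentially
  # flat prior (variance 1e6, a vanishing-prior surrogate), natural-space
  # learning rates and sensitivity land within 20% of the truth and the
  # bias within 0.15; the punishment learning rate is the least identified
  # because most feedback is reward
  cfg <- task_config(block1_trials = 3000, block2_trials = 3000,
                     block3_max_trials = 40, criterion_accuracy = 1)
  sp <- model_spec("M4")
  th <- c(eps_rew = 0.5, eps_pun = -1.5, rho = 0.7, b = 0.3)
  dat <- simulate_subject(subject_parameters(sp, th), config = cfg, seed = 61)
  instr <- dat[dat$stage == "instrumental", ]
  flat <- group_prior(rep(0, 4), rep(1e6, 4), sp$parameters)
  set.seed(62)
  fit <- map_fit(instr, sp, flat, n_restarts = 2)
  est <- to_natural(fit$theta_map, sp)
  truth <- to_natural(th, sp)
  rel <- abs(est - truth) / truth
  expect_true(all(rel[c("eps_rew", "eps_pun", "rho")] < 0.20))
  expect_lt(abs(est[["b"]] - truth[["b"]]), 0.15)
})

test_that("the MAP objective never falls below its value at the prior mean", {
  set.seed(63)
  sp <- model_spec("M4")
  pr <- default_group_prior(sp)
  for (r in 1:3) {
    trials <- random_instr_trials(40)
    fit <- map_fit(trials, sp, pr, n_restarts = 2)
    at_mean <- sequence_loglik(sp, pr$mean, trials) +
      sum(dnorm(pr$mean, pr$mean, sqrt(pr$variance), log = TRUE))
    expect_gte(fit$log_posterior, at_mean - 1e-8)
  }
})

test_that("the EM moment update matches hand-computed moments", {
  f1 <- make_subject_fit(c(x = 0), matrix(1e12, dimnames = list("x", "x")))
  f2 <- make_subject_fit(c(x = 2), matrix(1e12, dimnames = list("x", "x")))
  pr <- em_update_group(list(f1, f2))
  expect_equal(unname(pr$mean), 1)
  expect_equal(unname(pr$variance), 1, tolerance = 1e-6)
  # identical subjects with vanishing posterior variance: floor engages
  pr2 <- em_update_group(list(f1, f1))
  expect_equal(unname(pr2$variance), 1e-6)
  # extra per-subject uncertainty only increases the variance estimate
  f3 <- make_subject_fit(c(x = 0), matrix(2, dimnames = list("x", "x")))
  f4 <- make_subject_fit(c(x = 2), matrix(2, dimnames = list("x", "x")))
  pr3 <- em_update_group(list(f3, f4))
  expect_gte(unname(pr3$variance), unname(pr$variance))
  expect_equal(unname(pr3$variance), 1 + 0.5, tolerance = 1e-6)
  expect_error(em_update_group(list(f1)), "two")
})

test_that("em_fit with zero iterations fits under the initial wide prior", {
  set.seed(64)
  coh <- simulate_cohort(3, "M4", seed = 64)
  sp <- model_spec("M4")
  res <- em_fit(coh$trials, sp, max_iter = 0, n_restarts = 1)
  expect_equal(res$em_iterations, 0L)
  expect_equal(unname(res$group_prior$variance), rep(10, 4))
  instr <- coh$trials[coh$trials$stage == "instrumental", ]
  for (id in names(res$subject_fits)) {
    direct <- map_fit(instr[instr$subject_id == id, ], sp,
                      default_group_prior(sp), n_restarts = 1)
    expect_equal(res$subject_fits[[id]]$theta_map, direct$theta_map,
                 tolerance = 1e-8)
  }
})

test_that("EM iterations shrink the group variance below the wide prior", {
  coh <- simulate_cohort(10, "M4", seed = 65)
  res <- em_fit(coh$trials, model_spec("M4"), max_iter = 3, n_restarts = 1)
  expect_true(all(res$group_prior$variance > 0))
  expect_true(all(res$group_prior$variance < 10))
  expect_equal(length(res$em_trace), res$em_iterations + 1L)
  expect_true(all(is.finite(res$em_trace)))
})

test_that("group labels never enter the fit", {
  coh <- simulate_cohort(6, "M4", group = rep(c("a", "b"), 3), seed = 66)
  relabeled <- coh$trials
  relabeled$group <- rev(relabeled$group)
  a <- em_fit(coh$trials, model_spec("M4"), max_iter = 1, n_restarts = 1)
  b <- em_fit(relabeled, model_spec("M4"), max_iter = 1, n_restarts = 1)
  expect_equal(a$group_prior, b$group_prior)
  expect_equal(a$subject_fits[[1]]$theta_map, b$subject_fits[[1]]$theta_map)
})

test_that("two-stage transfer fitting conditions on frozen carryover values", {
  set.seed(67)
  coh <- simulate_cohort(4, "M4", transfer_model = "M4+M9", seed = 67)
  res <- fit_transfer(coh$trials, model = "M4+M9", max_iter = 1, n_restarts = 1)
  expect_s3_class(res$transfer, "pit_fit")
  expect_equal(res$transfer$spec$id, "M4+M9")
  expect_equal(sort(names(res$carryover)),
               sort(names(res$instrumental$subject_fits)))
  # transfer likelihood of a subject evaluates under that subject's carryover
  id <- names(res$carryover)[1]
  pit <- coh$trials[coh$trials$stage == "pit" & coh$trials$subject_id == id, ]
  ll <- sequence_loglik(model_spec("M4+M9"),
                        res$transfer$subject_fits[[id]]$theta_map, pit,
                        carryover = res$carryover[[id]])
  expect_equal(ll, res$transfer$subject_fits[[id]]$log_likelihood,
               tolerance = 1e-8)
})

test_that("fit results serialize to JSON and tidy parameter tables", {
  coh <- simulate_cohort(3, "M4", seed = 68)
  res <- em_fit(coh$trials, model_spec("M4"), max_iter = 1, n_restarts = 1)
  tab <- parameter_table(res)
  expect_equal(nrow(tab), 3 * 4)
  expect_true(all(c("unconstrained", "natural") %in% names(tab)))
  path <- tempfile(fileext = ".json")
  write_fit(res, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$model, "M4")
  expect_equal(length(parsed$subjects), 3L)
})
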