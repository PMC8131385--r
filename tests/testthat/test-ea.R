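make_series <- function(n_sessions, l1, l2) {
  data.frame(session = 0:n_sessions, score_L1 = l1, score_L2 = l2)
}

test_that("the fitness formula matches its hand-computed example", {
  # one patient, one session: E = (0,1) vs (0,0), S identical
  obs <- list(A = make_series(1, c(0.2, 0.2), c(0, 1)))
  sim <- list(A = make_series(1, c(0.2, 0.2), c(0, 0)))
  expect_equal(err_fitness(sim, obs), 1.0)
  # perfect prediction
  expect_equal(err_fitness(obs, obs), 0)
  # duplicating a patient leaves the mean unchanged
  obs2 <- c(obs, list(B = obs$A))
  sim2 <- c(sim, list(B = sim$A))
  expect_equal(err_fitness(sim2, obs2), 1.0)
})

test_that("the fitness equals a naive nested-loop recomputation", {
  with_seed(17, {
    for (rep in 1:5) {
      ns <- sample(3:6, 3, replace = TRUE)
      obs <- sim <- list()
      for (i in 1:3) {
        p <- paste0("P", i)
        obs[[p]] <- make_series(ns[i], stats::runif(ns[i] + 1),
                                stats::runif(ns[i] + 1))
        sim[[p]] <- make_series(ns[i], stats::runif(ns[i] + 1),
                                stats::runif(ns[i] + 1))
      }
      # naive double loop over patients and sessions
      tot <- 0
      for (p in names(obs)) {
        acc <- 0
        for (j in seq_len(nrow(obs[[p]]))) {
          acc <- acc + (obs[[p]]$score_L2[j] - sim[[p]]$score_L2[j])^2 +
            (obs[[p]]$score_L1[j] - sim[[p]]$score_L1[j])^2
        }
        tot <- tot + acc / (nrow(obs[[p]]) - 1)
      }
      expect_equal(err_fitness(sim, obs), tot / 3)
    }
  })
})

test_that("misaligned or missing series are rejected with the patient named", {
  obs <- list(A = make_series(2, c(0, 0, 0), c(0, 0, 0)))
  sim <- list(A = make_series(3, rep(0, 4), rep(0, 4)))
  expect_error(err_fitness(sim, obs), "session mismatch for patient A")
  expect_error(err_fitness(list(), obs), "missing probe series")
  # alternative normalization divides by the number of points
  obs1 <- list(A = make_series(1, c(0, 0), c(0, 1)))
  sim1 <- list(A = make_series(1, c(0, 0), c(0, 0)))
  expect_equal(err_fitness(sim1, obs1, normalize_by = "n_points"), 0.5)
})

test_that("the evolver keeps an elitist monotone best-so-far and restarts", {
  # deterministic synthetic objective: no simulations involved
  eval_fn <- function(p) (log10(p$rate_step2) + 1)^2 +
    0.1 * (p$cond_3a != "all")
  cfg <- ea_config(population_size = 8, max_generations = 30,
                   stagnation_restart = 5)
  res <- evolve(cfg, eval_fn, seed = 3)
  expect_true(all(diff(res$trace$best_so_far) <= 0))
  expect_lte(res$best$fitness, min(res$trace$best_generation))
  # restarts fire only after the stagnation window without improvement
  stag <- 0
  for (g in seq_len(nrow(res$trace))) {
    if (res$trace$restarted[g]) expect_gte(stag, 5)
    if (g > 1 && res$trace$best_so_far[g] < res$trace$best_so_far[g - 1]) {
      stag <- 0
    } else {
      stag <- stag + 1
    }
  }
  # converges near the optimum rate 0.1 on this smooth objective
  expect_lt(abs(log10(res$best$params$rate_step2) + 1), 0.3)
  expect_identical(res$best$params$cond_3a, "all")
})

test_that("candidate evaluation is deterministic and cached", {
  m <- lesioned_toy()
  prof <- toy_profile("L2", n_sessions = 3)
  profs <- as.data.frame(prof, stringsAsFactors = FALSE)
  plan <- select_treatment_words(m, naming_accuracy(m, m$lexicon$id, "L2"),
                                 "L2", seed = 5)
  truth <- treatment_params(0.1, 0.1, 0.05, 0.05)
  obs <- list(SYN = simulate_probe_series(truth, prof, m, plan,
                                          words_per_year = 600, seed = 3))
  models <- list(SYN = m); plans <- list(SYN = plan)
  f1 <- evaluate_candidate(truth, models, plans, obs, profs, seed = 7,
                           words_per_year = 600)
  f2 <- evaluate_candidate(truth, models, plans, obs, profs, seed = 7,
                           words_per_year = 600)
  expect_identical(f1, f2)
  expect_gte(f1, 0)
  cache <- new.env(parent = emptyenv())
  f3 <- evaluate_candidate(truth, models, plans, obs, profs, seed = 7,
                           words_per_year = 600, cache = cache)
  expect_identical(f3, f1)
  expect_identical(length(ls(cache)), 1L)
  # zero-rate candidate equals the closed-form baseline-persistence error
  zero <- treatment_params(0, 0, 0, 0)
  fz <- evaluate_candidate(zero, models, plans, obs, profs, seed = 7,
                           words_per_year = 0)
  base <- obs$SYN[1, ]
  persist <- obs$SYN
  persist$score_L1[] <- base$score_L1
  persist$score_L2[] <- base$score_L2
  expect_equal(fz, err_fitness(list(SYN = persist), obs))
})

test_that("leave-one-out never touches the held-out series during training", {
  m <- lesioned_toy()
  profs <- do.call(rbind, lapply(c("A", "B", "C"), function(p) {
    d <- as.data.frame(toy_profile("L2", n_sessions = 2),
                       stringsAsFactors = FALSE)
    d$patient_id <- p
    d
  }))
  plan <- select_treatment_words(m, naming_accuracy(m, m$lexicon$id, "L2"),
                                 "L2", seed = 5)
  truth <- treatment_params(0.1, 0.1, 0, 0)
  models <- list(A = m, B = m, C = m)
  plans <- list(A = plan, B = plan, C = plan)
  obs <- lapply(models, function(mm)
    simulate_probe_series(truth, profs[1, ], mm, plan,
                          words_per_year = 600, seed = 3))
  names(obs) <- names(models)
  cfg <- ea_config(population_size = 3, max_generations = 2,
                   stagnation_restart = 2)
  # isolation: with the held-out series poisoned, training on the remaining
  # patients and predicting the held-out one must never touch it
  poisoned <- obs
  poisoned$C <- structure("POISONED", class = "poison")
  fit <- fit_treatment_params(poisoned[c("A", "B")], models, plans, profs,
                              patients = c("A", "B"), config = cfg,
                              words_per_year = 600, seed = 9)
  pred <- predict(fit, models$C, plans$C, profs[profs$patient_id == "C", ],
                  n_sessions = 2, repeats = 2, seed = 10)
  expect_identical(nrow(pred), 3L)
  # full cross-validation driver: one fit per patient, each trained on the
  # other two, with held-out errors reported
  loo <- leave_one_out(obs, models, plans, profs, config = cfg,
                       words_per_year = 600, repeats_predict = 2, seed = 9)
  expect_s3_class(loo, "bilex_loo")
  expect_identical(names(loo$predictions), c("A", "B", "C"))
  expect_identical(names(loo$fits), c("A", "B", "C"))
  expect_setequal(loo$fits$A$patients, c("B", "C"))
  expect_true(all(is.finite(loo$summary$heldout_err)))
  expect_error(leave_one_out(obs["A"], models, plans, profs, config = cfg),
               "fewer than 2")
})

test_that("the fitted parameter object exposes the modelling interface", {
  m <- lesioned_toy()
  prof <- toy_profile("L2", n_sessions = 2)
  profs <- as.data.frame(prof, stringsAsFactors = FALSE)
  plan <- select_treatment_words(m, naming_accuracy(m, m$lexicon$id, "L2"),
                                 "L2", seed = 5)
  truth <- treatment_params(0.1, 0.1, 0, 0)
  obs <- list(SYN = simulate_probe_series(truth, prof, m, plan,
                                          words_per_year = 600, seed = 3))
  cfg <- ea_config(population_size = 4, max_generations = 3,
                   stagnation_restart = 3)
  fit <- fit_treatment_params(obs, list(SYN = m), list(SYN = plan), profs,
                              config = cfg, words_per_year = 600, seed = 11)
  expect_s3_class(fit, "bilex_ea_fit")
  co <- coef(fit)
  expect_identical(names(co)[1:4], c("rate_step1", "rate_step2",
                                     "rate_step3a", "rate_step3b"))
  expect_identical(nrow(fit$trace), 3L)
  pred <- predict(fit, m, plan, prof, repeats = 3, seed = 12)
  expect_identical(pred$session, 0:2)
  expect_true(all(pred$score_L2_min <= pred$score_L2))
  expect_true(all(pred$score_L2 <= pred$score_L2_max))
  out <- utils::capture.output(print(fit))
  expect_true(any(grepl("best fitness", out)))
})
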