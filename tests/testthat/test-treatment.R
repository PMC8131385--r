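test_that("treatment parameter validation enforces the six-gene contract", {
  p <- treatment_params(0.1, 0.2, 0, 0.05, "all", "translatable")
  expect_s3_class(p, "treatment_params")
  expect_error(treatment_params(-0.1, 0, 0, 0), "non-negative")
  expect_error(treatment_params(0, 0, 0, Inf), "finite")
  expect_error(treatment_params(0, 0, 0, 0, cond_3a = "sometimes"),
               "conditions")
})

test_that("treatment word selection matches the target baseline", {
  m <- lesioned_toy()
  lex <- m$lexicon
  global <- naming_accuracy(m, lex$id, "L2")
  plan <- select_treatment_words(m, global, "L2", n = 30, seed = 5)
  expect_identical(length(plan$word_ids), 30L)
  expect_identical(anyDuplicated(plan$word_ids), 0L)
  # re-score the returned set: within tolerance of the target
  expect_lte(abs(naming_accuracy(m, plan$word_ids, "L2") - global), 0.05)
  # determinism
  plan2 <- select_treatment_words(m, global, "L2", n = 30, seed = 5)
  expect_identical(plan$word_ids, plan2$word_ids)
  # unreachable target: returns closest achievable with recorded deviation
  dead <- apply_lesion(m, "L2", 1)
  plan3 <- select_treatment_words(dead, 0.5, "L2", n = 30, seed = 6)
  expect_equal(unname(plan3$baseline[["L2"]]), 0)
  expect_equal(plan3$deviation, 0.5)
  # zero target on a destroyed map: a set named 0/30
  plan4 <- select_treatment_words(dead, 0, "L2", n = 30, seed = 7)
  expect_equal(naming_accuracy(dead, plan4$word_ids, "L2"), 0)
})

test_that("zero learning rates make a session a probe-level no-op", {
  m <- lesioned_toy()
  plan <- select_treatment_words(m, naming_accuracy(m, m$lexicon$id, "L2"),
                                 "L2", seed = 5)
  before <- vapply(c("L1", "L2"), function(l)
    naming_accuracy(m, plan$word_ids, l), numeric(1))
  s <- run_session(m, plan, treatment_params(0, 0, 0, 0), seed = 6)
  expect_equal(unname(s$scores), unname(before))
  expect_equal(s$model$sem$W, m$sem$W)
  expect_equal(s$model$links, m$links)
})

test_that("condition masks gate step 3a exactly as instrumented", {
  m <- lesioned_toy()
  plan <- select_treatment_words(m, naming_accuracy(m, m$lexicon$id, "L2"),
                                 "L2", seed = 5)
  s <- run_session(m, plan, treatment_params(0.05, 0.05, 0.05, 0.05,
                                             "named_in_treated", "all"),
                   seed = 6)
  named_now <- vapply(plan$word_ids, function(w)
    name_word(m, w, "L2")$correct, logical(1))
  expect_identical(as.logical(s$named), unname(named_now))
  transl_now <- vapply(plan$word_ids, function(w)
    translate_word(m, w, "L2"), logical(1))
  expect_identical(as.logical(s$translatable), unname(transl_now))
})

test_that("session randomness is reproducible given the seed", {
  m <- lesioned_toy()
  plan <- select_treatment_words(m, naming_accuracy(m, m$lexicon$id, "L2"),
                                 "L2", seed = 5)
  pars <- treatment_params(0.1, 0.1, 0.05, 0.05)
  a <- run_session(m, plan, pars, seed = 11)
  b <- run_session(m, plan, pars, seed = 11)
  expect_identical(a$model, b$model)
  expect_identical(a$scores, b$scores)
})

test_that("a treatment course improves the treated language on a moderate lesion", {
  m <- lesioned_toy()
  prof <- toy_profile("L2", n_sessions = 8)
  plan <- select_treatment_words(m, naming_accuracy(m, m$lexicon$id, "L2"),
                                 "L2", seed = 5)
  pars <- treatment_params(0.1, 0.1, 0.05, 0.05)
  tr <- run_treatment(m, plan, pars, prof, words_per_year = 600, seed = 6)
  expect_identical(nrow(tr), 9L)
  expect_identical(tr$session, 0:8)
  expect_gt(tr$score_L2[9], tr$score_L2[1])
  # reproducibility of the full series
  tr2 <- run_treatment(m, plan, pars, prof, words_per_year = 600, seed = 6)
  expect_identical(tr, tr2)
  # n_sessions = 0: only the baseline row
  tr0 <- run_treatment(m, plan, pars, prof, n_sessions = 0, seed = 6)
  expect_identical(nrow(tr0), 1L)
})

test_that("without cross-language steps and exposure, the untreated set is frozen", {
  m <- lesioned_toy()
  prof <- toy_profile("L2", n_sessions = 5)
  plan <- select_treatment_words(m, naming_accuracy(m, m$lexicon$id, "L2"),
                                 "L2", seed = 5)
  pars <- treatment_params(0.05, 0.05, 0, 0)
  tr <- run_treatment(m, plan, pars, prof, between_session_exposure = FALSE,
                      seed = 6)
  expect_true(all(tr$score_L1 == tr$score_L1[1]))
  expect_gte(tr$score_L2[6], tr$score_L2[1])
})

test_that("conditioned cross-language retraining never reduces untreated gains", {
  # the cross-language channel is consolidative: gated on words whose
  # translation survives, it protects (and may restore) untreated-language
  # associations, and must never do worse than disabling it
  m <- trained_toy()
  m <- apply_lesion(m, "L2", 0.7)
  m <- apply_lesion(m, "L1", 0.45)
  prof <- toy_profile("L2", n_sessions = 6)
  plan <- select_treatment_words(m, naming_accuracy(m, m$lexicon$id, "L2"),
                                 "L2", seed = 5)
  gain <- function(pars, s) {
    tr <- run_treatment(m, plan, pars, prof, words_per_year = 600, seed = s)
    tr$score_L1[nrow(tr)] - tr$score_L1[1]
  }
  with_cross <- vapply(1:10, function(s)
    gain(treatment_params(0.05, 0.1, 0.1, 0.05,
                          "translatable", "translatable"), s), numeric(1))
  without <- vapply(1:10, function(s)
    gain(treatment_params(0.05, 0.1, 0, 0), s), numeric(1))
  expect_gte(mean(with_cross), mean(without))
})

test_that("small-rate treatment does not regress the treated language", {
  m <- lesioned_toy()
  prof <- toy_profile("L2", n_sessions = 5)
  plan <- select_treatment_words(m, naming_accuracy(m, m$lexicon$id, "L2"),
                                 "L2", seed = 5)
  pars <- treatment_params(0.02, 0.05, 0.01, 0.01)
  ok <- vapply(1:10, function(s) {
    tr <- run_treatment(m, plan, pars, prof, words_per_year = 600, seed = s)
    tr$score_L2[nrow(tr)] >= tr$score_L2[1]
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("the clinical stopping rule halts at 80% treated-language naming", {
  m <- lesioned_toy()
  prof <- toy_profile("L2", n_sessions = 20)
  plan <- select_treatment_words(m, naming_accuracy(m, m$lexicon$id, "L2"),
                                 "L2", seed = 5)
  pars <- treatment_params(0.2, 0.3, 0.05, 0.05)
  tr <- run_treatment(m, plan, pars, prof, n_sessions = 20,
                      words_per_year = 600, stopping_rule = TRUE, seed = 6)
  stopped_at <- nrow(tr) - 1L
  expect_lt(stopped_at, 20L)
  treated <- tr$score_L2[-1]
  if (max(treated) > 0.8) {
    # halted at the first session exceeding 80%
    first <- which(treated > 0.8)[1]
    expect_identical(stopped_at, first)
  }
})

test_that("probe series simulated from known parameters behave as fixtures", {
  m <- lesioned_toy()
  prof <- toy_profile("L2", n_sessions = 4)
  truth <- treatment_params(0.1, 0.1, 0.05, 0.05)
  s1 <- simulate_probe_series(truth, prof, m, words_per_year = 600, seed = 3)
  s2 <- simulate_probe_series(truth, prof, m, words_per_year = 600, seed = 3)
  expect_identical(s1, s2)
  expect_identical(s1$session, 0:4)
  # zero learning rates with no exposure: flat series at baseline
  zero <- treatment_params(0, 0, 0, 0)
  plan <- select_treatment_words(m, 0.3, "L2", seed = 9)
  flat <- run_treatment(m, plan, zero, prof, between_session_exposure = FALSE,
                        seed = 3)
  expect_true(all(flat$score_L1 == flat$score_L1[1]))
  expect_true(all(flat$score_L2 == flat$score_L2[1]))
})
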