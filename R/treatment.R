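COND_LEVELS <- c("named_in_treated", "translatable", "all")

#' Six-parameter treatment protocol candidate
#'
#' The treatment simulation is governed by four learning rates (semantic
#' retraining, treated-language retrieval retraining, and the two
#' cross-language link-retraining steps) and two condition genes selecting
#' which treatment words the cross-language steps apply to.
#'
#' @param rate_step1 semantic-map retraining rate.
#' @param rate_step2 treated-language retrieval retraining rate.
#' @param rate_step3a rate for retraining semantic/untreated links.
#' @param rate_step3b rate for retraining phonetic/phonetic links.
#' @param cond_3a,cond_3b `"named_in_treated"`, `"translatable"` or `"all"`.
#' @return an object of class `treatment_params`.
#' @export
treatment_params <- function(rate_step1, rate_step2, rate_step3a, rate_step3b,
                             cond_3a = "all", cond_3b = "all") {
  rates <- c(rate_step1, rate_step2, rate_step3a, rate_step3b)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop_bilex("learning rates must be finite and non-negative")
  if (!cond_3a %in% COND_LEVELS || !cond_3b %in% COND_LEVELS)
    stop_bilex("conditions must be one of: ",
               paste(COND_LEVELS, collapse = ", "))
  structure(list(rate_step1 = rate_step1, rate_step2 = rate_step2,
                 rate_step3a = rate_step3a, rate_step3b = rate_step3b,
                 cond_3a = cond_3a, cond_3b = cond_3b),
            class = "treatment_params")
}

#' @export
print.treatment_params <- function(x, ...) {
  cat("Treatment protocol parameters:\n")
  cat(sprintf("  rates: step1=%.4g step2=%.4g step3a=%.4g step3b=%.4g\n",
              x$rate_step1, x$rate_step2, x$rate_step3a, x$rate_step3b))
  cat("  conditions: 3a=", x$cond_3a, ", 3b=", x$cond_3b, "\n", sep = "")
  invisible(x)
}

#' Select a baseline-matched treatment word set
#'
#' Samples 30-word sets until the model's treated-language naming proportion
#' on the set is within tolerance of the target baseline; after `max_draws`
#' failed draws the best draw is refined by greedy swaps (exchanging named
#' for unnamed words, or vice versa, with words outside the set). If the
#' target is unreachable the closest achievable set is returned with the
#' deviation recorded on the plan.
#'
#' @param model a lesioned poststroke `bilex_model`.
#' @param target_baseline target naming proportion in the treated language.
#' @param treated_language `"L1"` or `"L2"`.
#' @param n number of treatment words (30 by default).
#' @param tol acceptance tolerance on the baseline proportion.
#' @param max_draws random draws before greedy refinement.
#' @param seed integer seed.
#' @return an object of class `treatment_plan`: treated language, word ids,
#'   achieved per-language baseline on the set, and the target.
#' @export
select_treatment_words <- function(model, target_baseline, treated_language,
                                   n = 30, tol = 0.05, max_draws = 50,
                                   seed = 1) {
  check_language(treated_language)
  lex <- model$lexicon
  if (n > lex$n_words)
    stop_bilex("treatment set size ", n, " exceeds lexicon size ",
               lex$n_words)
  named_all <- naming_correct(model, lex$id, treated_language)$correct
  with_seed(seed, {
    best_ids <- NULL
    best_dev <- Inf
    for (d in seq_len(max_draws)) {
      ids <- sort(sample(lex$id, n))
      score <- mean(named_all[match(ids, lex$id)])
      dev <- abs(score - target_baseline)
      if (dev < best_dev) { best_dev <- dev; best_ids <- ids }
      if (dev <= tol) break
    }
    ids <- best_ids
    if (best_dev > tol) {
      # greedy swap refinement toward the target baseline
      repeat {
        inside <- match(ids, lex$id)
        score <- mean(named_all[inside])
        if (abs(score - target_baseline) <= tol) break
        outside <- setdiff(seq_len(lex$n_words), inside)
        if (score < target_baseline) {
          drop <- inside[!named_all[inside]]
          add <- outside[named_all[outside]]
        } else {
          drop <- inside[named_all[inside]]
          add <- outside[!named_all[outside]]
        }
        if (length(drop) == 0 || length(add) == 0) break
        ids <- sort(c(setdiff(ids, lex$id[drop[sample.int(length(drop), 1)]]),
                      lex$id[add[sample.int(length(add), 1)]]))
      }
    }
  })
  baseline <- vapply(LANGS, function(l) naming_accuracy(model, ids, l),
                     numeric(1))
  structure(list(treated_language = treated_language, word_ids = ids,
                 baseline = baseline, target_baseline = target_baseline,
                 deviation = abs(baseline[[treated_language]] -
                                   target_baseline)),
            class = "treatment_plan")
}

#' @export
print.treatment_plan <- function(x, ...) {
  cat("Treatment plan:", length(x$word_ids), "words, treated language",
      x$treated_language, "\n")
  cat(sprintf("  baseline naming: L1=%.3f L2=%.3f (target %.3f in %s)\n",
              x$baseline[["L1"]], x$baseline[["L2"]], x$target_baseline,
              x$treated_language))
  invisible(x)
}

#' Run one simulated treatment session
#'
#' Executes, in order: (1) semantic-map retraining on the treatment words;
#' (2) treated-language retrieval retraining (treated phonetic map, semantic
#' map, and the links between them); (3a) for words passing `cond_3a`,
#' retraining of semantic/untreated links from the activation the treated
#' phonetic map evokes in the untreated map; (3b) for words passing
#' `cond_3b`, retraining of the phonetic/phonetic links from the activation
#' the semantic map evokes in the untreated map; then a naming probe of the
#' treatment set in both languages. Condition masks are evaluated at the
#' start of the session. Sessions on destroyed maps still run; affected
#' probes score 0.
#'
#' @param model a `bilex_model`.
#' @param plan a `treatment_plan`.
#' @param params a `treatment_params`.
#' @param seed integer seed (shuffling of word order within steps).
#' @param sigma_treat fixed SOM neighbourhood width during retraining.
#' @return list with the updated `model`, `scores` (named probe proportions)
#'   and the start-of-session condition masks (`named`, `translatable`).
#' @export
run_session <- function(model, plan, params, seed = NULL, sigma_treat = 1) {
  lex <- model$lexicon
  rows <- word_rows(lex, plan$word_ids)
  res <- with_seed(seed, cpp_run_session(
    model$sem$W, model$sem$alive, model$sem$shape[2], lex$sem,
    model$phon_L1$W, model$phon_L1$alive,
    model$phon_L2$W, model$phon_L2$alive, model$phon_L1$shape[2],
    lex$phon_L1, lex$phon_L2, model$phon_L1$labels, model$phon_L2$labels,
    model$links$sem.L1, model$links$L1.sem, model$links$sem.L2,
    model$links$L2.sem, model$links$L1.L2, model$links$L2.L1,
    as.integer(rows - 1L), as.integer(lex$id), match(plan$treated_language, LANGS),
    params$rate_step1, params$rate_step2, params$rate_step3a,
    params$rate_step3b, match(params$cond_3a, COND_LEVELS) - 1L,
    match(params$cond_3b, COND_LEVELS) - 1L, model$act_sigma, sigma_treat))
  model$sem$W <- res$semW
  model$phon_L1$W <- res$p1W
  model$phon_L2$W <- res$p2W
  model$links <- list(sem.L1 = res$L_s1, L1.sem = res$L_1s,
                      sem.L2 = res$L_s2, L2.sem = res$L_2s,
                      L1.L2 = res$L_12, L2.L1 = res$L_21)
  list(model = model,
       scores = c(L1 = res$score_L1, L2 = res$score_L2),
       named = res$named, translatable = res$translatable)
}

#' Run a full treatment course and return the probe series
#'
#' Session 0 records the pre-treatment baseline probe; each subsequent
#' session runs [run_session()] followed (optionally) by one simulated week
#' of exposure training at the patient's poststroke use proportions. With
#' `stopping_rule = TRUE` the course halts early once the treated-language
#' probe exceeds 80% or shows no improvement for three successive sessions,
#' mirroring the clinical protocol.
#'
#' @param model a poststroke `bilex_model`.
#' @param plan a `treatment_plan`.
#' @param params a `treatment_params`.
#' @param profile the patient row (poststroke use proportions, sessions).
#' @param n_sessions number of sessions (defaults to the profile's).
#' @param words_per_year exposure presentations per simulated year.
#' @param hebb_rate link rate for between-session exposure training.
#' @param between_session_exposure train one simulated week of exposure
#'   between sessions (default `TRUE`).
#' @param stopping_rule apply the clinical stopping rule (default `FALSE`:
#'   run exactly `n_sessions`).
#' @param seed integer seed.
#' @return a probe-series data frame (`session`, `score_L1`, `score_L2`)
#'   with the final model attached as attribute `model`.
#' @export
run_treatment <- function(model, plan, params, profile,
                          n_sessions = profile$n_sessions,
                          words_per_year = 1000, hebb_rate = 0.01,
                          between_session_exposure = TRUE,
                          stopping_rule = FALSE, seed = 1) {
  week <- data.frame(phase = "poststroke", duration = 1 / 52,
                     p_L1 = profile$pct_use_L1 / 100,
                     p_L2 = profile$pct_use_L2 / 100)
  baseline <- vapply(LANGS, function(l)
    naming_accuracy(model, plan$word_ids, l), numeric(1))
  scores <- list(c(session = 0, score_L1 = baseline[["L1"]],
                   score_L2 = baseline[["L2"]]))
  treated_scores <- numeric(0)
  for (j in seq_len(n_sessions)) {
    s <- run_session(model, plan, params, seed = derive_seed(seed, 11, j))
    model <- s$model
    scores[[j + 1]] <- c(session = j, score_L1 = s$scores[["L1"]],
                         score_L2 = s$scores[["L2"]])
    treated <- s$scores[[plan$treated_language]]
    treated_scores <- c(treated_scores, treated)
    if (stopping_rule) {
      flat <- length(treated_scores) >= 4 &&
        max(utils::tail(treated_scores, 3)) <=
          treated_scores[length(treated_scores) - 3]
      if (treated > 0.8 || flat) break
    }
    if (between_session_exposure)
      model <- train_exposure(model, week, words_per_year, hebb_rate,
                              seed = derive_seed(seed, 12, j))
  }
  out <- as.data.frame(do.call(rbind, scores))
  out$session <- as.integer(out$session)
  attr(out, "model") <- model
  out
}

#' Simulate a probe series from known treatment parameters
#'
#' Runs the full treatment pipeline with a known parameter set to produce
#' per-session probe trajectories, e.g. as ground-truth targets for
#' parameter-recovery experiments.
#'
#' @param ground_truth_params a `treatment_params`.
#' @param profile the patient row.
#' @param model the patient's poststroke `bilex_model`.
#' @param plan optional `treatment_plan` (selected from the model's
#'   treated-language baseline when omitted).
#' @param words_per_year exposure presentations per simulated year.
#' @param seed integer seed.
#' @return a probe-series data frame as from [run_treatment()].
#' @export
simulate_probe_series <- function(ground_truth_params, profile, model,
                                  plan = NULL, words_per_year = 1000,
                                  seed = 1) {
  if (is.null(plan)) {
    base <- naming_accuracy(model, model$lexicon$id,
                            profile$treated_language)
    plan <- select_treatment_words(model, base, profile$treated_language,
                                   n = min(30, model$lexicon$n_words),
                                   seed = derive_seed(seed, 21))
  }
  run_treatment(model, plan, ground_truth_params, profile,
                words_per_year = words_per_year,
                seed = derive_seed(seed, 22))
}
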