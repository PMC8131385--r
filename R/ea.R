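#' Mean-squared probe-trajectory error of a candidate
#'
#' The fitness function for treatment-parameter candidates: for every
#' patient i in the training subset, the squared deviations between
#' simulated and observed probe proportions in both languages are summed
#' over sessions j = 0..n_i (baseline included), divided by n_i (the number
#' of treatment sessions), and averaged over patients. Perfect prediction
#' gives 0.
#'
#' @param candidate_series named list (by patient) of simulated probe data
#'   frames (`session`, `score_L1`, `score_L2`).
#' @param observed named list of observed probe data frames.
#' @param patients patient ids forming the training subset T (defaults to
#'   all patients in `observed`).
#' @param normalize_by `"n_sessions"` divides each patient's sum of n_i + 1
#'   session terms by n_i (the published form); `"n_points"` divides by
#'   n_i + 1.
#' @return a non-negative scalar.
#' @export
err_fitness <- function(candidate_series, observed, patients = NULL,
                        normalize_by = c("n_sessions", "n_points")) {
  normalize_by <- match.arg(normalize_by)
  patients <- patients %||% names(observed)
  terms <- vapply(patients, function(p) {
    obs <- observed[[p]]
    sim <- candidate_series[[p]]
    if (is.null(obs) || is.null(sim))
      stop_bilex("missing probe series for patient ", p)
    if (nrow(obs) != nrow(sim) ||
        !identical(as.integer(obs$session), as.integer(sim$session)))
      stop_bilex("session mismatch for patient ", p, ": observed has ",
                 nrow(obs), " rows, candidate has ", nrow(sim))
    n_i <- nrow(obs) - 1L
    if (n_i < 1) stop_bilex("patient ", p, " has no treatment sessions")
    ss <- sum((obs$score_L2 - sim$score_L2)^2 +
                (obs$score_L1 - sim$score_L1)^2)
    ss / if (normalize_by == "n_sessions") n_i else (n_i + 1L)
  }, numeric(1))
  mean(terms)
}

#' Evaluate a candidate parameter set against observed trajectories
#'
#' Runs the treatment simulation for every patient in the training subset
#' (averaging `repeats` runs per patient), then scores the averaged series
#' with [err_fitness()]. Results are cached by candidate/subset/seed when a
#' cache environment is supplied.
#'
#' @param params a `treatment_params`.
#' @param models named list of poststroke `bilex_model`s.
#' @param plans named list of `treatment_plan`s.
#' @param observed named list of observed probe series.
#' @param profiles patient table.
#' @param patients training subset T (patient ids).
#' @param repeats simulation repeats per patient.
#' @param seed integer seed.
#' @param words_per_year exposure presentations per simulated year.
#' @param cache optional environment used as a memoization table.
#' @return fitness (non-negative scalar).
#' @export
evaluate_candidate <- function(params, models, plans, observed, profiles,
                               patients = names(observed), repeats = 1,
                               seed = 1, words_per_year = 1000,
                               cache = NULL) {
  key <- NULL
  if (!is.null(cache)) {
    key <- paste(c(sprintf("%.17g", c(params$rate_step1, params$rate_step2,
                                      params$rate_step3a, params$rate_step3b)),
                   params$cond_3a, params$cond_3b, patients, repeats, seed),
                 collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
  }
  sims <- lapply(patients, function(p) {
    profile <- profiles[profiles$patient_id == p, ]
    reps <- lapply(seq_len(repeats), function(r)
      run_treatment(models[[p]], plans[[p]], params, profile,
                    n_sessions = nrow(observed[[p]]) - 1L,
                    words_per_year = words_per_year,
                    seed = derive_seed(seed, match(p, names(observed)), r)))
    avg <- reps[[1]]
    if (repeats > 1) {
      avg$score_L1 <- rowMeans(sapply(reps, `[[`, "score_L1"))
      avg$score_L2 <- rowMeans(sapply(reps, `[[`, "score_L2"))
    }
    avg
  })
  names(sims) <- patients
  fit <- err_fitness(sims, observed, patients)
  if (!is.null(cache)) cache[[key]] <- fit
  fit
}

#' Evolutionary-algorithm configuration
#'
#' @param population_size candidates per generation (>= 2).
#' @param max_generations generations to run.
#' @param stagnation_restart restart from a fresh random population after
#'   this many generations without a new global best (the global best is
#'   preserved).
#' @param mutation_sigma log-scale Gaussian mutation SD for the rates.
#' @param cond_reset_prob probability of resetting a condition gene to a
#'   random level during mutation.
#' @param rate_reset_prob probability of resampling a rate gene from the
#'   log-uniform prior during mutation (lets the search escape collapsed
#'   near-zero rates, which log-scale mutation alone cannot leave).
#' @param tournament_k tournament size for parent selection.
#' @param rate_range range for log-uniform rate initialization.
#' @param repeats simulation repeats per evaluation.
#' @return a list of class `ea_config`.
#' @export
ea_config <- function(population_size = 30, max_generations = 100,
                      stagnation_restart = 20, mutation_sigma = 0.3,
                      cond_reset_prob = 0.1, rate_reset_prob = 0.1,
                      tournament_k = 3,
                      rate_range = c(1e-3, 0.5), repeats = 1) {
  if (population_size < 2) stop_bilex("population must be >= 2")
  if (stagnation_restart > max_generations)
    stop_bilex("stagnation_restart must be <= max_generations")
  structure(list(population_size = population_size,
                 max_generations = max_generations,
                 stagnation_restart = stagnation_restart,
                 mutation_sigma = mutation_sigma,
                 cond_reset_prob = cond_reset_prob,
                 rate_reset_prob = rate_reset_prob,
                 tournament_k = tournament_k, rate_range = rate_range,
                 repeats = repeats), class = "ea_config")
}

random_params <- function(rate_range) {
  lr <- log(rate_range)
  r <- exp(stats::runif(4, lr[1], lr[2]))
  treatment_params(r[1], r[2], r[3], r[4],
                   sample(COND_LEVELS, 1), sample(COND_LEVELS, 1))
}

mutate_params <- function(p, sigma, cond_reset_prob, rate_reset_prob,
                          rate_range) {
  rates <- c(p$rate_step1, p$rate_step2, p$rate_step3a, p$rate_step3b)
  rates <- exp(log(pmax(rates, rate_range[1] / 10)) + stats::rnorm(4, 0, sigma))
  rates <- pmin(pmax(rates, rate_range[1] / 10), rate_range[2] * 2)
  lr <- log(rate_range)
  for (k in 1:4) if (stats::runif(1) < rate_reset_prob)
    rates[k] <- exp(stats::runif(1, lr[1], lr[2]))
  conds <- c(p$cond_3a, p$cond_3b)
  for (k in 1:2) if (stats::runif(1) < cond_reset_prob)
    conds[k] <- sample(COND_LEVELS, 1)
  treatment_params(rates[1], rates[2], rates[3], rates[4], conds[1], conds[2])
}

crossover_params <- function(a, b) {
  pick <- function(x, y) if (stats::runif(1) < 0.5) x else y
  treatment_params(pick(a$rate_step1, b$rate_step1),
                   pick(a$rate_step2, b$rate_step2),
                   pick(a$rate_step3a, b$rate_step3a),
                   pick(a$rate_step3b, b$rate_step3b),
                   pick(a$cond_3a, b$cond_3a), pick(a$cond_3b, b$cond_3b))
}

#' Evolve treatment parameters against a fitness closure
#'
#' Tournament selection, uniform crossover of the six genes, log-normal
#' mutation of the rates with occasional random resets of the condition
#' genes, elitism of size one, and a restart from a fresh random population
#' (preserving the global best) after a stagnation window without
#' improvement.
#'
#' @param config an [ea_config()].
#' @param eval_fn function taking a `treatment_params` and returning its
#'   fitness (lower is better).
#' @param seed integer seed.
#' @return list with `best` (list: `params`, `fitness`, `generation`) and
#'   `trace` (data frame: generation, generation best, best-so-far, restart
#'   flag).
#' @export
evolve <- function(config, eval_fn, seed = 1) {
  with_seed(seed, {
    new_pop <- function() lapply(seq_len(config$population_size),
                                 function(i) random_params(config$rate_range))
    pop <- new_pop()
    fit <- vapply(pop, eval_fn, numeric(1))
    best <- list(params = pop[[which.min(fit)]], fitness = min(fit),
                 generation = 0L)
    stag <- 0L
    trace <- vector("list", config$max_generations)
    for (g in seq_len(config$max_generations)) {
      restarted <- FALSE
      if (stag >= config$stagnation_restart) {
        pop <- new_pop()
        fit <- vapply(pop, eval_fn, numeric(1))
        stag <- 0L
        restarted <- TRUE
      } else {
        tournament <- function() {
          k <- sample.int(config$population_size,
                          min(config$tournament_k, config$population_size))
          pop[[k[which.min(fit[k])]]]
        }
        elite <- pop[[which.min(fit)]]
        children <- lapply(seq_len(config$population_size - 1L), function(i)
          mutate_params(crossover_params(tournament(), tournament()),
                        config$mutation_sigma, config$cond_reset_prob,
                        config$rate_reset_prob, config$rate_range))
        pop <- c(list(elite), children)
        fit <- vapply(pop, eval_fn, numeric(1))
      }
      gen_best <- min(fit)
      if (gen_best < best$fitness) {
        best <- list(params = pop[[which.min(fit)]], fitness = gen_best,
                     generation = g)
        stag <- 0L
      } else {
        stag <- stag + 1L
      }
      trace[[g]] <- data.frame(generation = g, best_generation = gen_best,
                               best_so_far = best$fitness,
                               restarted = restarted)
    }
    list(best = best, trace = do.call(rbind, trace))
  })
}

#' Fit the six treatment parameters to observed probe trajectories
#'
#' The model-fitting front end: evolves a population of candidate parameter
#' sets against the observed per-session naming probes of the training
#' patients, evaluating each candidate by simulating the full treatment
#' course on every patient's poststroke model.
#'
#' @inheritParams evaluate_candidate
#' @param config an [ea_config()].
#' @param words_per_year exposure presentations per simulated year.
#' @return an object of class `bilex_ea_fit` with `params` (best candidate),
#'   `fitness`, `trace`, and the data references used.
#' @export
fit_treatment_params <- function(observed, models, plans, profiles,
                                 patients = names(observed),
                                 config = ea_config(), words_per_year = 1000,
                                 seed = 1) {
  cache <- new.env(parent = emptyenv())
  eval_fn <- function(params)
    evaluate_candidate(params, models, plans, observed, profiles, patients,
                       repeats = config$repeats,
                       seed = derive_seed(seed, 31),
                       words_per_year = words_per_year, cache = cache)
  res <- evolve(config, eval_fn, seed = derive_seed(seed, 32))
  structure(list(params = res$best$params, fitness = res$best$fitness,
                 generation = res$best$generation, trace = res$trace,
                 patients = patients, config = config,
                 words_per_year = words_per_year, seed = seed),
            class = "bilex_ea_fit")
}

#' @export
print.bilex_ea_fit <- function(x, ...) {
  cat("Evolutionary fit of treatment parameters\n")
  cat("  training patients:", paste(x$patients, collapse = ", "), "\n")
  cat("  best fitness (mean-squared probe error):",
      format(x$fitness, digits = 5), "found in generation", x$generation,
      "\n")
  print(x$params)
  invisible(x)
}

#' @export
summary.bilex_ea_fit <- function(object, ...) {
  print(object)
  tr <- object$trace
  cat("  generations:", nrow(tr), "; restarts:", sum(tr$restarted), "\n")
  invisible(object)
}

#' @export
coef.bilex_ea_fit <- function(object, ...) {
  p <- object$params
  c(rate_step1 = p$rate_step1, rate_step2 = p$rate_step2,
    rate_step3a = p$rate_step3a, rate_step3b = p$rate_step3b,
    cond_3a = match(p$cond_3a, COND_LEVELS),
    cond_3b = match(p$cond_3b, COND_LEVELS))
}

#' @export
plot.bilex_ea_fit <- function(x, ...) {
  plot(x$trace$generation, x$trace$best_so_far, type = "s",
       xlab = "generation", ylab = "best-so-far fitness", ...)
  graphics::points(x$trace$generation[x$trace$restarted],
                   x$trace$best_so_far[x$trace$restarted], pch = 4)
  invisible(x)
}

#' Predict a patient's treatment response from a fitted parameter set
#'
#' Applies the fitted parameters to a (typically held-out) patient's
#' poststroke model, running the treatment simulation `repeats` times and
#' reporting per-session medians with min/max ranges.
#'
#' @param object a `bilex_ea_fit`.
#' @param model the patient's poststroke `bilex_model`.
#' @param plan the patient's `treatment_plan`.
#' @param profile the patient row.
#' @param n_sessions sessions to simulate (defaults to the profile's).
#' @param repeats simulation repeats (10 by default).
#' @param seed integer seed.
#' @param ... unused.
#' @return a data frame with per-session median and min/max of both
#'   languages' probe scores.
#' @export
predict.bilex_ea_fit <- function(object, model, plan, profile,
                                 n_sessions = profile$n_sessions,
                                 repeats = 10, seed = 1, ...) {
  runs <- lapply(seq_len(repeats), function(r)
    run_treatment(model, plan, object$params, profile,
                  n_sessions = n_sessions,
                  words_per_year = object$words_per_year,
                  seed = derive_seed(seed, 41, r)))
  s1 <- sapply(runs, `[[`, "score_L1")
  s2 <- sapply(runs, `[[`, "score_L2")
  if (is.null(dim(s1))) { s1 <- matrix(s1, nrow = 1); s2 <- matrix(s2, nrow = 1) }
  data.frame(session = runs[[1]]$session,
             score_L1 = apply(s1, 1, stats::median),
             score_L1_min = apply(s1, 1, min),
             score_L1_max = apply(s1, 1, max),
             score_L2 = apply(s2, 1, stats::median),
             score_L2_min = apply(s2, 1, min),
             score_L2_max = apply(s2, 1, max))
}

#' Leave-one-out cross-validation of the treatment model
#'
#' For each patient, evolves treatment parameters on all other patients'
#' observed probe series and predicts the held-out patient's treatment
#' response from their poststroke model; the held-out patient's observed
#' series is never seen by the optimizer.
#'
#' @inheritParams fit_treatment_params
#' @param repeats_predict simulation repeats per held-out prediction.
#' @return list of class `bilex_loo`: per-patient `fits`, `predictions`
#'   (median + range series), and a summary table of held-out prediction
#'   errors where observed series are available.
#' @export
leave_one_out <- function(observed, models, plans, profiles,
                          config = ea_config(), words_per_year = 1000,
                          repeats_predict = 10, seed = 1) {
  patients <- names(observed)
  if (length(patients) < 2)
    stop_bilex("leave-one-out undefined with fewer than 2 patients")
  fits <- list()
  predictions <- list()
  for (p in patients) {
    train <- setdiff(patients, p)
    fit <- fit_treatment_params(observed[train], models, plans, profiles,
                                patients = train, config = config,
                                words_per_year = words_per_year,
                                seed = derive_seed(seed, 51,
                                                   match(p, patients)))
    profile <- profiles[profiles$patient_id == p, ]
    pred <- predict(fit, models[[p]], plans[[p]], profile,
                    repeats = repeats_predict,
                    seed = derive_seed(seed, 52, match(p, patients)))
    fits[[p]] <- fit
    predictions[[p]] <- pred
  }
  held_err <- vapply(patients, function(p) {
    obs <- observed[[p]]
    if (!is.data.frame(obs) || nrow(obs) != nrow(predictions[[p]]))
      return(NA_real_)
    err_fitness(list(p = predictions[[p]][, c("session", "score_L1",
                                              "score_L2")]),
                list(p = obs), "p")
  }, numeric(1))
  structure(list(fits = fits, predictions = predictions,
                 summary = data.frame(patient_id = patients,
                                      heldout_err = held_err)),
            class = "bilex_loo")
}

#' @export
print.bilex_loo <- function(x, ...) {
  cat("Leave-one-out cross-validation over", length(x$fits), "patients\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
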