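#' Scale configuration for simulations
#'
#' Bundles the lexicon, map, training and lesion-search settings used by the
#' pipeline. `"reduced"` is the desk-scale configuration used throughout the
#' package's own analyses (chosen so that phonetic maps hold at least as
#' many units as there are words, which the naming rule requires to reach
#' high scores); `"full"` mirrors the published corpus and a larger map
#' complement.
#'
#' @param scale `"reduced"` or `"full"`.
#' @return a named list of settings.
#' @export
bilex_config <- function(scale = c("reduced", "full")) {
  scale <- match.arg(scale)
  if (scale == "reduced") {
    list(scale = scale, n_words = 120, n_categories = 12, d_sem = 100,
         d_phon = 40, sem_shape = c(18, 18), phon_shape = c(14, 14),
         words_per_year = 1000, hebb_rate = 0.01, act_sigma = 0.5,
         extents = seq(0, 1, length.out = 41), lesion_repeats = 3,
         n_probe = 60, n_treatment = 30, n_papt = 52)
  } else {
    list(scale = scale, n_words = 638, n_categories = 30, d_sem = 200,
         d_phon = 60, sem_shape = c(30, 30), phon_shape = c(26, 26),
         words_per_year = 5000, hebb_rate = 0.01, act_sigma = 0.5,
         extents = seq(0, 1, length.out = 41), lesion_repeats = 3,
         n_probe = 60, n_treatment = 30, n_papt = 52)
  }
}

#' Regression quality of simulated against actual scores
#'
#' Ordinary least squares of simulated on actual scores with the standard
#' coefficient of determination. A constant simulated vector yields
#' `r_squared = 0`; fewer than 3 pairs or zero variance in the actual scores
#' is an error.
#'
#' @param actual numeric vector of observed scores.
#' @param simulated numeric vector of model scores (same length).
#' @return list with `r_squared`, `slope`, `intercept`, `n`.
#' @export
fit_quality <- function(actual, simulated) {
  n <- length(actual)
  if (n != length(simulated)) stop_bilex("length mismatch")
  if (n < 3) stop_bilex("undefined fit: need at least 3 score pairs")
  if (stats::var(actual) == 0)
    stop_bilex("undefined fit: actual scores have zero variance")
  if (stats::var(simulated) == 0)
    return(list(r_squared = 0, slope = 0, intercept = mean(simulated), n = n))
  m <- stats::lm(simulated ~ actual)
  # summary.lm warns on numerically perfect fits; R^2 = 1 is a valid outcome
  list(r_squared = suppressWarnings(summary(m)$r.squared),
       slope = unname(stats::coef(m)[2]),
       intercept = unname(stats::coef(m)[1]), n = n)
}

#' Per-session regressions of observed on predicted treatment response
#'
#' For each requested session count, regresses the patients' observed
#' change-from-baseline on the predicted change, separately for the treated
#' and untreated language. Patients flagged `exclude_untreated` in the
#' profile table (e.g. rising untreated-language baselines) are dropped from
#' the untreated-language rows.
#'
#' @param observed named list (by patient) of observed probe series.
#' @param predicted named list of predicted probe series.
#' @param sessions integer vector of session counts to evaluate.
#' @param profiles patient table (for `treated_language` and the optional
#'   `exclude_untreated` flag).
#' @return a data frame with columns `session`, `language`
#'   (`treated`/`untreated`), `r_squared`, `n`.
#' @export
session_regressions <- function(observed, predicted, sessions, profiles) {
  rows <- list()
  for (s in sessions) {
    for (role in c("treated", "untreated")) {
      obs_change <- numeric()
      pred_change <- numeric()
      for (p in names(observed)) {
        prof <- profiles[profiles$patient_id == p, ]
        if (role == "untreated" && isTRUE(prof$exclude_untreated)) next
        lang <- if (role == "treated") prof$treated_language else
          setdiff(LANGS, prof$treated_language)
        col <- paste0("score_", lang)
        ob <- observed[[p]]
        pr <- predicted[[p]]
        if (max(ob$session) < s || max(pr$session) < s) next
        obs_change <- c(obs_change, ob[[col]][ob$session == s] -
                          ob[[col]][ob$session == 0])
        pred_change <- c(pred_change, pr[[col]][pr$session == s] -
                           pr[[col]][pr$session == 0])
      }
      r2 <- if (length(obs_change) >= 3 && stats::var(obs_change) > 0)
        fit_quality(obs_change, pred_change)$r_squared else NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(session = s, language = role, r_squared = r2,
                   n = length(obs_change))
    }
  }
  do.call(rbind, rows)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Build the 13 lesion-fitted patient models and score the fit
#'
#' Pipeline stage wrapper: generates the shared lexicon, item and probe
#' fixtures, builds one lesion-fitted poststroke model per patient, and
#' regresses actual against simulated scores (semantic-association test and
#' naming in each language).
#'
#' @param profiles patient table (defaults to the bundled 13 patients).
#' @param config scale configuration.
#' @param seed integer seed.
#' @param progress print one line per patient.
#' @return list with `fits` (named list of `impairment_fit`), `scores`
#'   (long data frame of target/achieved scores), and `quality` (R-squared
#'   etc. per measure).
#' @export
build_patient_cohort <- function(profiles = bilex_patients(),
                                 config = bilex_config(), seed = 1,
                                 progress = FALSE) {
  lexicon <- generate_lexicon(config$n_words, config$n_categories,
                              config$d_sem, config$d_phon,
                              seed = derive_seed(seed, 61))
  items <- generate_papt_items(lexicon, config$n_papt,
                               seed = derive_seed(seed, 62))
  probe_words <- with_seed(derive_seed(seed, 63),
                           sort(sample(lexicon$id, config$n_probe)))
  fits <- list()
  for (i in seq_len(nrow(profiles))) {
    p <- profiles$patient_id[i]
    fits[[p]] <- fit_poststroke(profiles[i, ], lexicon, items, probe_words,
                                config, seed = derive_seed(seed, 64, i))
    if (progress)
      message(sprintf("%s: extents sem=%.3f L1=%.3f L2=%.3f, achieved %s",
                      p, fits[[p]]$extents["sem"], fits[[p]]$extents["L1"],
                      fits[[p]]$extents["L2"],
                      paste(fits[[p]]$achieved, collapse = "/")))
  }
  scores <- do.call(rbind, lapply(names(fits), function(p)
    data.frame(patient_id = p,
               measure = c("papt", "bnt_L1", "bnt_L2"),
               target = unname(fits[[p]]$targets),
               achieved = unname(fits[[p]]$achieved))))
  quality <- lapply(split(scores, scores$measure), function(d)
    fit_quality(d$target, d$achieved))
  list(fits = fits, scores = scores, quality = quality,
       lexicon = lexicon, papt_items = items, probe_words = probe_words)
}

#' Run the end-to-end pipeline and write its reports
#'
#' Orchestrates lexicon generation, per-patient lesion fitting, an optional
#' synthetic-ground-truth evolutionary optimization with leave-one-out
#' cross-validation, and writes CSV/JSON reports to `out_dir`. Every
#' artifact embeds the configuration hash and master seed. Stages whose
#' outputs already exist with a matching hash are skipped when
#' `resume = TRUE`.
#'
#' @param config scale configuration from [bilex_config()].
#' @param out_dir output directory (created if missing).
#' @param profiles patient table.
#' @param seed master seed.
#' @param run_ea also run the synthetic-truth EA + LOO stage (slow).
#' @param ea_cfg EA configuration for that stage.
#' @param resume skip stages with up-to-date outputs.
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(config = bilex_config(), out_dir, profiles = bilex_patients(),
                         seed = 1, run_ea = FALSE,
                         ea_cfg = ea_config(population_size = 10,
                                            max_generations = 10,
                                            stagnation_restart = 10),
                         resume = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(list(config = config, seed = seed))
  stamp <- list(config_hash = hash, seed = seed)
  fits_file <- file.path(out_dir, "lesion_fits.csv")
  quality_file <- file.path(out_dir, "fit_quality.json")
  fresh <- function(path) {
    if (!resume || !file.exists(path)) return(FALSE)
    ok <- tryCatch(identical(jsonlite::read_json(quality_file)$config_hash,
                             hash), error = function(e) FALSE)
    ok
  }
  if (!fresh(quality_file)) {
    cohort <- build_patient_cohort(profiles, config, seed)
    utils::write.csv(cbind(cohort$scores, config_hash = hash, seed = seed),
                     fits_file, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(c(stamp, list(quality = cohort$quality)),
                         quality_file, auto_unbox = TRUE, digits = NA)
    if (run_ea) {
      truth <- treatment_params(0.1, 0.1, 0.05, 0.05, "all", "all")
      models <- lapply(cohort$fits, `[[`, "model")
      plans <- list()
      observed <- list()
      for (p in names(models)) {
        profile <- profiles[profiles$patient_id == p, ]
        base <- naming_accuracy(models[[p]], models[[p]]$lexicon$id,
                                profile$treated_language)
        plans[[p]] <- select_treatment_words(models[[p]], base,
                                             profile$treated_language,
                                             n = config$n_treatment,
                                             seed = derive_seed(seed, 71, match(p, names(models))))
        observed[[p]] <- simulate_probe_series(truth, profile, models[[p]],
                                               plans[[p]],
                                               config$words_per_year,
                                               seed = derive_seed(seed, 72, match(p, names(models))))
      }
      loo <- leave_one_out(observed, models, plans, profiles, ea_cfg,
                           config$words_per_year, repeats_predict = 3,
                           seed = derive_seed(seed, 73))
      preds <- do.call(rbind, lapply(names(loo$predictions), function(p)
        cbind(patient_id = p, loo$predictions[[p]],
              config_hash = hash, seed = seed)))
      utils::write.csv(preds, file.path(out_dir, "loo_predictions.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(cbind(loo$summary, config_hash = hash, seed = seed),
                       file.path(out_dir, "loo_summary.csv"),
                       row.names = FALSE, quote = FALSE)
    }
  }
  invisible(out_dir)
}
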