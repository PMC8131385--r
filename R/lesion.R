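MAPS <- c("sem", "L1", "L2")

map_field <- function(map) if (map == "sem") "sem" else paste0("phon_", map)

# unit indices deleted by a circular lesion: all units within the radius
# around the centre whose enclosed alive fraction best matches the extent
circular_kill <- function(som, extent, center = NULL) {
  nr <- som$shape[1]; nc <- som$shape[2]
  if (is.null(center)) center <- c((nr - 1) / 2, (nc - 1) / 2)
  rows <- (seq_len(nr * nc) - 1L) %/% nc
  cols <- (seq_len(nr * nc) - 1L) %% nc
  d <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  alive <- which(som$alive)
  radii <- c(-1, sort(unique(d[alive])))
  frac <- vapply(radii, function(r) mean(d[alive] <= r), numeric(1))
  r_best <- radii[which.min(abs(frac - extent))]
  alive[d[alive] <= r_best]
}

#' Apply a simulated stroke lesion to one map
#'
#' Deletes units (and all their associative connections) from the chosen
#' map. `method = "circular"` removes the disc around `center` whose
#' enclosed fraction of currently-alive units best matches `extent`;
#' `method = "diffuse"` removes a uniform random subset of alive units of
#' size `round(extent * alive)`. Link rows and columns touching deleted
#' units are zeroed and surviving rows renormalized. The input model is not
#' modified.
#'
#' @param model a `bilex_model`.
#' @param map `"sem"`, `"L1"` or `"L2"`.
#' @param extent target fraction of units deleted, in `[0, 1]`.
#' @param method `"circular"` (default) or `"diffuse"`.
#' @param center circular lesion centre as `c(row, col)` (0-based grid
#'   coordinates); defaults to the map centre.
#' @param seed seed for diffuse unit sampling.
#' @return the lesioned `bilex_model` (a new object).
#' @export
apply_lesion <- function(model, map, extent, method = c("circular", "diffuse"),
                         center = NULL, seed = NULL) {
  method <- match.arg(method)
  if (!map %in% MAPS) stop_bilex("map must be one of ", paste(MAPS, collapse = ", "))
  if (extent < 0 || extent > 1) stop_bilex("extent must be within [0, 1]")
  fld <- map_field(map)
  som <- model[[fld]]
  kill <- if (extent == 0) {
    integer()
  } else if (extent == 1) {
    which(som$alive)
  } else if (method == "circular") {
    circular_kill(som, extent, center)
  } else {
    alive <- which(som$alive)
    k <- round(extent * length(alive))
    if (k > 0) with_seed(seed, alive[sample.int(length(alive), k)]) else integer()
  }
  if (length(kill) == 0) return(model)
  som$alive[kill] <- FALSE
  som$labels[kill] <- NA_integer_
  model[[fld]] <- som
  # zero associative connections of the deleted units and renormalize
  for (ln in names(model$links)) {
    ends <- strsplit(ln, ".", fixed = TRUE)[[1]]
    W <- model$links[[ln]]
    if (ends[1] == map) W[kill, ] <- 0
    if (ends[2] == map) {
      W[, kill] <- 0
      tgt_alive <- model[[map_field(ends[2])]]$alive
      s <- rowSums(W[, tgt_alive, drop = FALSE])
      nz <- s > 0
      W[nz, ] <- W[nz, , drop = FALSE] / s[nz]
    }
    model$links[[ln]] <- W
  }
  model
}

papt_curve_at <- function(model, items, extent, method, repeats, seed) {
  reps <- if (method == "circular") 1L else repeats
  counts <- vapply(seq_len(reps), function(r) {
    les <- apply_lesion(model, "sem", extent, method,
                        seed = derive_seed(seed, 101, r))
    simulate_papt(les, items, seed = derive_seed(seed, 102, r))$count
  }, numeric(1))
  mean(counts)
}

#' Fit semantic lesion extent to a semantic-association target score
#'
#' Evaluates the simulated semantic-association score over a grid of lesion
#' extents (averaging repeats for stochastic placements) and returns the
#' extent whose score is closest to the target; ties go to the smaller
#' extent.
#'
#' @param model an intact (prestroke) `bilex_model`.
#' @param papt_target target raw score (0-52 scale for 52 items).
#' @param papt_items item data frame.
#' @param extents grid of candidate extents.
#' @param method lesion method.
#' @param repeats repeats per extent for stochastic placements.
#' @param seed integer seed.
#' @return list with `extent`, and `curve` (data frame extent/score).
#' @export
fit_semantic_damage <- function(model, papt_target, papt_items,
                                extents = seq(0, 1, length.out = 41),
                                method = "circular", repeats = 3, seed = 1) {
  scores <- vapply(extents, function(e)
    papt_curve_at(model, papt_items, e, method, repeats, seed), numeric(1))
  best <- extents[which.min(abs(scores - papt_target))]
  list(extent = best, curve = data.frame(extent = extents, score = scores),
       target = papt_target)
}

naming_curve_at <- function(model, probe_ids, language, extent, method,
                            repeats, seed) {
  reps <- if (method == "circular") 1L else repeats
  mean(vapply(seq_len(reps), function(r) {
    les <- apply_lesion(model, language, extent, method,
                        seed = derive_seed(seed, 201, r))
    BNT_MAX * naming_accuracy(les, probe_ids, language)
  }, numeric(1)))
}

#' Fit phonetic lesion extents to naming targets in both languages
#'
#' With the semantic lesion already applied, each language's phonetic map is
#' lesioned independently over a grid of extents and the extent whose
#' simulated naming score is closest to that language's target is chosen.
#' If the semantic lesion alone already pushes naming below the target, no
#' phonetic damage can reach it: the extent stays 0 and the language is
#' flagged unreachable.
#'
#' @param model a `bilex_model` with the semantic lesion applied.
#' @param bnt_targets named numeric `c(L1 = ..., L2 = ...)` on the 0-60 scale.
#' @param probe_words probe word ids (the fixed 60-word probe set).
#' @param extents grid of candidate extents.
#' @param method lesion method.
#' @param repeats repeats per extent for stochastic placements.
#' @param seed integer seed.
#' @return list with `extents` (named), `curves`, `unreachable` (named
#'   logical).
#' @export
fit_phonetic_damage <- function(model, bnt_targets, probe_words,
                                extents = seq(0, 1, length.out = 41),
                                method = "circular", repeats = 3, seed = 1) {
  out_ext <- c(L1 = 0, L2 = 0)
  unreachable <- c(L1 = FALSE, L2 = FALSE)
  curves <- list()
  for (l in LANGS) {
    scores <- vapply(extents, function(e)
      naming_curve_at(model, probe_words, l, e, method, repeats,
                      derive_seed(seed, match(l, LANGS))), numeric(1))
    curves[[l]] <- data.frame(extent = extents, score = scores)
    if (scores[1] < bnt_targets[[l]] - 0.5) {
      unreachable[l] <- TRUE
      out_ext[l] <- 0
    } else {
      out_ext[l] <- extents[which.min(abs(scores - bnt_targets[[l]]))]
    }
  }
  list(extents = out_ext, curves = curves, unreachable = unreachable,
       targets = bnt_targets)
}

#' Build a lesion-fitted poststroke patient model
#'
#' Trains a fresh model under the patient's prestroke exposure schedule up
#' to the age of stroke onset, fits semantic damage to the patient's
#' semantic-association score, then phonetic damage per language to the
#' naming scores, continues exposure training at the poststroke use
#' proportions until the model reaches the age at testing, and evaluates the
#' achieved scores at that age.
#'
#' @param profile one patient row.
#' @param lexicon a `bilex_lexicon`.
#' @param papt_items semantic-association items (the 52-item fixture set).
#' @param probe_words the fixed 60-word naming probe set (word ids).
#' @param config scale configuration from [bilex_config()].
#' @param method lesion method (`"circular"` default).
#' @param seed integer seed.
#' @return an object of class `impairment_fit` with the lesioned model, the
#'   fitted extents, target/achieved scores at onset and at testing age,
#'   residuals, and the fitting curves.
#' @export
fit_poststroke <- function(profile, lexicon, papt_items, probe_words,
                           config = bilex_config(), method = "circular",
                           seed = 1) {
  sched <- schedule_from_profile(profile)
  model <- bilex_model(lexicon, config$sem_shape, config$phon_shape,
                       config$act_sigma, seed = derive_seed(seed, 1))
  model <- train_exposure(model, sched[sched$phase == "prestroke", ],
                          config$words_per_year, config$hebb_rate,
                          seed = derive_seed(seed, 2))
  sem_fit <- fit_semantic_damage(model, profile$papt, papt_items,
                                 config$extents, method, config$lesion_repeats,
                                 seed = derive_seed(seed, 3))
  model_sem <- apply_lesion(model, "sem", sem_fit$extent, method,
                            seed = derive_seed(seed, 4))
  targets_bnt <- c(L1 = profile$bnt_L1, L2 = profile$bnt_L2)
  phon_fit <- fit_phonetic_damage(model_sem, targets_bnt, probe_words,
                                  config$extents, method,
                                  config$lesion_repeats,
                                  seed = derive_seed(seed, 5))
  model_les <- apply_lesion(model_sem, "L1", phon_fit$extents["L1"], method,
                            seed = derive_seed(seed, 6))
  model_les <- apply_lesion(model_les, "L2", phon_fit$extents["L2"], method,
                            seed = derive_seed(seed, 7))
  achieved_onset <- achieved_scores(model_les, papt_items, probe_words,
                                    seed = derive_seed(seed, 8))
  # post-lesion aging: continued exposure at poststroke use proportions
  post <- sched[sched$phase == "poststroke", ]
  if (nrow(post) > 0 && sum(post$duration) > 0)
    model_les <- train_exposure(model_les, post, config$words_per_year,
                                config$hebb_rate,
                                seed = derive_seed(seed, 9))
  achieved <- achieved_scores(model_les, papt_items, probe_words,
                              seed = derive_seed(seed, 10))
  targets <- c(papt = profile$papt, bnt_L1 = profile$bnt_L1,
               bnt_L2 = profile$bnt_L2)
  structure(list(model = model_les, profile = profile,
                 extents = c(sem = sem_fit$extent, phon_fit$extents),
                 method = method, targets = targets,
                 achieved_onset = achieved_onset, achieved = achieved,
                 residuals = achieved - targets,
                 curves = c(list(sem = sem_fit$curve), phon_fit$curves),
                 unreachable = phon_fit$unreachable, seed = seed),
            class = "impairment_fit")
}

#' @rdname fit_poststroke
#' @export
build_poststroke_model <- fit_poststroke

achieved_scores <- function(model, papt_items, probe_words, seed = NULL) {
  c(papt = simulate_papt(model, papt_items, seed = seed)$count,
    bnt_L1 = bnt_score(model, probe_words, "L1"),
    bnt_L2 = bnt_score(model, probe_words, "L2"))
}

#' @export
print.impairment_fit <- function(x, ...) {
  cat("Lesion-fitted poststroke model for", x$profile$patient_id, "\n")
  cat("  lesion extents (", x$method, "): sem=", round(x$extents["sem"], 3),
      " L1=", round(x$extents["L1"], 3), " L2=", round(x$extents["L2"], 3),
      "\n", sep = "")
  m <- rbind(target = x$targets, achieved = x$achieved,
             residual = x$residuals)
  print(m)
  if (any(x$unreachable))
    cat("  note: naming target unreachable (semantic lesion overshoots) in:",
        paste(names(which(x$unreachable)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.impairment_fit <- function(object, ...) {
  print(object)
  cat("  achieved at onset:", paste(names(object$achieved_onset),
                                    object$achieved_onset, collapse = ", "),
      "\n")
  invisible(object)
}

#' @export
coef.impairment_fit <- function(object, ...) object$extents

#' @export
residuals.impairment_fit <- function(object, ...) object$residuals

#' @export
plot.impairment_fit <- function(x, ...) {
  oldpar <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(oldpar))
  panels <- list(sem = c("semantic damage", "PAPT-style score", "papt"),
                 L1 = c("L1 phonetic damage", "naming score", "bnt_L1"),
                 L2 = c("L2 phonetic damage", "naming score", "bnt_L2"))
  for (m in names(panels)) {
    cv <- x$curves[[m]]
    plot(cv$extent, cv$score, type = "l", xlab = panels[[m]][1],
         ylab = panels[[m]][2], ...)
    graphics::abline(h = x$targets[panels[[m]][3]], lty = 2)
    graphics::abline(v = x$extents[m], lty = 3)
  }
  invisible(x)
}
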