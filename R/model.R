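LANGS <- c("L1", "L2")
LINK_NAMES <- c("sem.L1", "L1.sem", "sem.L2", "L2.sem", "L1.L2", "L2.L1")

check_language <- function(language) {
  if (!language %in% LANGS) stop_bilex("language must be 'L1' or 'L2'")
  language
}

#' Construct an untrained three-map bilingual lexicon model
#'
#' The model holds a shared semantic map, one phonetic map per language, and
#' six directed associative link matrices (semantic to/from each phonetic
#' map, and the two phonetic maps to/from each other). Links start uniform
#' over alive target units; maps start with random weights and are labelled
#' by nearest word vector.
#'
#' @param lexicon a `bilex_lexicon`.
#' @param sem_shape semantic map grid shape `c(rows, cols)`.
#' @param phon_shape phonetic map grid shape (both languages).
#' @param act_sigma width (grid cells) of the Gaussian activation bump used
#'   for cross-map transfer.
#' @param seed integer seed for weight initialization.
#' @return an object of class `bilex_model`.
#' @export
bilex_model <- function(lexicon, sem_shape = c(18, 18), phon_shape = c(14, 14),
                        act_sigma = 0.5, seed = 1) {
  with_seed(seed, {
    sem <- som_new(sem_shape, lexicon$d_sem)
    phon_L1 <- som_new(phon_shape, lexicon$d_phon)
    phon_L2 <- som_new(phon_shape, lexicon$d_phon)
  })
  sem <- som_relabel(sem, lexicon$sem, lexicon$id)
  phon_L1 <- som_relabel(phon_L1, lexicon$phon_L1, lexicon$id)
  phon_L2 <- som_relabel(phon_L2, lexicon$phon_L2, lexicon$id)
  ns <- prod(sem_shape)
  np <- prod(phon_shape)
  uni <- function(nsrc, ntgt) matrix(1 / ntgt, nsrc, ntgt)
  links <- list(sem.L1 = uni(ns, np), L1.sem = uni(np, ns),
                sem.L2 = uni(ns, np), L2.sem = uni(np, ns),
                L1.L2 = uni(np, np), L2.L1 = uni(np, np))
  structure(list(sem = sem, phon_L1 = phon_L1, phon_L2 = phon_L2,
                 links = links, lexicon = lexicon, age = 0,
                 act_sigma = act_sigma),
            class = "bilex_model")
}

#' @export
print.bilex_model <- function(x, ...) {
  cat("Three-map bilingual lexicon model (age", format(x$age, digits = 4),
      "simulated years)\n")
  cat("  semantic map: ", x$sem$shape[1], "x", x$sem$shape[2], " (",
      sum(x$sem$alive), " alive)\n", sep = "")
  for (l in LANGS)
    cat("  phonetic ", l, ":  ", x[[paste0("phon_", l)]]$shape[1], "x",
        x[[paste0("phon_", l)]]$shape[2], " (",
        sum(x[[paste0("phon_", l)]]$alive), " alive)\n", sep = "")
  cat("  lexicon:", x$lexicon$n_words, "words\n")
  invisible(x)
}

phon_map <- function(model, language) model[[paste0("phon_", language)]]

#' Build an exposure schedule from a patient profile
#'
#' Prestroke: L1-only from birth to the L2 age of acquisition, then a
#' constant language mixture chosen in closed form so that the time-weighted
#' lifetime average equals the profile's lifetime-exposure percentages at the
#' age of testing. Poststroke: a separate epoch at the profile's poststroke
#' use percentages, lasting the years between stroke onset and testing.
#' If the lifetime L2 percentage cannot be reached in the time available
#' after acquisition, the post-acquisition L2 proportion is clamped to 1 with
#' a warning.
#'
#' @param profile one patient row (data frame row or list) from a patient
#'   table.
#' @return a data frame of epochs with columns `phase`
#'   (`"prestroke"`/`"poststroke"`), `duration` (simulated years), `p_L1`,
#'   `p_L2`; the stroke-onset age is attached as attribute `onset_age`.
#' @export
schedule_from_profile <- function(profile) {
  age <- profile$age_at_testing
  aoa <- profile$l2_aoa
  onset <- age - profile$years_post_onset
  share_L2 <- profile$pct_lifetime_L2 / 100
  if (aoa > 0) {
    p2 <- share_L2 * age / (age - aoa)
    if (p2 > 1) {
      warning("lifetime L2 exposure unreachable after acquisition age; ",
              "clamping post-acquisition L2 proportion to 1")
      p2 <- 1
    }
  } else {
    p2 <- share_L2
  }
  pre <- data.frame(phase = character(), duration = numeric(),
                    p_L1 = numeric(), p_L2 = numeric())
  add <- function(df, phase, duration, p2) {
    if (duration <= 0) return(df)
    rbind(df, data.frame(phase = phase, duration = duration,
                         p_L1 = 1 - p2, p_L2 = p2))
  }
  pre <- add(pre, "prestroke", min(aoa, onset), 0)
  pre <- add(pre, "prestroke", onset - min(aoa, onset), p2)
  out <- add(pre, "poststroke", profile$years_post_onset,
             profile$pct_use_L2 / 100)
  attr(out, "onset_age") <- onset
  out
}

# prestroke SOM learning-rate and neighbourhood decay, as a function of
# simulated age in years; both decay exponentially to a floor so that late
# (including poststroke) exposure training uses small, stable values
som_rate_at <- function(age) 0.02 + 0.28 * exp(-age / 5)
som_sigma_at <- function(age, grid_max) {
  0.4 + (grid_max / 3 - 0.4) * exp(-age / 4)
}

#' Hebbian update of an associative link matrix
#'
#' `W[u, v]` grows by `rate * a_src[u] * a_tgt[v]`; every updated row is then
#' renormalized to unit sum over alive target units. `rate = 0` is a no-op.
#'
#' @param links link weight matrix (source units x target units).
#' @param source_activation,target_activation activation vectors.
#' @param rate Hebbian learning rate.
#' @param alive_target logical alive-mask of the target map.
#' @return the updated matrix.
#' @export
hebbian_update <- function(links, source_activation, target_activation, rate,
                           alive_target = rep(TRUE, ncol(links))) {
  cpp_hebbian_update(links, source_activation, target_activation, rate,
                     alive_target)
}

#' Train a model under an exposure schedule
#'
#' For each presentation a word and a language are sampled according to the
#' epoch proportions; the semantic map and the exposed language's phonetic
#' map are SOM-trained on the word, the semantic/exposed links are updated
#' by Hebbian co-activation, and the activation evoked in the unexposed
#' phonetic map (through the semantic links) trains the phonetic-phonetic
#' links. SOM rate and neighbourhood decay with simulated age. The model's
#' age advances by the schedule duration and all maps are relabelled at the
#' end.
#'
#' @param model a `bilex_model`.
#' @param schedule epoch data frame as from [schedule_from_profile()] (any
#'   subset of rows); columns `duration` and `p_L2` are used.
#' @param words_per_year presentations per simulated year.
#' @param hebb_rate Hebbian rate for link training during exposure.
#' @param seed integer seed (`NULL` = current RNG state).
#' @param relabel relabel all maps after training (default `TRUE`).
#' @param poststroke_plasticity factor scaling SOM and Hebbian rates during
#'   epochs whose `phase` is `"poststroke"`, reflecting reduced learning
#'   capacity of the damaged system relative to healthy development.
#' @return the trained `bilex_model`.
#' @export
train_exposure <- function(model, schedule, words_per_year = 1000,
                           hebb_rate = 0.01, seed = NULL, relabel = TRUE,
                           poststroke_plasticity = 0.25) {
  lex <- model$lexicon
  phases <- schedule$phase %||% rep("prestroke", nrow(schedule))
  with_seed(seed, {
    for (e in seq_len(nrow(schedule))) {
      dur <- schedule$duration[e]
      if (dur <= 0) next
      p2 <- schedule$p_L2[e]
      scale <- if (identical(phases[e], "poststroke"))
        poststroke_plasticity else 1
      n_chunks <- max(1L, ceiling(dur / 0.5))
      chunk_dur <- dur / n_chunks
      for (ch in seq_len(n_chunks)) {
        mid_age <- model$age + chunk_dur / 2
        n_pres <- round(chunk_dur * words_per_year)
        if (n_pres > 0) {
          up <- cpp_train_exposure_chunk(
            model$sem$W, model$sem$alive, model$sem$shape[2], lex$sem,
            model$phon_L1$W, model$phon_L1$alive,
            model$phon_L2$W, model$phon_L2$alive,
            model$phon_L1$shape[2], lex$phon_L1, lex$phon_L2,
            model$links$sem.L1, model$links$L1.sem, model$links$sem.L2,
            model$links$L2.sem, model$links$L1.L2, model$links$L2.L1,
            n_pres, p2,
            scale * som_rate_at(mid_age),
            som_sigma_at(mid_age, max(model$sem$shape)),
            scale * som_rate_at(mid_age),
            som_sigma_at(mid_age, max(model$phon_L1$shape)),
            scale * hebb_rate, model$act_sigma)
          model$sem$W <- up$semW
          model$phon_L1$W <- up$p1W
          model$phon_L2$W <- up$p2W
          model$links <- list(sem.L1 = up$L_s1, L1.sem = up$L_1s,
                              sem.L2 = up$L_s2, L2.sem = up$L_2s,
                              L1.L2 = up$L_12, L2.L1 = up$L_21)
        }
        model$age <- model$age + chunk_dur
      }
    }
  })
  if (relabel) {
    model$sem <- som_relabel(model$sem, lex$sem, lex$id)
    model$phon_L1 <- som_relabel(model$phon_L1, lex$phon_L1, lex$id)
    model$phon_L2 <- som_relabel(model$phon_L2, lex$phon_L2, lex$id)
  }
  model
}

word_rows <- function(lexicon, word_ids) {
  rows <- match(word_ids, lexicon$id)
  if (anyNA(rows)) stop_bilex("unknown word id(s): ",
                              paste(word_ids[is.na(rows)], collapse = ", "))
  rows
}

#' Simulate naming of words
#'
#' A word's semantic vector is presented to the semantic map; the winner's
#' activation bump is transferred through the semantic-to-phonetic links, and
#' the word counts as correctly named if the most highly activated alive
#' phonetic unit carries that word's label. A destroyed phonetic (or
#' semantic) map yields an incorrect response, not an error.
#'
#' @param model a `bilex_model`.
#' @param word_id a single word id (for `name_word`).
#' @param language `"L1"` or `"L2"`: which phonetic map to name into.
#' @return `name_word`: list with `correct` (logical) and `winner` (1-based
#'   phonetic unit index or `NA`).
#' @export
name_word <- function(model, word_id, language) {
  check_language(language)
  r <- naming_correct(model, word_id, language)
  list(correct = r$correct[1],
       winner = if (is.na(r$winner[1])) NA_integer_ else r$winner[1] + 1L)
}

naming_correct <- function(model, word_ids, language) {
  pm <- phon_map(model, language)
  rows <- word_rows(model$lexicon, word_ids)
  cpp_name_words(model$sem$W, model$sem$alive, model$sem$shape[2],
                 model$links[[paste0("sem.", language)]], pm$alive, pm$labels,
                 model$lexicon$sem[rows, , drop = FALSE],
                 as.integer(word_ids), model$act_sigma)
}

#' Naming accuracy over a word set
#'
#' @param model a `bilex_model`.
#' @param word_ids word ids to probe.
#' @param language `"L1"` or `"L2"`.
#' @return proportion of `word_ids` correctly named, in `[0, 1]`.
#' @export
naming_accuracy <- function(model, word_ids, language) {
  if (length(word_ids) == 0) stop_bilex("empty word set: accuracy undefined")
  mean(naming_correct(model, word_ids, language)$correct)
}

#' Picture-naming style score on a 60-word probe set
#'
#' `round(60 * accuracy)` on the designated probe set, comparable to a
#' 60-item picture naming test score.
#'
#' @inheritParams naming_accuracy
#' @return integer score 0-60.
#' @export
bnt_score <- function(model, word_ids, language) {
  as.integer(round(BNT_MAX * naming_accuracy(model, word_ids, language)))
}

#' Simulate translation of a word between languages
#'
#' The word's phonetic vector is presented to the source-language phonetic
#' map and activation is transferred through the phonetic-phonetic links;
#' correct iff the most active alive target unit carries the word's label.
#'
#' @param model a `bilex_model`.
#' @param word_id a single word id.
#' @param from_language source language, `"L1"` or `"L2"`.
#' @return logical: correctly translated.
#' @export
translate_word <- function(model, word_id, from_language) {
  check_language(from_language)
  translation_correct(model, word_id, from_language)$correct[1]
}

translation_correct <- function(model, word_ids, from_language) {
  to <- setdiff(LANGS, from_language)
  src <- phon_map(model, from_language)
  tgt <- phon_map(model, to)
  rows <- word_rows(model$lexicon, word_ids)
  cpp_translate_words(src$W, src$alive, src$shape[2],
                      model$links[[paste0(from_language, ".", to)]],
                      tgt$alive, tgt$labels,
                      lexicon_vectors(model$lexicon, from_language)[rows, ,
                                                                    drop = FALSE],
                      as.integer(word_ids), model$act_sigma)
}

#' Simulate a semantic-association (PAPT-style) test
#'
#' Per item, the target and both options are presented to the (possibly
#' lesioned) semantic map; the winners' weight vectors identify the
#' distinguishing feature (the dimension where the two options' winner
#' vectors differ most) and the option whose winner vector is closer to the
#' target's on that feature is chosen. If the semantic map is destroyed each
#' item is scored by a fair coin from the seeded generator.
#'
#' @param model a `bilex_model`.
#' @param items item data frame from [generate_papt_items()].
#' @param seed seed for coin flips on a destroyed map (`NULL` = current RNG).
#' @return list with `prop` (proportion correct), `count` (raw number
#'   correct) and `n`.
#' @export
simulate_papt <- function(model, items, seed = NULL) {
  rows_t <- word_rows(model$lexicon, items$target_id)
  rows_a <- word_rows(model$lexicon, items$option_a_id)
  rows_b <- word_rows(model$lexicon, items$option_b_id)
  choice <- cpp_papt_choose(model$sem$W, model$sem$alive,
                            model$lexicon$sem[rows_t, , drop = FALSE],
                            model$lexicon$sem[rows_a, , drop = FALSE],
                            model$lexicon$sem[rows_b, , drop = FALSE])
  undecided <- choice < 0
  if (any(undecided))
    choice[undecided] <- with_seed(seed,
                                   as.integer(stats::runif(sum(undecided)) < 0.5))
  picked <- ifelse(choice == 0, "a", "b")
  count <- sum(picked == items$correct_option)
  list(prop = count / nrow(items), count = as.integer(count),
       n = nrow(items))
}

#' Write / read a model snapshot as JSON
#'
#' Full-precision plain-text serialization of maps, links, age and lexicon.
#'
#' @param model a `bilex_model`.
#' @param path file path.
#' @return `read_bilex_model` returns a `bilex_model`.
#' @export
write_bilex_model <- function(model, path) {
  obj <- list(version = 1L, age = model$age, act_sigma = model$act_sigma,
              lexicon = unclass(model$lexicon),
              links = model$links,
              maps = lapply(list(sem = model$sem, phon_L1 = model$phon_L1,
                                 phon_L2 = model$phon_L2), unclass))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bilex_model
#' @export
read_bilex_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix_map <- function(m) {
    structure(list(W = m$W, shape = as.integer(m$shape),
                   alive = as.logical(m$alive),
                   labels = as.integer(m$labels)), class = "som_map")
  }
  lex <- obj$lexicon
  lex$id <- as.integer(lex$id)
  lex$category <- as.integer(lex$category)
  lex$sem <- matrix(as.integer(lex$sem), nrow = length(lex$id))
  lex$n_words <- as.integer(lex$n_words)
  lex$n_categories <- as.integer(lex$n_categories)
  lex$d_sem <- as.integer(lex$d_sem)
  lex$d_phon <- as.integer(lex$d_phon)
  structure(list(sem = fix_map(obj$maps$sem),
                 phon_L1 = fix_map(obj$maps$phon_L1),
                 phon_L2 = fix_map(obj$maps$phon_L2),
                 links = lapply(obj$links, as.matrix),
                 lexicon = structure(lex, class = "bilex_lexicon"),
                 age = obj$age, act_sigma = obj$act_sigma),
            class = "bilex_model")
}
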