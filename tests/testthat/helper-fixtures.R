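# Shared small fixtures, built once per test run. Heavier trained models are
# cached lazily so the cost is paid only by the files that need them.

tiny_lexicon <- function(seed = 1, n = 60) {
  generate_lexicon(n, 6, d_sem = 80, d_phon = 30, seed = seed)
}

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# balanced, converged toy model on the 60-word lexicon
trained_toy <- function() {
  fixture("trained_toy", function() {
    lex <- tiny_lexicon()
    m <- bilex_model(lex, c(12, 12), c(10, 10), act_sigma = 0.5, seed = 2)
    train_exposure(m, data.frame(phase = "prestroke", duration = 30,
                                 p_L2 = 0.5),
                   words_per_year = 600, hebb_rate = 0.01, seed = 3)
  })
}

# moderately lesioned poststroke toy (both phonetic maps at 0.6)
lesioned_toy <- function() {
  fixture("lesioned_toy", function() {
    m <- trained_toy()
    m <- apply_lesion(m, "L1", 0.6)
    apply_lesion(m, "L2", 0.6)
  })
}

toy_profile <- function(treated = "L2", n_sessions = 6) {
  list(patient_id = "SYN", years_post_onset = 1, age_at_testing = 31,
       l2_aoa = 0, pct_lifetime_L1 = 50, pct_lifetime_L2 = 50,
       pct_use_L1 = 50, pct_use_L2 = 50, bnt_L1 = 30, bnt_L2 = 30,
       papt = 45, treated_language = treated, n_sessions = n_sessions)
}

random_som <- function(shape = c(6, 6), d = 5, seed = 1, n_dead = 0) {
  m <- som_new(shape, d, seed = seed)
  if (n_dead > 0) {
    dead <- with_seed(seed + 1,
                      sample.int(length(m$alive), n_dead))
    m$alive[dead] <- FALSE
  }
  m
}

# independent R-side recomputation of the naming decision
naming_oracle <- function(model, word_id, language) {
  lex <- model$lexicon
  row <- match(word_id, lex$id)
  sem <- model$sem
  d2 <- colSums((t(sem$W) - lex$sem[row, ])^2)
  d2[!sem$alive] <- Inf
  ws <- which.min(d2)
  nc <- sem$shape[2]
  rows <- (seq_along(sem$alive) - 1) %/% nc
  cols <- (seq_along(sem$alive) - 1) %% nc
  gd2 <- (rows - rows[ws])^2 + (cols - cols[ws])^2
  a <- ifelse(sem$alive & gd2 <= 9 * model$act_sigma^2,
              exp(-gd2 / (2 * model$act_sigma^2)), 0)
  pm <- model[[paste0("phon_", language)]]
  act <- as.numeric(t(model$links[[paste0("sem.", language)]]) %*% a)
  act[!pm$alive] <- -Inf
  u <- which.max(act)
  list(correct = isTRUE(pm$labels[u] == word_id), winner = u)
}
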