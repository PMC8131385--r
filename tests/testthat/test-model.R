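test_that("exposure schedules reproduce lifetime percentages in closed form", {
  pats <- bilex_patients()
  p1 <- pats[pats$patient_id == "P1", ]
  s <- schedule_from_profile(p1)
  pre <- s[s$phase == "prestroke", ]
  # closed-form rearrangement: p_L2 = share * age / (age - aoa)
  expect_equal(pre$p_L2[2], 0.28 * 44 / (44 - 19), tolerance = 1e-12)
  # re-averaging the full schedule recovers the lifetime share at testing
  full <- rbind(pre, data.frame(phase = "x", duration = p1$years_post_onset,
                                p_L1 = NA, p_L2 = pre$p_L2[2]))
  expect_equal(sum(full$duration * full$p_L2) / sum(full$duration), 0.28,
               tolerance = 1e-12)
  expect_equal(attr(s, "onset_age"), 37)
  # poststroke epoch carries the use percentages
  post <- s[s$phase == "poststroke", ]
  expect_equal(post$p_L2, 0.22)
  expect_equal(post$duration, 7)
})

test_that("degenerate schedules: simultaneous acquisition and single language", {
  prof <- list(age_at_testing = 40, l2_aoa = 0, years_post_onset = 0,
               pct_lifetime_L2 = 50, pct_use_L2 = 50)
  s <- schedule_from_profile(prof)
  expect_identical(nrow(s[s$phase == "prestroke", ]), 1L)
  expect_equal(s$p_L2[1], 0.5)
  prof2 <- list(age_at_testing = 40, l2_aoa = 10, years_post_onset = 0,
                pct_lifetime_L2 = 0, pct_use_L2 = 0)
  s2 <- schedule_from_profile(prof2)
  expect_true(all(s2$p_L2 == 0))
  # unsatisfiable lifetime share clamps with a warning
  prof3 <- list(age_at_testing = 40, l2_aoa = 30, years_post_onset = 0,
                pct_lifetime_L2 = 80, pct_use_L2 = 50)
  expect_warning(s3 <- schedule_from_profile(prof3), "clamp")
  expect_equal(max(s3$p_L2), 1)
})

test_that("Hebbian updates normalize rows and sharpen co-activated pairs", {
  W <- matrix(1 / 4, 3, 4)
  a_src <- c(1, 0, 0)
  a_tgt <- c(0, 0, 1, 0)
  expect_equal(hebbian_update(W, a_src, a_tgt, rate = 0), W)
  up <- hebbian_update(W, a_src, a_tgt, rate = 0.5)
  expect_gt(up[1, 3], W[1, 3])
  expect_true(all(up[1, -3] < W[1, -3]))
  expect_equal(rowSums(up), rep(1, 3))
  expect_equal(up[2:3, ], W[2:3, ])
  # property: row sums over alive targets equal 1 after random updates
  with_seed(21, {
    alive <- c(TRUE, TRUE, FALSE, TRUE)
    W2 <- matrix(stats::runif(12), 3, 4)
    W2[, !alive] <- 0
    W2 <- W2 / rowSums(W2)
    for (i in 1:20) {
      a1 <- stats::runif(3)
      a2 <- stats::runif(4) * alive
      W2 <- hebbian_update(W2, a1, a2, 0.3, alive)
      expect_equal(rowSums(W2[, alive, drop = FALSE]), rep(1, 3))
      expect_true(all(W2[, !alive] == 0))
    }
  })
})

test_that("zero-duration exposure training leaves the model unchanged", {
  lex <- tiny_lexicon()
  m <- bilex_model(lex, c(8, 8), c(6, 6), seed = 2)
  m2 <- train_exposure(m, data.frame(phase = "prestroke", duration = 0,
                                     p_L2 = 0.5),
                       words_per_year = 600, seed = 3)
  expect_equal(m2$sem$W, m$sem$W)
  expect_equal(m2$links, m$links)
  expect_equal(m2$age, m$age)
})

test_that("training is deterministic under a fixed seed", {
  lex <- tiny_lexicon()
  sched <- data.frame(phase = "prestroke", duration = 2, p_L2 = 0.5)
  m <- bilex_model(lex, c(8, 8), c(6, 6), seed = 2)
  a <- train_exposure(m, sched, words_per_year = 600, seed = 42)
  b <- train_exposure(m, sched, words_per_year = 600, seed = 42)
  expect_identical(a, b)
  c <- train_exposure(m, sched, words_per_year = 600, seed = 43)
  expect_false(identical(a$sem$W, c$sem$W))
})

test_that("single-language exposure leaves the other language unlearned", {
  lex <- tiny_lexicon()
  m <- bilex_model(lex, c(12, 12), c(10, 10), act_sigma = 0.5, seed = 4)
  m <- train_exposure(m, data.frame(phase = "prestroke", duration = 25,
                                    p_L2 = 0),
                      words_per_year = 600, seed = 5)
  expect_gt(naming_accuracy(m, lex$id, "L1"), 0.7)
  expect_lt(naming_accuracy(m, lex$id, "L2"), 0.1)
})

test_that("converged L2 accuracy is monotone in the L2 exposure proportion", {
  lex <- tiny_lexicon()
  levels <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  acc <- matrix(NA_real_, 3, length(levels))
  for (s in 1:3) {
    m0 <- bilex_model(lex, c(12, 12), c(10, 10), act_sigma = 0.5,
                      seed = 30 + s)
    for (k in seq_along(levels)) {
      m <- train_exposure(m0, data.frame(phase = "prestroke", duration = 25,
                                         p_L2 = levels[k]),
                          words_per_year = 600, seed = 60 + s)
      acc[s, k] <- naming_accuracy(m, lex$id, "L2")
    }
  }
  rho <- stats::cor(levels, colMeans(acc), method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("naming decisions match an explicit transfer-argmax oracle", {
  m <- trained_toy()
  ids <- m$lexicon$id[seq(1, 60, by = 6)]
  for (w in ids) for (l in c("L1", "L2")) {
    got <- name_word(m, w, l)
    want <- naming_oracle(m, w, l)
    expect_identical(got$correct, want$correct)
    expect_identical(got$winner, want$winner)
  }
})

test_that("naming accuracy equals the recount of per-word decisions", {
  m <- trained_toy()
  ids <- m$lexicon$id
  per_word <- vapply(ids, function(w) name_word(m, w, "L1")$correct,
                     logical(1))
  expect_equal(naming_accuracy(m, ids, "L1"), mean(per_word))
  expect_error(naming_accuracy(m, integer(), "L1"), "empty")
  probe <- ids[1:30]
  expect_identical(bnt_score(m, probe, "L1"),
                   as.integer(round(60 * naming_accuracy(m, probe, "L1"))))
})

test_that("a converged balanced model names and translates well", {
  m <- trained_toy()
  lex <- m$lexicon
  expect_gt(naming_accuracy(m, lex$id, "L1"), 0.8)
  expect_gt(naming_accuracy(m, lex$id, "L2"), 0.8)
  tr <- mean(vapply(lex$id, function(w) translate_word(m, w, "L1"),
                    logical(1)))
  expect_gt(tr, 0.5)
})

test_that("destroyed maps make naming and translation incorrect, not errors", {
  m <- trained_toy()
  dead <- apply_lesion(m, "L2", 1)
  expect_false(name_word(dead, 0L, "L2")$correct)
  expect_equal(naming_accuracy(dead, m$lexicon$id, "L2"), 0)
  expect_false(translate_word(dead, 0L, "L2"))
})

test_that("a hand-built semantic map with perfect prototypes aces the test", {
  lex <- tiny_lexicon(seed = 31)
  items <- generate_papt_items(lex, 20, seed = 32)
  m <- bilex_model(lex, c(8, 8), c(6, 6), seed = 33)
  # plant every word's exact semantic vector in its own unit
  m$sem$W[seq_len(60), ] <- lex$sem
  m$sem$W[61:64, ] <- 10  # far away, never winners
  expect_equal(simulate_papt(m, items)$prop, 1.0)
})

test_that("an untrained map scores far below a trained one on triplets", {
  lex <- tiny_lexicon(seed = 3)
  items <- generate_papt_items(lex, 52, seed = 4)
  props <- vapply(1:10, function(s) {
    m <- bilex_model(lex, c(12, 12), c(10, 10), seed = 400 + s)
    simulate_papt(m, items)$prop
  }, numeric(1))
  # an untrained map retains weak similarity information through winner
  # selection, so it scores above a fair coin but far below convergence
  expect_gt(mean(props), 0.4)
  expect_lt(mean(props), 0.78)
  expect_gt(simulate_papt(trained_toy(),
                          generate_papt_items(tiny_lexicon(), 52, seed = 4))$prop,
            mean(props))
})

test_that("a destroyed semantic map scores items by a seeded fair coin", {
  m <- trained_toy()
  items <- generate_papt_items(m$lexicon, 52, seed = 4)
  dead <- apply_lesion(m, "sem", 1)
  r1 <- simulate_papt(dead, items, seed = 9)
  r2 <- simulate_papt(dead, items, seed = 9)
  expect_identical(r1$count, r2$count)
  counts <- vapply(1:20, function(s)
    simulate_papt(dead, items, seed = s)$count, integer(1))
  expect_gt(mean(counts) / 52, 0.35)
  expect_lt(mean(counts) / 52, 0.65)
})

test_that("model snapshots round-trip through JSON", {
  lex <- tiny_lexicon(seed = 41, n = 10)
  m <- bilex_model(lex, c(4, 4), c(4, 4), seed = 42)
  m <- train_exposure(m, data.frame(phase = "prestroke", duration = 1,
                                    p_L2 = 0.5),
                      words_per_year = 200, seed = 43)
  path <- tempfile(fileext = ".json")
  write_bilex_model(m, path)
  back <- read_bilex_model(path)
  expect_equal(back$sem$W, m$sem$W, tolerance = 1e-12)
  expect_equal(back$links, m$links, tolerance = 1e-12)
  expect_identical(back$sem$labels, m$sem$labels)
  expect_equal(back$age, m$age)
  unlink(path)
})
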