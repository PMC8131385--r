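#' Generate a synthetic bilingual lexicon
#'
#' Builds a word inventory with one shared binary semantic vector and two
#' per-language phonetic vectors per word. Semantic vectors have taxonomic
#' structure: each category owns a disjoint block of core features plus a few
#' shared "pool" features, and every word adds word-distinctive pool features.
#' Half of the later words in a category are generated as taxonomic siblings
#' (an existing word plus one extra feature), which guarantees that
#' semantic-association triplets with a single defining feature exist.
#' Phonetic vectors are real-valued in `[0, 1]`; a tunable fraction of words
#' ("cognates") get correlated L1/L2 phonetic forms.
#'
#' @param n_words number of words (ids are dense `0..n_words-1`).
#' @param n_categories number of semantic categories.
#' @param d_sem semantic dimensionality (binary features).
#' @param d_phon phonetic dimensionality per language.
#' @param cross_language_phon_similarity fraction of words whose two phonetic
#'   vectors are correlated (cognate-like structure).
#' @param seed integer seed; the same seed gives a byte-identical lexicon.
#' @param core_size core features per category (disjoint across categories).
#' @param cat_pool_size shared pool features per category.
#' @param n_distinctive word-distinctive pool features for non-sibling words.
#' @param sibling_prob probability that a later word in a category is built
#'   as parent-plus-one-feature rather than drawn fresh.
#' @return an object of class `bilex_lexicon`: a list with `id`, `category`,
#'   binary matrix `sem` and matrices `phon_L1`, `phon_L2` (one row per word).
#' @export
generate_lexicon <- function(n_words, n_categories, d_sem = 100, d_phon = 40,
                             cross_language_phon_similarity = 0.2, seed = 1,
                             core_size = 4, cat_pool_size = 3,
                             n_distinctive = 2, sibling_prob = 0.5) {
  if (n_categories < 1) stop_bilex("n_categories must be >= 1")
  if (n_words < n_categories)
    stop_bilex("n_words (", n_words, ") must be >= n_categories (",
               n_categories, ")")
  n_core <- n_categories * core_size
  pool <- seq.int(n_core + 1, length.out = max(0, d_sem - n_core))
  if (length(pool) < cat_pool_size + n_distinctive + 2)
    stop_bilex("d_sem = ", d_sem, " too small: need > ", n_core,
               " core features plus a shared pool of at least ",
               cat_pool_size + n_distinctive + 2, " features")
  with_seed(seed, {
    category <- sort(rep_len(seq_len(n_categories), n_words))
    sem <- matrix(0L, n_words, d_sem)
    cat_features <- lapply(seq_len(n_categories), function(cc) {
      core <- seq.int((cc - 1L) * core_size + 1L, length.out = core_size)
      c(core, sample(pool, cat_pool_size))
    })
    for (w in seq_len(n_words)) {
      cc <- category[w]
      earlier <- which(category[seq_len(w - 1L)] == cc)
      if (length(earlier) > 0 && stats::runif(1) < sibling_prob) {
        parent <- sem[earlier[sample.int(length(earlier), 1)], ]
        free <- pool[parent[pool] == 0L]
        extra <- free[sample.int(length(free), 1)]
        vec <- parent
        vec[extra] <- 1L
      } else {
        vec <- integer(d_sem)
        vec[cat_features[[cc]]] <- 1L
        vec[sample(pool, n_distinctive)] <- 1L
      }
      # enforce distinct semantic vectors
      tries <- 0L
      while (w > 1 &&
             any(colSums(abs(t(sem[seq_len(w - 1L), , drop = FALSE]) - vec)) == 0)) {
        free <- pool[vec[pool] == 0L]
        vec[free[sample.int(length(free), 1)]] <- 1L
        tries <- tries + 1L
        if (tries > 20L) stop_bilex("could not build distinct semantic vectors")
      }
      sem[w, ] <- vec
    }
    phon_L1 <- matrix(stats::runif(n_words * d_phon), n_words, d_phon)
    phon_L2 <- matrix(stats::runif(n_words * d_phon), n_words, d_phon)
    cognate <- stats::runif(n_words) < cross_language_phon_similarity
    if (any(cognate)) {
      k <- sum(cognate)
      phon_L2[cognate, ] <- clamp01(phon_L1[cognate, , drop = FALSE] +
                                      matrix(stats::rnorm(k * d_phon, 0, 0.1),
                                             k, d_phon))
    }
    structure(list(id = 0:(n_words - 1L), category = category, sem = sem,
                   phon_L1 = phon_L1, phon_L2 = phon_L2,
                   n_words = n_words, n_categories = n_categories,
                   d_sem = d_sem, d_phon = d_phon, cognate = cognate),
              class = "bilex_lexicon")
  })
}

#' @export
print.bilex_lexicon <- function(x, ...) {
  cat("Synthetic bilingual lexicon\n")
  cat("  words:", x$n_words, " categories:", x$n_categories, "\n")
  cat("  semantic features:", x$d_sem, " (binary); phonetic dims:",
      x$d_phon, "per language\n")
  cat("  cognate-like words:", sum(x$cognate), "\n")
  invisible(x)
}

lexicon_vectors <- function(lexicon, map) {
  switch(map,
         sem = lexicon$sem,
         L1 = lexicon$phon_L1,
         L2 = lexicon$phon_L2,
         stop_bilex("unknown map '", map, "'"))
}

#' Generate semantic-association (PAPT-style) triplet items
#'
#' Each item has a target word and two same-category options that differ in a
#' single defining semantic feature; exactly one option shares that feature
#' with the target, and a perfect reasoner choosing the option that shares
#' the distinguishing feature scores 100%. Option pairs are taken from the
#' lexicon's nested (sibling) word pairs; targets come from other categories.
#'
#' @param lexicon a `bilex_lexicon`.
#' @param n_items number of items to build.
#' @param seed integer seed.
#' @return a data frame with columns `target_id`, `option_a_id`,
#'   `option_b_id`, `distinguishing_feature` (1-based semantic feature
#'   index) and `correct_option` (`"a"` or `"b"`).
#' @export
generate_papt_items <- function(lexicon, n_items = 52, seed = 1) {
  if (n_items == 0)
    return(data.frame(target_id = integer(), option_a_id = integer(),
                      option_b_id = integer(),
                      distinguishing_feature = integer(),
                      correct_option = character()))
  sem <- lexicon$sem
  cat <- lexicon$category
  # sibling ordered pairs (rich, plain): plain's features are a subset of
  # rich's and the pair differs in exactly one defining feature
  pairs <- list()
  for (cc in unique(cat)) {
    idx <- which(cat == cc)
    if (length(idx) < 2) next
    for (i in idx) for (j in idx) {
      if (i == j) next
      extra <- which(sem[i, ] == 1L & sem[j, ] == 0L)
      rev <- any(sem[j, ] == 1L & sem[i, ] == 0L)
      if (!rev && length(extra) == 1)
        pairs[[length(pairs) + 1L]] <- list(rich = i, plain = j, extra = extra)
    }
  }
  if (length(pairs) == 0)
    stop_bilex("lexicon too small/homogeneous: no nested same-category ",
               "word pairs available for triplet construction")
  with_seed(seed, {
    out <- vector("list", n_items)
    tries <- 0L
    k <- 0L
    while (k < n_items) {
      tries <- tries + 1L
      if (tries > 200L * n_items)
        stop_bilex("lexicon too small/homogeneous to build ", n_items,
                   " valid triplet items")
      p <- pairs[[sample.int(length(pairs), 1)]]
      f <- p$extra[sample.int(length(p$extra), 1)]
      cand <- which(cat != cat[p$rich] & sem[, f] == 1L)
      if (length(cand) == 0) next
      tgt <- cand[sample.int(length(cand), 1)]
      flip <- stats::runif(1) < 0.5
      k <- k + 1L
      out[[k]] <- data.frame(
        target_id = lexicon$id[tgt],
        option_a_id = lexicon$id[if (flip) p$plain else p$rich],
        option_b_id = lexicon$id[if (flip) p$rich else p$plain],
        distinguishing_feature = f,
        correct_option = if (flip) "b" else "a",
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Write / read a lexicon as JSON
#'
#' Plain-text serialization for reproducible fixtures; `read_lexicon`
#' round-trips the object written by `write_lexicon`.
#'
#' @param lexicon a `bilex_lexicon`.
#' @param path file path.
#' @return `read_lexicon` returns a `bilex_lexicon`.
#' @export
write_lexicon <- function(lexicon, path) {
  jsonlite::write_json(unclass(lexicon), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$id <- as.integer(obj$id)
  obj$category <- as.integer(obj$category)
  obj$sem <- matrix(as.integer(obj$sem), nrow = length(obj$id))
  obj$n_words <- as.integer(obj$n_words)
  obj$n_categories <- as.integer(obj$n_categories)
  obj$d_sem <- as.integer(obj$d_sem)
  obj$d_phon <- as.integer(obj$d_phon)
  structure(obj, class = "bilex_lexicon")
}
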