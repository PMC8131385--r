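#' Create a self-organizing map
#'
#' A rectangular grid of weight vectors with an alive-mask (used to model
#' lesions by unit deletion) and optional unit-to-word labels. Weights are
#' initialized uniformly in `[0, 1]`.
#'
#' @param shape grid shape `c(rows, cols)`.
#' @param d input dimensionality.
#' @param seed integer seed for weight initialization (`NULL` = current RNG).
#' @return an object of class `som_map` with fields `W` (units x d weight
#'   matrix, row-major unit order), `shape`, `alive` (logical), `labels`
#'   (integer word ids, `NA` where unlabeled or dead).
#' @export
som_new <- function(shape, d, seed = NULL) {
  n <- shape[1] * shape[2]
  W <- with_seed(seed, matrix(stats::runif(n * d), n, d))
  structure(list(W = W, shape = as.integer(shape),
                 alive = rep(TRUE, n), labels = rep(NA_integer_, n)),
            class = "som_map")
}

#' @export
print.som_map <- function(x, ...) {
  cat("SOM:", x$shape[1], "x", x$shape[2], "grid, input dim", ncol(x$W),
      "-", sum(x$alive), "of", length(x$alive), "units alive\n")
  invisible(x)
}

#' Find the winning unit for an input vector
#'
#' Returns the alive unit minimizing Euclidean distance to the input; ties
#' are broken by the lowest row-major index. Dead units are never returned.
#'
#' @param map a `som_map`.
#' @param input_vec numeric input vector.
#' @return 1-based unit index.
#' @export
find_winner <- function(map, input_vec) {
  w <- cpp_find_winner(map$W, map$alive, input_vec)
  if (w < 0) stop_bilex("map destroyed: no alive units")
  w + 1L
}

#' One SOM training step
#'
#' Moves the winner and its neighbours toward the input by
#' `rate * exp(-d^2 / (2 sigma^2))`, where `d` is grid Euclidean distance
#' (truncated at three sigma). Dead units are never updated; `rate = 0`
#' leaves the map unchanged.
#'
#' @param map a `som_map`.
#' @param input_vec numeric input vector.
#' @param rate SOM learning rate.
#' @param sigma Gaussian neighbourhood radius in grid cells.
#' @return the updated `som_map`.
#' @export
som_train_step <- function(map, input_vec, rate, sigma) {
  if (!any(map$alive)) stop_bilex("map destroyed: no alive units")
  map$W <- cpp_som_train_step(map$W, map$alive, map$shape[2], input_vec,
                              rate, sigma)
  map
}

#' Label map units with word ids
#'
#' Winner labelling: each word's winning unit gets that word's id (the
#' nearest such word when several words share a winner); alive units that win
#' nothing get the id of their nearest word vector. Dead units keep `NA`.
#'
#' @param map a `som_map`.
#' @param vectors matrix of word vectors (one row per word).
#' @param ids integer word ids, one per row of `vectors`.
#' @return the relabelled `som_map`.
#' @export
som_relabel <- function(map, vectors, ids = seq_len(nrow(vectors)) - 1L) {
  map$labels <- cpp_relabel(map$W, map$alive, vectors, as.integer(ids))
  map
}

#' Mean quantization error of a map on a vector set
#'
#' Mean squared Euclidean distance between each vector and its winning
#' unit's weights; the standard SOM convergence diagnostic.
#'
#' @inheritParams som_relabel
#' @return a non-negative scalar (NA if the map is destroyed).
#' @export
som_quant_error <- function(map, vectors) {
  cpp_quant_error(map$W, map$alive, vectors)
}

#' Gaussian activation pattern centred on a winner unit
#'
#' The graded map activation used for cross-map transfer: a Gaussian bump
#' over grid distance centred at the winning unit (peak 1, truncated at three
#' sigma, zero on dead units).
#'
#' @param map a `som_map`.
#' @param winner 1-based unit index.
#' @param sigma bump width in grid cells.
#' @return numeric activation vector over units.
#' @export
activation_bump <- function(map, winner, sigma = 1) {
  as.numeric(cpp_activation_bump(length(map$alive), map$shape[2],
                                 winner - 1L, sigma, map$alive))
}
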