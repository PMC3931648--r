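#' Euclidean distance between two acceleration triples
#'
#' The distance used throughout the classifier: the square root of the sum
#' over the three axes of squared coordinate differences, both points in g.
#'
#' @param a,b Numeric length-3 vectors `(x, y, z)`, finite.
#' @return A non-negative scalar.
#' @examples
#' euclidean_distance(c(1, 2, 2), c(0, 0, 0))  # 3
#' @export
euclidean_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 3L || length(b) != 3L)
    stop("acceleration triples must have length 3", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("acceleration triples must be finite", call. = FALSE)
  sqrt(sum((a - b)^2))
}

# Squared distances from each row of the n x 3 matrix `queries` to each row
# of the m x 3 matrix `train`; returns an n x m matrix.  Clamped at zero to
# absorb the negative epsilons the expansion (|q|^2 + |t|^2 - 2 q.t) can
# produce in floating point.
cross_dist2 <- function(queries, train) {
  q2 <- rowSums(queries^2)
  t2 <- rowSums(train^2)
  d2 <- outer(q2, t2, "+") - 2 * tcrossprod(queries, train)
  d2[d2 < 0] <- 0
  d2
}

# Majority vote over k neighbour labels.  Ties between labels with equal
# maximal count are broken uniformly at random (consuming the current RNG
# stream only when a tie exists); prob is the count of the chosen label
# over k.
majority_vote <- function(labels) {
  counts <- table(labels)
  winners <- names(counts)[counts == max(counts)]
  winner <- if (length(winners) == 1L) winners else
    winners[sample.int(length(winners), 1L)]
  list(winning_label = winner,
       prob = as.integer(counts[[winner]]) / length(labels))
}

#' Classify one acceleration triple against a labelled training set
#'
#' Finds the `k` training samples of least Euclidean distance to the query
#' and assigns the majority label among them.  The confidence output `prob`
#' is the proportion of the `k` neighbours belonging to the winning class,
#' so `prob * k` is always an integer in `1..k`.
#'
#' Tie handling: if two or more labels share the maximal neighbour count,
#' the winner is drawn uniformly at random among them (seed the RNG via
#' `seed` or [set.seed()] for reproducibility); `prob` is computed for the
#' label actually chosen.  Distance ties at the k-th neighbour rank are
#' resolved deterministically in favour of the lowest training row indices,
#' keeping the neighbourhood size exactly `k`.
#'
#' @param query Numeric length-3 vector `(x, y, z)` in g.
#' @param training A fully labelled [accel_dataset] with at least `k` rows.
#' @param k Number of neighbours (positive integer, default 3).
#' @param seed Optional integer seed for vote tie-breaking; `NULL` (the
#'   default) uses the current RNG state.
#' @return An object of class `neighbor_vote`: a list with
#'   `query` (the triple), `neighbor_index`, `neighbor_distance` (ascending),
#'   `neighbor_label` (each length `k`), `winning_label` and `prob`.
#' @export
classify_point <- function(query, training, k = 3L, seed = NULL) {
  query <- as.numeric(query)
  if (length(query) != 3L || !all(is.finite(query)))
    stop("query must be a finite (x, y, z) triple", call. = FALSE)
  check_training(training, k)
  if (!is.null(seed)) set.seed(seed)
  d2 <- cross_dist2(matrix(query, nrow = 1L),
                    as.matrix(training[, c("x", "y", "z")]))[1L, ]
  idx <- order(d2, seq_along(d2))[seq_len(k)]  # stable: index breaks ties
  vote <- majority_vote(training$label[idx])
  structure(list(query = query,
                 neighbor_index = idx,
                 neighbor_distance = sqrt(d2[idx]),
                 neighbor_label = training$label[idx],
                 winning_label = vote$winning_label,
                 prob = vote$prob),
            class = "neighbor_vote")
}

#' @export
print.neighbor_vote <- function(x, ...) {
  cat(sprintf("<neighbor_vote> k=%d -> %s (prob %.3f)\n",
              length(x$neighbor_index), x$winning_label, x$prob))
  invisible(x)
}

check_training <- function(training, k) {
  if (!inherits(training, "accel_dataset"))
    stop("training must be an accel_dataset", call. = FALSE)
  if (!is_fully_labeled(training))
    stop("training set must be fully labelled", call. = FALSE)
  k <- as.integer(k)
  if (is.na(k) || k < 1L)
    stop("k must be a positive integer", call. = FALSE)
  if (k > nrow(training))
    stop("k (", k, ") exceeds training-set size (", nrow(training), ")",
         call. = FALSE)
  invisible(k)
}

#' Classify every sample of a test dataset
#'
#' Runs [classify_point()] for each test sample against the same training
#' set, in order.  Output is deterministic for a given `seed`: the RNG is
#' seeded once, and draws are consumed only when a vote tie occurs.
#'
#' @param test An [accel_dataset] of query samples (labels, if any, are
#'   ignored here and used later for verification).
#' @param training A fully labelled [accel_dataset].
#' @param k Number of neighbours (default 3).
#' @param seed Integer seed for vote tie-breaking (default 1).
#' @return A `data.frame` of class `knn_votes` with one row per test
#'   sample: `index`, `predicted` (winning behaviour) and `prob`.
#' @examples
#' spec <- default_ethogram(seed = 7)
#' sets <- simulate_dataset(spec)
#' votes <- classify_dataset(sets$testing, sets$training, k = 3)
#' table(votes$predicted)
#' @export
classify_dataset <- function(test, training, k = 3L, seed = 1L) {
  if (!inherits(test, "accel_dataset"))
    stop("test must be an accel_dataset", call. = FALSE)
  if (nrow(test) == 0L)
    stop("test set is empty", call. = FALSE)
  k <- check_training(training, k)
  if (!is.null(seed)) set.seed(seed)
  d2 <- cross_dist2(as.matrix(test[, c("x", "y", "z")]),
                    as.matrix(training[, c("x", "y", "z")]))
  m <- ncol(d2)
  predicted <- character(nrow(d2))
  prob <- numeric(nrow(d2))
  for (i in seq_len(nrow(d2))) {
    idx <- order(d2[i, ], seq_len(m))[seq_len(k)]
    vote <- majority_vote(training$label[idx])
    predicted[i] <- vote$winning_label
    prob[i] <- vote$prob
  }
  structure(data.frame(index = seq_len(nrow(d2)),
                       predicted = predicted, prob = prob),
            k = k, class = c("knn_votes", "data.frame"))
}
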