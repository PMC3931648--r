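#' Discard-aware confusion counts under a minimum-majority threshold
#'
#' Classifications whose confidence `prob` reaches the threshold are kept;
#' the rest are discarded.  Each test sample then falls into exactly one
#' cell: kept and correct = true positive (TP); kept and incorrect = false
#' positive (FP); discarded and incorrect = true negative (TN); discarded
#' and correct = false negative (FN).  Note that discarding a correct
#' classification counts as a false negative.  "Reaches" is implemented as
#' `prob >= threshold`, so a unanimous vote (`prob = 1`) always passes.
#'
#' Because correctness does not depend on the threshold, `TP + FN` (total
#' correct votes) and `FP + TN` (total incorrect votes) are invariant
#' across thresholds for fixed votes.
#'
#' @param votes A `knn_votes` data frame from [classify_dataset()], or any
#'   data frame with columns `predicted` and `prob`.
#' @param truths Character vector of true behaviour labels, same length.
#' @param threshold Minimum-majority threshold in `[0, 1]`.
#' @return An object of class `confusion_counts`: a list with integer
#'   fields `TP`, `FP`, `TN`, `FN` and the `threshold` applied.
#' @examples
#' v <- data.frame(predicted = c("a", "b", "b", "a"),
#'                 prob = c(0.9, 0.9, 0.4, 0.4))
#' confusion_counts(v, truths = c("a", "a", "a", "a"), threshold = 0.5)
#' @export
confusion_counts <- function(votes, truths, threshold) {
  if (!is.data.frame(votes) ||
      !all(c("predicted", "prob") %in% names(votes)))
    stop("votes must have columns 'predicted' and 'prob'", call. = FALSE)
  truths <- as.character(truths)
  if (length(truths) != nrow(votes))
    stop("votes (", nrow(votes), ") and truths (", length(truths),
         ") differ in length", call. = FALSE)
  if (nrow(votes) == 0L)
    stop("no classifications to evaluate", call. = FALSE)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must be a number in [0, 1]", call. = FALSE)
  correct <- votes$predicted == truths
  kept <- votes$prob >= threshold
  structure(list(TP = sum(correct & kept),
                 FP = sum(!correct & kept),
                 TN = sum(!correct & !kept),
                 FN = sum(correct & !kept),
                 threshold = threshold),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf(
    "<confusion_counts> threshold %.2f: TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
    x$threshold, x$TP, x$FP, x$TN, x$FN, x$TP + x$FP + x$TN + x$FN))
  invisible(x)
}

#' Performance metrics from discard-aware confusion counts
#'
#' `accuracy()` is the overall proportion of correctly handled samples,
#' `(TP + TN) / (TP + FP + TN + FN)`; `precision()` is the proportion of
#' kept classifications that were correct, `TP / (TP + FP)`; `recall()` is
#' the proportion of correctly classified samples that survived the
#' threshold, `TP / (TP + FN)`; `proportion_classified()` is the fraction
#' of the test set kept, `(TP + FP) / n`.
#'
#' A zero denominator (e.g. everything discarded, so `TP + FP = 0`) yields
#' `NA_real_`, an explicit undefined-metric state — never a silent 0 or 1.
#'
#' @param counts A [confusion_counts] object.
#' @return A number in `[0, 1]`, or `NA_real_` when undefined.
#' @name metrics
NULL

#' @rdname metrics
#' @export
accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$TP + counts$FP + counts$TN + counts$FN
  if (n == 0L) return(NA_real_)
  (counts$TP + counts$TN) / n
}

#' @rdname metrics
#' @export
precision <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  kept <- counts$TP + counts$FP
  if (kept == 0L) return(NA_real_)
  counts$TP / kept
}

#' @rdname metrics
#' @export
recall <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  pos <- counts$TP + counts$FN
  if (pos == 0L) return(NA_real_)
  counts$TP / pos
}

#' @rdname metrics
#' @export
proportion_classified <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$TP + counts$FP + counts$TN + counts$FN
  if (n == 0L) return(NA_real_)
  (counts$TP + counts$FP) / n
}

#' Sweep the minimum-majority threshold and correlate metrics against it
#'
#' Applies each threshold in turn to the same classifications, computes the
#' confusion counts and all four metrics per threshold, then computes the
#' Spearman rank correlation (with exact permutation p-values at these
#' small n) of each metric against the threshold.  Raising the threshold
#' can only move kept samples to the discarded side, so
#' `proportion_classified` and `recall` are non-increasing across any
#' ascending grid.
#'
#' @inheritParams confusion_counts
#' @param thresholds Strictly increasing thresholds in `[0, 1]`; default
#'   `c(0.5, 0.6, 0.7, 0.8, 0.9)`.
#' @return An object of class `threshold_sweep`: a list with `metrics` (a
#'   data frame with one row per threshold: `threshold`, `TP`, `FP`, `TN`,
#'   `FN`, `proportion_classified`, `accuracy`, `precision`, `recall`) and
#'   `correlations` (a data frame `metric`, `r`, `p`; `r` is `NA` for a
#'   constant metric).
#' @export
threshold_sweep <- function(votes, truths,
                            thresholds = c(0.5, 0.6, 0.7, 0.8, 0.9)) {
  if (length(thresholds) == 0L || anyNA(thresholds) ||
      any(thresholds < 0 | thresholds > 1))
    stop("thresholds must be values in [0, 1]", call. = FALSE)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing", call. = FALSE)
  rows <- lapply(thresholds, function(th) {
    cc <- confusion_counts(votes, truths, th)
    data.frame(threshold = th, TP = cc$TP, FP = cc$FP, TN = cc$TN,
               FN = cc$FN,
               proportion_classified = proportion_classified(cc),
               accuracy = accuracy(cc), precision = precision(cc),
               recall = recall(cc))
  })
  metrics <- do.call(rbind, rows)
  cors <- lapply(c("proportion_classified", "accuracy", "precision",
                   "recall"), function(m) {
    ok <- !is.na(metrics[[m]])
    ct <- if (sum(ok) >= 3L)
      spearman_rank(metrics$threshold[ok], metrics[[m]][ok])
    else list(r = NA_real_, p = NA_real_)
    data.frame(metric = m, r = ct$r, p = ct$p)
  })
  structure(list(metrics = metrics, correlations = do.call(rbind, cors)),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat("<threshold_sweep>\n")
  print(x$metrics, row.names = FALSE)
  cat("Spearman rank correlation of each metric against threshold:\n")
  print(x$correlations, row.names = FALSE)
  invisible(x)
}

#' Spearman rank correlation with exact permutation p-value at small n
#'
#' Computes Spearman's r as the Pearson correlation of average ranks (ties
#' averaged).  The two-sided p-value is obtained by full enumeration of all
#' `n!` permutations of `ys` when `n <= 9` — exact even with ties — and by
#' the t approximation with `n - 2` degrees of freedom otherwise.  The
#' threshold sweeps evaluated here have n = 5, where the exact test
#' matters.
#'
#' @param xs,ys Numeric vectors of equal length >= 3.
#' @return A list with `r` in `[-1, 1]` and two-sided `p`.  When either
#'   vector has zero rank variance (all values tied) `r` and `p` are
#'   `NA_real_`.
#' @examples
#' spearman_rank(1:5, c(10, 8, 6, 4, 2))  # r = -1
#' @export
spearman_rank <- function(xs, ys) {
  xs <- as.numeric(xs); ys <- as.numeric(ys)
  n <- length(xs)
  if (length(ys) != n)
    stop("xs and ys must have equal length", call. = FALSE)
  if (n < 3L)
    stop("need at least 3 observations", call. = FALSE)
  if (anyNA(xs) || anyNA(ys))
    stop("missing values not allowed", call. = FALSE)
  rx <- rank(xs); ry <- rank(ys)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(r = NA_real_, p = NA_real_))
  # tie-free ranks: the classical d^2 form is exact (gives r = +/-1 on
  # perfectly monotone data with no floating-point residue); with ties,
  # Pearson on average ranks
  r <- if (!anyDuplicated(rx) && !anyDuplicated(ry))
    1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  else stats::cor(rx, ry)
  p <- if (n <= 9L) {
    perms <- all_permutations(n)
    # r for every permutation at once: with centred x-ranks cx the row sums
    # ryp %*% cx give (n-1) * cov(rx, ry_perm)
    cx <- rx - mean(rx)
    ryp <- matrix(ry[perms], nrow(perms), n)
    r_all <- as.vector(ryp %*% cx) / ((n - 1) * stats::sd(rx) * stats::sd(ry))
    mean(abs(r_all) >= abs(r) - 1e-12)
  } else {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = min(p, 1))
}

# All n! permutations of 1..n as an n! x n integer matrix (n <= 9).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (pos in seq_len(n)) {
    blk <- nrow(sub)
    block <- matrix(0L, blk, n)
    block[, pos] <- n
    block[, -pos] <- sub
    out[row + seq_len(blk), ] <- block
    row <- row + blk
  }
  out
}
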