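# Shared fixtures and independent oracles for the test suite.

# Random labelled dataset in a bounded box; continuous coordinates, so
# distance ties have probability zero.
random_training <- function(n, labels = c("a", "b", "c"), rate = 20) {
  accel_dataset(x = runif(n, -2, 2), y = runif(n, -2, 2),
                z = runif(n, -2, 2), sample_rate = rate,
                label = sample(labels, n, replace = TRUE))
}

# Exhaustive compute-all-distances-and-sort nearest-neighbour reference,
# coded independently of the package internals (per-row sqrt/sum loop).
oracle_neighbors <- function(query, training, k) {
  d <- vapply(seq_len(nrow(training)), function(j)
    sqrt(sum((c(training$x[j], training$y[j], training$z[j]) - query)^2)),
    0)
  idx <- order(d, seq_along(d))[seq_len(k)]
  counts <- table(training$label[idx])
  list(index = idx,
       winners = names(counts)[counts == max(counts)],
       prob = max(counts) / k)
}

# Literal per-sample if/else transcription of the discard-aware
# TP/FP/TN/FN definitions.
oracle_confusion <- function(correct, prob, threshold) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(correct)) {
    if (prob[i] >= threshold) {
      if (correct[i]) tp <- tp + 1L else fp <- fp + 1L
    } else {
      if (correct[i]) fn <- fn + 1L else tn <- tn + 1L
    }
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

# Random vote set paired with truths; prob values on the k=3 lattice.
random_votes <- function(n, labels = c("u", "v", "w")) {
  truths <- sample(labels, n, replace = TRUE)
  correct <- runif(n) < 0.7
  predicted <- ifelse(correct, truths,
                      vapply(truths, function(tr)
                        sample(setdiff(labels, tr), 1L), ""))
  list(votes = data.frame(predicted = predicted,
                          prob = sample(c(1 / 3, 2 / 3, 1), n,
                                        replace = TRUE)),
       truths = truths)
}

# Straightforward recursive permutation enumerator (list of index
# vectors), independent of the package's matrix-based one.
enumerate_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in enumerate_perms(n - 1L))
    for (pos in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
  out
}

# Spearman r via rank-then-Pearson, and exact two-sided permutation p by
# looping the enumerator above; the reference for spearman_rank().
oracle_spearman <- function(x, y) {
  r <- cor(rank(x), rank(y))
  rs <- vapply(enumerate_perms(length(y)),
               function(pm) cor(rank(x), rank(y)[pm]), 0)
  list(r = r, p = mean(abs(rs) >= abs(r) - 1e-12))
}

write_tmp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
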