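test_that("each confusion cell fills from its defining case", {
  v <- data.frame(predicted = c("a", "b", "b", "a"),
                  prob = c(0.9, 0.9, 0.4, 0.4))
  cc <- confusion_counts(v, truths = c("a", "a", "a", "a"),
                         threshold = 0.5)
  expect_identical(cc$TP, 1L)  # kept, correct
  expect_identical(cc$FP, 1L)  # kept, incorrect
  expect_identical(cc$TN, 1L)  # discarded, incorrect
  expect_identical(cc$FN, 1L)  # discarded, correct
})

test_that("threshold zero discards nothing", {
  rv <- random_votes(50)
  cc <- confusion_counts(rv$votes, rv$truths, threshold = 0)
  expect_identical(cc$TN, 0L)
  expect_identical(cc$FN, 0L)
  expect_identical(cc$TP + cc$FP, 50L)
  # and accuracy = precision, recall = 1 exactly
  expect_identical(accuracy(cc), precision(cc))
  if (cc$TP > 0) expect_identical(recall(cc), 1)
})

test_that("counts match a literal per-sample if/else transcription", {
  withr::local_seed(23)
  for (rep in 1:5) {
    rv <- random_votes(200)
    correct <- rv$votes$predicted == rv$truths
    for (th in c(0.5, 0.6, 0.7, 0.8, 0.9)) {
      cc <- confusion_counts(rv$votes, rv$truths, th)
      ref <- oracle_confusion(correct, rv$votes$prob, th)
      expect_identical(c(TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN),
                       ref)
      expect_identical(cc$TP + cc$FP + cc$TN + cc$FN, 200L)
    }
  }
})

test_that("correct and incorrect totals are conserved across thresholds", {
  withr::local_seed(29)
  rv <- random_votes(150)
  counts <- lapply(seq(0, 1, by = 0.1), function(th)
    confusion_counts(rv$votes, rv$truths, th))
  pos <- vapply(counts, function(cc) cc$TP + cc$FN, 0L)
  neg <- vapply(counts, function(cc) cc$FP + cc$TN, 0L)
  expect_identical(unique(pos), pos[1L])
  expect_identical(unique(neg), neg[1L])
  # monotone cell movement as the threshold rises
  tp <- vapply(counts, `[[`, 0L, "TP"); fp <- vapply(counts, `[[`, 0L, "FP")
  tn <- vapply(counts, `[[`, 0L, "TN"); fn <- vapply(counts, `[[`, 0L, "FN")
  expect_true(all(diff(tp) <= 0))
  expect_true(all(diff(fp) <= 0))
  expect_true(all(diff(tn) >= 0))
  expect_true(all(diff(fn) >= 0))
})

test_that("metric ratios and their undefined states are right", {
  cc <- function(tp, fp, tn, fn)
    structure(list(TP = tp, FP = fp, TN = tn, FN = fn, threshold = 0.5),
              class = "confusion_counts")
  expect_identical(accuracy(cc(1, 1, 1, 1)), 0.5)
  expect_identical(accuracy(cc(7, 0, 0, 0)), 1)
  expect_identical(precision(cc(3, 1, 0, 0)), 0.75)
  expect_identical(recall(cc(4, 0, 0, 1)), 0.8)
  expect_identical(proportion_classified(cc(2, 2, 4, 0)), 0.5)
  # all classifications discarded / nothing correct: explicit NA, not 0 or 1
  expect_identical(precision(cc(0, 0, 3, 2)), NA_real_)
  expect_identical(recall(cc(0, 3, 2, 0)), NA_real_)
  withr::local_seed(31)
  for (rep in 1:20) {
    q <- as.list(rpois(4, 5))
    x <- cc(q[[1]], q[[2]], q[[3]], q[[4]])
    n <- sum(unlist(q))
    if (n > 0) expect_equal(accuracy(x), (q[[1]] + q[[3]]) / n)
    if (q[[1]] + q[[2]] > 0)
      expect_equal(precision(x), q[[1]] / (q[[1]] + q[[2]]))
    if (q[[1]] + q[[4]] > 0)
      expect_equal(recall(x), q[[1]] / (q[[1]] + q[[4]]))
  }
})

test_that("sweeps reproduce per-threshold recomputation and monotonicity", {
  withr::local_seed(37)
  rv <- random_votes(120)
  sw <- threshold_sweep(rv$votes, rv$truths)
  expect_identical(sw$metrics$threshold, c(0.5, 0.6, 0.7, 0.8, 0.9))
  for (i in seq_len(nrow(sw$metrics))) {
    cc <- confusion_counts(rv$votes, rv$truths, sw$metrics$threshold[i])
    expect_identical(sw$metrics$TP[i], cc$TP)
    expect_equal(sw$metrics$accuracy[i], accuracy(cc))
    expect_equal(sw$metrics$precision[i], precision(cc))
    expect_equal(sw$metrics$recall[i], recall(cc))
    expect_equal(sw$metrics$proportion_classified[i],
                 proportion_classified(cc))
  }
  expect_true(all(diff(sw$metrics$proportion_classified) <= 0))
  expect_true(all(diff(sw$metrics$recall) <= 0))
})

test_that("a perfect unanimous vote set saturates every metric", {
  votes <- data.frame(predicted = rep("Walk", 10), prob = rep(1, 10))
  sw <- threshold_sweep(votes, rep("Walk", 10))
  expect_true(all(sw$metrics$accuracy == 1))
  expect_true(all(sw$metrics$precision == 1))
  expect_true(all(sw$metrics$recall == 1))
  expect_true(all(sw$metrics$proportion_classified == 1))
  # constant metrics have zero rank variance: correlations undefined
  expect_true(all(is.na(sw$correlations$r)))
})

test_that("sweep input validation rejects bad threshold grids", {
  votes <- data.frame(predicted = "a", prob = 1)
  expect_error(threshold_sweep(votes, "a", thresholds = c(0.9, 0.5)),
               "increasing")
  expect_error(threshold_sweep(votes, "a", thresholds = c(0.5, 1.2)),
               "\\[0, 1\\]")
  expect_error(confusion_counts(votes, c("a", "b"), 0.5), "differ")
})

test_that("spearman r is exact on monotone fixtures and symmetric cases", {
  expect_identical(spearman_rank(1:5, c(2, 4, 6, 8, 10))$r, 1)
  expect_identical(spearman_rank(1:5, c(10, 8, 6, 4, 2))$r, -1)
  withr::local_seed(41)
  for (rep in 1:10) {
    x <- runif(8)
    expect_identical(spearman_rank(x, x)$r, 1)
    expect_identical(spearman_rank(x, -x)$r, -1)
  }
  expect_true(is.na(spearman_rank(1:5, rep(3, 5))$r))
  expect_error(spearman_rank(1:4, 1:3), "equal length")
  expect_error(spearman_rank(1:2, 2:1), "at least 3")
})

test_that("spearman matches enumeration and cor.test at n = 5", {
  withr::local_seed(43)
  for (rep in 1:8) {
    x <- 1:5
    y <- if (rep <= 5) sample(10:50, 5) else sample(c(1, 1, 2, 3, 3))
    got <- spearman_rank(x, y)
    ref <- oracle_spearman(x, y)
    expect_equal(got$r, ref$r, tolerance = 1e-12)
    expect_equal(got$p, ref$p, tolerance = 1e-12)
    if (!anyDuplicated(y)) {  # tie-free: cor.test's exact test applies
      ct <- cor.test(x, y, method = "spearman", exact = TRUE)
      expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
      expect_equal(got$p, ct$p.value, tolerance = 1e-9)
    }
  }
})

test_that("large-n spearman falls back to the t approximation", {
  withr::local_seed(47)
  x <- 1:30
  y <- x + rnorm(30, sd = 8)
  got <- spearman_rank(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = FALSE))
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
  expect_gt(got$p, 0); expect_lte(got$p, 1)
})
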