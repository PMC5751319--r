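test_that("knn_predict matches exhaustive sorting and honours the tie rules", {
  train <- rbind(c(0, 0), c(1, 0), c(2, 0), c(10, 0), c(11, 0))
  y <- factor(c("a", "a", "a", "b", "b"))
  expect_equal(as.character(knn_predict(train, y, c(1.4, 0), 3)), "a")
  expect_equal(as.character(knn_predict(train, y, c(10.4, 0), 2)), "b")

  set.seed(21)
  qx <- matrix(rnorm(20, sd = 4), 10, 2)
  for (q in seq_len(10)) {
    for (k in c(1, 3, 5)) {
      expect_equal(as.character(knn_predict(train, y, qx[q, ], k)),
                   oracle_knn(train, y, qx[q, ], k))
    }
  }

  # single training sample: its label, always
  expect_equal(as.character(knn_predict(matrix(c(5, 5), 1), factor("z"),
                                        c(-3, 2), 1)), "z")
  # k = N: global majority
  expect_equal(as.character(knn_predict(train, y, c(100, 0), 5)), "a")
  # vote tie at k = 2 between one 'a' and one 'b': nearest neighbour decides
  expect_equal(as.character(knn_predict(rbind(c(0, 0), c(3, 0)),
                                        factor(c("a", "b")), c(1, 0), 2)), "a")
  expect_error(knn_predict(train, y, c(0, 0), 0), "between 1")
  expect_error(knn_predict(train, y, c(0, 0), 6), "between 1")
})

test_that("jackknife accumulates one prediction per sample and nails separated blobs", {
  d <- make_blobs(3, 5, dim = 3, separation = 30, noise_sd = 0.5, seed = 8)
  jk <- jackknife(d, s = 10, d = 2, k = 3, mode = "strict")
  expect_length(jk$predictions, 15L)
  expect_equal(sum(jk$counts$TP + jk$counts$FN), 15L)  # count conservation
  expect_equal(eval_metrics(jk$counts)$Q, 1)
  expect_equal(jk$counts$TP, unname(d$class_sizes))
})

test_that("fast-mode jackknife equals an independent loop implementation", {
  d <- make_blobs(2, 8, dim = 2, separation = 3, noise_sd = 1.5, seed = 9)
  jk <- jackknife(d, s = 1, d = 1, k = 3, mode = "fast")
  model <- fit_kda(d, s = 1, d = 1)
  proj <- kda_project(model, d$x)
  preds <- character(16)
  for (i in 1:16) {
    preds[i] <- oracle_knn(proj[-i, , drop = FALSE], d$labels[-i],
                           proj[i, ], 3)
  }
  expect_equal(as.character(jk$predictions), preds)
})

test_that("strict and fast jackknife agree when classes are well separated", {
  d <- make_blobs(2, 6, dim = 2, separation = 40, noise_sd = 0.5, seed = 10)
  strict <- jackknife(d, s = 10, d = 1, k = 3, mode = "strict")
  fast <- jackknife(d, s = 10, d = 1, k = 3, mode = "fast")
  expect_equal(as.character(strict$predictions), as.character(fast$predictions))
})

test_that("jackknife refuses folds that annihilate a class", {
  x <- rbind(matrix(rnorm(10), 5, 2), c(9, 9))
  d <- labeled_dataset(x, c(rep("a", 5), "b"))
  expect_error(jackknife(d, s = 1, d = 1, k = 2, mode = "strict"), "'b'")
})

test_that("confusion counts are consistent one-vs-rest tallies", {
  truth <- factor(c("a", "a", "a", "b", "b", "c"))
  pred <- factor(c("a", "b", "a", "b", "b", "a"), levels = c("a", "b", "c"))
  cc <- confusion_counts(truth, pred)
  expect_equal(cc$TP, c(2L, 2L, 0L))
  expect_equal(cc$FN, c(1L, 0L, 1L))
  expect_equal(cc$FP, c(1L, 1L, 0L))
  expect_true(all(cc$TP + cc$FN + cc$FP + cc$TN == 6L))
})

test_that("metrics reproduce the hand-checked confusion example", {
  cc <- structure(
    data.frame(class = "pos", TP = 8L, FN = 2L, FP = 1L, TN = 9L),
    n = 20L, class = c("confusion_counts", "data.frame")
  )
  rep <- eval_metrics(cc)
  expect_equal(rep$per_class$Sen, 0.8)
  expect_equal(rep$per_class$Spe, 0.9)
  expect_equal(rep$per_class$MCC, (8 * 9 - 2 * 1) / sqrt(10 * 9 * 10 * 11))
  expect_equal(rep$per_class$MCC, 0.7035265, tolerance = 1e-6)
  # the historical specificity variant divides by TP + FP instead
  expect_equal(eval_metrics(cc, spe_variant = "printed")$per_class$Spe, 1)
})

test_that("an error-free diagonal confusion scores 1 everywhere", {
  truth <- factor(rep(c("a", "b"), each = 4))
  rep <- eval_metrics(confusion_counts(truth, truth))
  expect_equal(rep$Q, 1)
  expect_equal(rep$per_class$Sen, c(1, 1))
  expect_equal(rep$per_class$Spe, c(1, 1))
  expect_equal(rep$per_class$MCC, c(1, 1))
})

test_that("zero-denominator classes become NA and print as '-'", {
  truth <- factor(c("a", "a", "b"), levels = c("a", "b"))
  pred <- factor(c("a", "a", "a"), levels = c("a", "b"))
  rep <- eval_metrics(confusion_counts(truth, pred))
  # class b: TP + FP = 0 -> MCC undefined
  expect_true(is.na(rep$per_class$MCC[2]))
  out <- capture.output(print(rep))
  expect_true(any(grepl("-", out[grepl(" b ", out)])))
})

test_that("overall accuracy is relabeling-invariant and equals micro accuracy", {
  set.seed(13)
  truth <- factor(sample(letters[1:3], 40, replace = TRUE))
  pred <- factor(sample(letters[1:3], 40, replace = TRUE), levels = levels(truth))
  q1 <- eval_metrics(confusion_counts(truth, pred))$Q
  expect_equal(q1, mean(truth == pred))
  relab <- c(a = "z", b = "y", c = "x")
  q2 <- eval_metrics(confusion_counts(factor(relab[as.character(truth)]),
                                      factor(relab[as.character(pred)],
                                             levels = c("x", "y", "z"))))$Q
  expect_equal(q2, q1)
})

test_that("swapping positive and negative roles swaps Sen and Spe", {
  truth <- factor(c(rep("p", 10), rep("n", 10)))
  pred <- factor(c(rep("p", 8), "n", "n", rep("n", 9), "p"),
                 levels = levels(truth))
  rep <- eval_metrics(confusion_counts(truth, pred))
  i_p <- which(rep$per_class$class == "p")
  i_n <- which(rep$per_class$class == "n")
  expect_equal(rep$per_class$Sen[i_p], rep$per_class$Spe[i_n])
  expect_equal(rep$per_class$Spe[i_p], rep$per_class$Sen[i_n])
})
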