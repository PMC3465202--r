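test_that("knn prediction matches a brute-force distance-sort oracle", {
  # 7-point 1-D toy, k = 5
  train_x <- matrix(c(0, 1, 2, 3, 10, 11, 12), ncol = 1)
  train_y <- c("A", "A", "A", "B", "B", "B", "B")
  query <- matrix(c(1.5, 9, 5.5, 100), ncol = 1)
  ds <- expression_dataset(train_x, paste0("s", 1:7), "g1", train_y)
  got <- knn_predict(ds, query, k = 5)
  expect_equal(got, oracle_knn(train_x, train_y, query, 5))

  # identity: query equal to a training sample with k = 1
  expect_equal(as.character(knn_predict(ds, matrix(10), k = 1)), "B")
  # cluster center goes to its cluster
  expect_equal(as.character(knn_predict(ds, matrix(1), k = 3)), "A")
  expect_error(knn_predict(ds, matrix(1), k = 9), "exceeds")
})

test_that("knn is invariant to constant shifts and training order", {
  ds <- tiny_dataset(m = 10, n = 3, seed = 2)
  q <- matrix(rnorm(6), 2, 3)
  base <- knn_predict(ds, q, k = 5)
  shifted <- expression_dataset(ds$values + 7, ds$sample_ids, ds$gene_ids,
                                ds$labels)
  expect_equal(knn_predict(shifted, q + 7, k = 5), base)
  perm <- c(4, 1, 9, 2, 10, 3, 8, 5, 7, 6)
  permds <- expression_dataset(ds$values[perm, ], ds$sample_ids[perm],
                               ds$gene_ids, ds$labels[perm])
  expect_equal(knn_predict(permds, q, k = 5), base)
})

test_that("cv_accuracy is 1 on separable data and near chance under the null", {
  sep <- separable_dataset()
  spec <- classifier_spec("knn", cv_folds = 4, seed = 1)
  expect_equal(cv_accuracy(sep, c("g1", "g2"), spec), 1)

  accs <- vapply(1:20, function(s) {
    ds <- genebeam:::with_seed(100 + s, {
      x <- matrix(rnorm(40 * 2), 40, 2)
      expression_dataset(x, paste0("s", 1:40), c("g1", "g2"),
                         rep(c("A", "B"), 20))
    })
    cv_accuracy(ds, c("g1", "g2"), classifier_spec("knn", seed = s))
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("2-fold knn CV equals a hand-enumerated split evaluation", {
  ds <- tiny_dataset(m = 6, n = 2, seed = 8)
  spec <- classifier_spec("knn", knn_k = 1, cv_folds = 2, seed = 4)
  fold <- make_folds(ds$labels, 2, 4)
  correct <- 0
  for (f in 1:2) {
    tr <- fold != f
    pred <- oracle_knn(ds$values[tr, , drop = FALSE],
                       as.character(ds$labels[tr]),
                       ds$values[!tr, , drop = FALSE], 1)
    correct <- correct + sum(pred == ds$labels[!tr])
  }
  expect_equal(cv_accuracy(ds, c("g1", "g2"), spec, fold = fold), correct / 6)
})

test_that("svm accuracy is the grid maximum and non-decreasing in grid size", {
  sep <- separable_dataset(m_per_class = 5)
  small <- classifier_spec("svm_rbf", C_grid = 200, gamma_grid = 0.5,
                           cv_folds = 5, seed = 2)
  big <- classifier_spec("svm_rbf", C_grid = c(200, 400),
                         gamma_grid = c(0.001, 0.5, 5), cv_folds = 5, seed = 2)
  a_small <- cv_accuracy(sep, c("g1", "g2"), small)
  a_big <- cv_accuracy(sep, c("g1", "g2"), big)
  expect_gte(a_big, a_small)
  expect_equal(a_big, 1)
})

test_that("full-fold statistics follow the mean/(m-1), std/(m-2) definitions", {
  s <- fullfold_stats(c(0.8, 0.9, 1.0))   # m = 4: CV(2), CV(3), CV(4)
  expect_equal(s$mean, 0.9)
  expect_equal(s$std, 0.1)                # sqrt((0.01 + 0 + 0.01) / 2)
  expect_equal(fullfold_stats(rep(1, 5))$std, 0)

  sep <- separable_dataset(m_per_class = 4)
  ff <- full_fold_cv(sep, c("g1", "g2"), classifier_spec("knn", knn_k = 3))
  expect_equal(length(ff$per_k), sep$m - 1)
  expect_equal(ff$mean, 1)
  expect_equal(ff$std, 0)
  expect_true(ff$mean >= min(ff$per_k) && ff$mean <= max(ff$per_k))
})

test_that("subset-size guideline gives floor(m_t / 5k) with boundary flag", {
  r <- recommended_max_subset_size(80, 2)
  expect_equal(as.integer(r), 8L)
  expect_true(attr(r, "boundary"))
  expect_equal(as.integer(recommended_max_subset_size(100, 4)), 5L)
  expect_equal(as.integer(recommended_max_subset_size(83, 2)), 8L)
  expect_false(attr(recommended_max_subset_size(83, 2), "boundary"))
  expect_error(recommended_max_subset_size(9, 2), "no admissible")
})

test_that("confusion metrics match their definitions and flag undefined rates", {
  m <- metrics_from_counts(TP = 5, TN = 5, FP = 0, FN = 0)
  expect_equal(unlist(m[c("acc", "sp", "tpr", "ppv", "npv")]),
               c(acc = 1, sp = 1, tpr = 1, ppv = 1, npv = 1))
  m2 <- metrics_from_counts(TP = 3, TN = 5, FP = 1, FN = 1)
  expect_equal(m2$acc, 0.8)
  expect_equal(m2$tpr, 0.75)
  expect_equal(m2$ppv, 0.75)
  expect_equal(m2$fpr, 1 - m2$sp)
  # acc = (tpr*P + sp*N)/(P+N)
  P <- m2$TP + m2$FN; N <- m2$TN + m2$FP
  expect_equal(m2$acc, (m2$tpr * P + m2$sp * N) / (P + N))
  m3 <- metrics_from_counts(TP = 3, TN = 0, FP = 0, FN = 1)
  expect_true(is.na(m3$sp))
  expect_error(metrics_from_counts(0, 0, 0, 0), "positive")
})

test_that("roc_auc equals pair counting and the pROC trapezoid", {
  scores <- c(0.9, 0.8, 0.8, 0.3, 0.2, 0.8)
  labels <- c("pos", "pos", "neg", "neg", "neg", "pos")
  pos <- scores[labels == "pos"]; neg <- scores[labels == "neg"]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(roc_auc(scores, labels, positive = "pos"), mean(pairs))
  expect_equal(roc_auc(c(1, 2, 3, 4), c("n", "n", "p", "p"), "p"), 1)
  expect_equal(roc_auc(rep(1, 6), rep(c("n", "p"), 3), "p"), 0.5)
  skip_if_not_installed("pROC")
  pr <- pROC::auc(pROC::roc(labels, scores, levels = c("neg", "pos"),
                            direction = "<", quiet = TRUE))
  expect_equal(roc_auc(scores, labels, positive = "pos"), as.numeric(pr))
})
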