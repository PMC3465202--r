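# Majority-voting ensemble built from the optimal gene subsets, one
# individual classifier per subset, with a vote-ratio confidence level.

#' Keep the subsets fully covered by a test platform
#'
#' Cross-platform test sets measure only part of the training platform's
#' genes; an individual classifier can only vote if every gene of its
#' subset is present. Returns the surviving subsets.
#'
#' @param opt An `optimal_subsets` collection.
#' @param test Test [expression_dataset()].
#' @return The filtered `optimal_subsets`.
#' @export
shared_subsets <- function(opt, test) {
  keep <- Filter(function(s) all(s$genes %in% test$gene_ids), opt$subsets)
  if (!length(keep))
    stop("no subset is fully covered by the test dataset; no ensemble possible")
  out <- opt
  out$subsets <- keep
  out$union_genes <- sort(unique(unlist(lapply(keep, `[[`, "genes"))))
  out
}

#' Ensemble confidence level
#'
#' The ratio of the largest to the second-largest vote count in a test
#' sample's voting vector. A unanimous vote (second-largest count 0) is
#' assigned the ensemble size N, the maximal attainable confidence, so
#' conf always lies in `[1, N]`.
#'
#' @param counts Non-negative per-class vote counts.
#' @param N Total number of voting classifiers; must equal `sum(counts)`.
#' @return The confidence level (report layers render it to 4 decimals).
#' @examples
#' confidence(c(116, 184), 300)   # 1.5862...
#' confidence(c(297, 3), 300)     # 99
#' confidence(c(300, 0), 300)     # 300 (unanimous)
#' @export
confidence <- function(counts, N = sum(counts)) {
  if (any(counts < 0)) stop("vote counts must be non-negative")
  if (sum(counts) != N) stop("vote counts must sum to N")
  if (N < 1) stop("N must be >= 1")
  s <- sort(counts, decreasing = TRUE)
  m_max <- s[1]
  m_sec <- if (length(s) > 1) s[2] else 0
  if (m_sec == 0) N else m_max / m_sec
}

# Train one SVM classifier on a subset and predict the test samples,
# selecting (C, gamma) per the requested mode. Returns the factor of
# predictions.
svm_subset_predict <- function(train, test, genes, spec, mode) {
  xtr <- train$values[, genes, drop = FALSE]
  xte <- test$values[, genes, drop = FALSE]
  fold <- make_folds(train$labels, min(spec$cv_folds, train$m), spec$seed)
  grid <- expand.grid(gamma = sort(spec$gamma_grid), C = sort(spec$C_grid))
  cvacc <- vapply(seq_len(nrow(grid)), function(i) {
    svm_cv_one(xtr, train$labels, fold, grid$C[i], grid$gamma[i],
               spec$normalize == "per_fold")
  }, numeric(1))
  best <- which(cvacc == max(cvacc))   # grid order: gamma asc, then C asc
  if (mode == "unbiased" || length(best) == 1L) {
    pick <- best[1L]
    return(svm_fit_predict(xtr, train$labels, xte, grid$C[pick],
                           grid$gamma[pick]))
  }
  # biased: among the training-CV-optimal ties, take the pair with the
  # highest test accuracy
  preds <- lapply(best, function(i)
    svm_fit_predict(xtr, train$labels, xte, grid$C[i], grid$gamma[i]))
  testacc <- vapply(preds, function(p) mean(p == test$labels), numeric(1))
  preds[[which.max(testacc)]]
}

#' Majority-voting ensemble prediction
#'
#' Builds one individual classifier per optimal gene subset (each trained
#' on the full training set restricted to that subset), lets every
#' classifier vote on every test sample, and predicts by simple majority.
#' Vote ties go to the class listed first in the label set, with the
#' confidence recorded as 1 (an explicit low-confidence flag).
#'
#' For the SVM, `mode = "unbiased"` picks each classifier's (C, gamma) by
#' training-set CV with the deterministic grid-order tie-break — the honest
#' generalization estimate. `mode = "biased"` additionally breaks
#' training-CV ties by test accuracy; its accuracy is optimistic by
#' construction and all outputs label it as biased. k-NN has no such
#' hyperparameter feedback, so only `"unbiased"` applies.
#'
#' @param train,test Train and test [expression_dataset()]s sharing the
#'   subsets' genes (apply [shared_subsets()] / [align_cross_platform()]
#'   first for cross-platform pairs).
#' @param opt An `optimal_subsets` collection (already filtered to subsets
#'   covered by `test`).
#' @param spec A [classifier_spec()].
#' @param mode `"unbiased"` (default) or `"biased"` (SVM only).
#' @return An `ensemble_result`: list with `per_sample` (data.frame:
#'   sample_id, one vote column per class, conf, predicted, true, correct),
#'   `accuracy` (voted), `individual_acc` (each member classifier's test
#'   accuracy), `mode`, `n_classifiers`.
#' @export
ensemble_predict <- function(train, test, opt, spec,
                             mode = c("unbiased", "biased")) {
  mode <- match.arg(mode)
  if (mode == "biased" && spec$kind == "knn")
    stop("biased mode is an SVM hyperparameter phenomenon; k-NN has no grid")
  subs <- opt$subsets
  if (!length(subs)) stop("no subsets to build an ensemble from")
  for (s in subs) {
    if (!all(s$genes %in% train$gene_ids) || !all(s$genes %in% test$gene_ids))
      stop("subset gene(s) missing from train or test; run shared_subsets()")
  }
  N <- length(subs)
  lev <- levels(train$labels)
  votes <- matrix(0L, nrow = test$m, ncol = length(lev),
                  dimnames = list(test$sample_ids, lev))
  individual_acc <- numeric(N)
  for (si in seq_len(N)) {
    s <- subs[[si]]
    pred <- if (spec$kind == "knn") {
      knn_predict(restrict_genes(train, s$genes),
                  test$values[, s$genes, drop = FALSE], spec$knn_k)
    } else {
      svm_subset_predict(train, test, s$genes, spec, mode)
    }
    individual_acc[si] <- mean(pred == test$labels)
    pi <- match(as.character(pred), lev)
    votes[cbind(seq_len(test$m), pi)] <- votes[cbind(seq_len(test$m), pi)] + 1L
  }
  predicted <- character(test$m)
  conf <- numeric(test$m)
  for (i in seq_len(test$m)) {
    v <- votes[i, ]
    top <- which(v == max(v))
    if (length(top) > 1L) {           # tie: first class in label order
      predicted[i] <- lev[top[1L]]
      conf[i] <- 1
    } else {
      predicted[i] <- lev[top]
      conf[i] <- confidence(v, N)
    }
  }
  true <- as.character(test$labels)
  correct <- predicted == true
  per_sample <- data.frame(sample_id = test$sample_ids, votes,
                           conf = conf, predicted = predicted, true = true,
                           correct = correct,
                           check.names = FALSE, stringsAsFactors = FALSE)
  structure(list(per_sample = per_sample, accuracy = mean(correct),
                 individual_acc = individual_acc,
                 mode = mode, n_classifiers = N),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("ensemble_result (", x$mode, "): ", x$n_classifiers,
      " classifiers, accuracy ",
      sprintf("%.2f%%", 100 * x$accuracy), "\n", sep = "")
  invisible(x)
}

#' Write a per-sample ensemble report
#'
#' TSV with one row per test sample: sample id, per-class vote counts,
#' confidence (4 decimals), predicted and true class, and C/E for
#' correct/error.
#'
#' @param res An `ensemble_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ensemble_report <- function(res, path) {
  ps <- res$per_sample
  ps$conf <- sprintf("%.4f", ps$conf)
  ps$correct <- ifelse(ps$correct, "C", "E")
  utils::write.table(ps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
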