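# Wrapped classifiers and cross-validation statistics.
#
# Accuracies are stored as fractions in [0, 1] throughout; report/CLI layers
# render percentages.

#' Classifier specification
#'
#' Bundles the wrapped-classifier settings used to score gene subsets:
#' either Euclidean 5-NN or an RBF-kernel SVM whose accuracy is the maximum
#' over a (C, gamma) grid, both evaluated by seeded stratified k-fold
#' cross-validation.
#'
#' The default SVM grid is C in \{200, 400\} and gamma in
#' \{a x 10^e : a = 1..9, e = -5..-1\} united with \{1, ..., 10\}; grid ties
#' are broken by grid order (gamma ascending, then C ascending).
#'
#' @param kind `"knn"` or `"svm_rbf"`.
#' @param knn_k Odd positive neighbor count (odd avoids tied binary votes).
#' @param C_grid,gamma_grid Positive numeric grids for the SVM.
#' @param cv_folds Number of CV folds (default 10).
#' @param seed Integer seed that fixes the fold partition.
#' @param normalize `"none"` (data are assumed normalized once up front,
#'   matching per-evaluation z-scoring of the restricted gene block since
#'   column z-scoring commutes with column subsetting) or `"per_fold"`
#'   (leakage-safe: each fold's training statistics are applied to its test
#'   block).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("knn", "svm_rbf"),
                            knn_k = 5,
                            C_grid = c(200, 400),
                            gamma_grid = default_gamma_grid(),
                            cv_folds = 10,
                            seed = 1,
                            normalize = c("none", "per_fold")) {
  kind <- match.arg(kind)
  normalize <- match.arg(normalize)
  if (knn_k < 1 || knn_k %% 2 == 0) stop("knn_k must be an odd positive integer")
  if (any(C_grid <= 0) || any(gamma_grid <= 0))
    stop("SVM grid values must be positive")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  structure(list(kind = kind, knn_k = as.integer(knn_k),
                 C_grid = as.numeric(C_grid),
                 gamma_grid = as.numeric(gamma_grid),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 normalize = normalize),
            class = "classifier_spec")
}

#' @rdname classifier_spec
#' @export
default_gamma_grid <- function() {
  c(as.vector(outer(1:9, 10^(-5:-1))), 1:10)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Stratified cross-validation folds
#'
#' Assigns each sample a fold in 1..nfolds, stratified by class: within each
#' class the samples are shuffled (deterministically from `seed`) and dealt
#' round-robin, so fold class proportions match the data as closely as
#' integer counts allow.
#'
#' @param labels Factor (or vector) of class labels.
#' @param nfolds Number of folds, between 2 and `length(labels)`.
#' @param seed Integer seed.
#' @return Integer vector of fold assignments.
#' @export
make_folds <- function(labels, nfolds, seed) {
  labels <- factor(labels)
  m <- length(labels)
  if (nfolds < 2 || nfolds > m) stop("nfolds must be in [2, m]")
  fold <- integer(m)
  with_seed(seed, {
    offset <- 0L
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      # continue the round-robin across classes so fold sizes stay balanced
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% nfolds) + 1L
      offset <- offset + length(idx)
    }
  })
  fold
}

# Internal matrix k-NN with the deterministic tie rule: majority vote;
# multi-class vote ties go to the class of the nearest neighbor among the
# tied classes.
knn_predict_matrix <- function(train_x, train_y, query_x, k) {
  train_y <- factor(train_y)
  nl <- nlevels(train_y)
  yi <- as.integer(train_y)
  out <- integer(nrow(query_x))
  for (q in seq_len(nrow(query_x))) {
    d2 <- colSums((t(train_x) - query_x[q, ])^2)
    nb <- order(d2, seq_along(d2))[seq_len(k)]
    votes <- tabulate(yi[nb], nbins = nl)
    top <- which(votes == max(votes))
    if (length(top) == 1L) {
      out[q] <- top
    } else {
      out[q] <- yi[nb[which(yi[nb] %in% top)[1L]]]
    }
  }
  factor(levels(train_y)[out], levels = levels(train_y))
}

#' k-nearest-neighbor prediction
#'
#' Euclidean-distance majority-vote k-NN. Multi-class vote ties are broken
#' deterministically by the class of the nearest neighbor among the tied
#' classes (for binary problems an odd `k` never ties).
#'
#' @param train An [expression_dataset()] (typically restricted to a gene
#'   subset).
#' @param query Numeric matrix of query samples (columns in `train`'s gene
#'   order), or an `expression_dataset` sharing `train`'s genes.
#' @param k Odd neighbor count, at most the training-sample count.
#' @return Factor of predicted labels, levels as in `train$labels`.
#' @export
knn_predict <- function(train, query, k = 5) {
  if (inherits(query, "expression_dataset"))
    query <- query$values[, train$gene_ids, drop = FALSE]
  query <- matrix(as.numeric(query), ncol = train$n)
  if (k > train$m) stop("k exceeds the number of training samples")
  knn_predict_matrix(train$values, train$labels, query, k)
}

# Pooled CV accuracy for k-NN from a precomputed squared-distance matrix.
knn_cv_from_d2 <- function(d2, labels, fold, k) {
  knn_cv_acc_cpp(d2, as.integer(labels) - 1L, as.integer(fold),
                 as.integer(k), nlevels(labels))
}

svm_fit_predict <- function(train_x, train_y, test_x, cost, gamma) {
  fit <- e1071::svm(train_x, train_y, type = "C-classification",
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  stats::predict(fit, test_x)
}

# Pooled CV accuracy over folds for one (C, gamma) pair.
svm_cv_one <- function(x, y, fold, cost, gamma, per_fold_norm) {
  correct <- 0L
  for (f in sort(unique(fold))) {
    tr <- fold != f
    xtr <- x[tr, , drop = FALSE]; xte <- x[!tr, , drop = FALSE]
    if (per_fold_norm) {
      sc <- zscore_train_stats(xtr)
      xtr <- sc$apply(xtr); xte <- sc$apply(xte)
    }
    if (nlevels(droplevels(y[tr])) < 2) next
    pred <- svm_fit_predict(xtr, y[tr], xte, cost, gamma)
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

zscore_train_stats <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(apply = function(z) sweep(sweep(z, 2, mu, "-"), 2, sdv, "/"))
}

#' Cross-validated accuracy of a gene subset
#'
#' The wrapper objective Acc(T): stratified k-fold CV accuracy of the
#' configured classifier on the dataset restricted to `genes`, pooled over
#' folds (fraction of all samples predicted correctly out-of-fold). For the
#' RBF SVM the returned accuracy is the maximum over the (C, gamma) grid.
#'
#' @param ds An [expression_dataset()] (normalized by the caller unless
#'   `spec$normalize = "per_fold"`).
#' @param genes Character vector of gene ids defining the subset T.
#' @param spec A [classifier_spec()].
#' @param fold Optional precomputed fold assignment (integer vector as from
#'   [make_folds()]); by default folds are drawn from `spec$seed`.
#' @return Accuracy fraction in `[0, 1]`.
#' @export
cv_accuracy <- function(ds, genes, spec, fold = NULL) {
  sub <- restrict_genes(ds, genes)
  if (is.null(fold)) fold <- make_folds(sub$labels, spec$cv_folds, spec$seed)
  if (spec$kind == "knn") {
    if (spec$normalize == "per_fold") {
      correct <- 0L
      for (f in sort(unique(fold))) {
        tr <- fold != f
        sc <- zscore_train_stats(sub$values[tr, , drop = FALSE])
        pred <- knn_predict_matrix(sc$apply(sub$values[tr, , drop = FALSE]),
                                  sub$labels[tr],
                                  sc$apply(sub$values[!tr, , drop = FALSE]),
                                  spec$knn_k)
        correct <- correct + sum(pred == sub$labels[!tr])
      }
      return(correct / sub$m)
    }
    d2 <- as.matrix(stats::dist(sub$values))^2
    return(knn_cv_from_d2(d2, sub$labels, fold, spec$knn_k))
  }
  # svm_rbf: maximum over the grid, gamma ascending then C ascending
  best <- 0
  for (cost in sort(spec$C_grid)) for (g in sort(spec$gamma_grid)) {
    a <- svm_cv_one(sub$values, sub$labels, fold, cost, g,
                    spec$normalize == "per_fold")
    if (a > best) best <- a
  }
  best
}

#' Full-fold cross-validation
#'
#' Runs k-fold CV for every fold count k = 2..m (k = m is LOOCV) and
#' summarizes the accuracy sequence CV(k) by its mean
#' (sum of CV(k) over k, divided by m - 1) and standard deviation
#' (denominator m - 2). A subset that scores well across all fold counts is
#' robust to the bias/variance trade-off of any single k.
#'
#' @inheritParams cv_accuracy
#' @return A `fullfold_result`: list with `per_k` (named accuracy vector for
#'   k = 2..m), `mean`, `std`.
#' @export
full_fold_cv <- function(ds, genes, spec) {
  if (ds$m < 3) stop("Full-fold CV needs at least 3 samples")
  ks <- 2:ds$m
  per_k <- vapply(ks, function(k) {
    sp <- spec; sp$cv_folds <- as.integer(k)
    cv_accuracy(ds, genes, sp)
  }, numeric(1))
  names(per_k) <- ks
  c(list(per_k = per_k), fullfold_stats(per_k)) |>
    structure(class = "fullfold_result")
}

#' Full-fold summary statistics
#'
#' Aggregates a CV(k) accuracy sequence for k = 2..m: mean over the m - 1
#' values and standard deviation with denominator m - 2.
#'
#' @param per_k Numeric vector of CV(k) accuracies, k = 2..m (length m - 1).
#' @return List with `mean` and `std`.
#' @export
fullfold_stats <- function(per_k) {
  if (length(per_k) < 2) stop("need CV(k) for at least k = 2, 3")
  list(mean = mean(per_k), std = stats::sd(per_k))
}

#' Sample-size guideline for the maximal subset size
#'
#' The design guideline that the per-class training-sample count should be
#' more than five times the feature count gives the largest admissible gene
#' subset size floor(m_t / (5 k)). When m_t / (5 k) is an exact integer the
#' value sits on the guideline boundary and is flagged via the `"boundary"`
#' attribute. E.g. 80 training samples in 2 classes admit at most 8 genes.
#'
#' @param m_t Training-sample count.
#' @param k Class count.
#' @return Integer subset-size bound with logical attribute `"boundary"`.
#' @export
recommended_max_subset_size <- function(m_t, k) {
  if (m_t < 5 * k)
    stop("no admissible subset size: m_t must be at least 5 * k")
  n_s <- m_t %/% (5 * k)
  structure(as.integer(n_s), boundary = (m_t %% (5 * k)) == 0)
}

#' Confusion-matrix performance metrics
#'
#' Computes accuracy, specificity, sensitivity (TPR), FPR, PPV and NPV from
#' binary confusion counts. A rate whose denominator is zero is reported as
#' `NA` (undefined), never as 0.
#'
#' @param TP,TN,FP,FN Non-negative integer counts; their total must be > 0.
#' @return A `metric_set` list with the counts and the six rates.
#' @export
metrics_from_counts <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("at least one count must be positive")
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  sp <- rate(TN, FP + TN)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 acc = (TP + TN) / total,
                 sp = sp,
                 tpr = rate(TP, TP + FN),
                 fpr = if (is.na(sp)) NA_real_ else 1 - sp,
                 ppv = rate(TP, TP + FP),
                 npv = rate(TN, TN + FN)),
            class = "metric_set")
}

#' Area under the ROC curve
#'
#' AUC as the probability that a positive sample outscores a negative one,
#' ties counted one half (midrank convention); identical to the trapezoidal
#' area under the TPR-vs-FPR curve.
#'
#' @param scores Numeric per-sample scores (larger = more positive).
#' @param labels Binary labels; `positive` names the positive class
#'   (default: the second factor level).
#' @param positive Value of `labels` treated as positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must contain exactly two classes")
  if (is.null(positive)) positive <- levels(labels)[2]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)   # midranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
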