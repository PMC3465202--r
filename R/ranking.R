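# Occurrence-frequency gene ranking across optimal subsets, top-k accuracy
# curves, and the power-law (log-log) diagnostic.

#' Gene occurrence-frequency table
#'
#' Counts how many optimal subsets each gene appears in, accumulated over
#' all supplied search runs (a subset contributes once per run it appears
#' in). A gene's frequency measures its importance: genes recurring across
#' many minimal high-accuracy subsets are the strongest tumor-marker
#' candidates. Ties are broken by ascending Kruskal-Wallis p-value (when a
#' ranking is supplied), then by gene id.
#'
#' @param runs A single `optimal_subsets` or a list of them.
#' @param ranking Optional `gene_ranking` used for the tie-break.
#' @return A `frequency_table` data.frame: `rank`, `gene_id`, `count`,
#'   `kwrst_p` (NA when no ranking given), ordered by descending count.
#' @export
gene_frequency <- function(runs, ranking = NULL) {
  if (inherits(runs, "optimal_subsets")) runs <- list(runs)
  if (!length(runs)) stop("runs must be non-empty")
  all_genes <- unlist(lapply(runs, function(r)
    unlist(lapply(r$subsets, `[[`, "genes"))))
  tab <- table(all_genes)
  gene_id <- names(tab)
  count <- as.integer(tab)
  p <- if (is.null(ranking)) rep(NA_real_, length(gene_id)) else {
    ranking$pvalues[match(gene_id, ranking$gene_ids)]
  }
  ord <- order(-count, p, gene_id)
  out <- data.frame(rank = seq_along(gene_id),
                    gene_id = gene_id[ord], count = count[ord],
                    kwrst_p = p[ord], stringsAsFactors = FALSE)
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Top-ranked genes from a frequency table
#'
#' @param ft A `frequency_table` from [gene_frequency()].
#' @param n Number of genes, at most the number of distinct genes listed.
#' @return Character vector of the first `n` gene ids in table order.
#' @export
top_genes <- function(ft, n) {
  if (n < 1 || n > nrow(ft))
    stop("n must be between 1 and the number of distinct genes (", nrow(ft), ")")
  ft$gene_id[seq_len(n)]
}

#' Prediction accuracy versus number of top-ranked genes
#'
#' For each k, trains the configured classifier on the top-k
#' frequency-ranked genes and evaluates accuracy on the test set. A gene
#' absent from the test platform is skipped and the next-ranked gene
#' substituted (the cross-platform convention); substitutions are recorded
#' in the result.
#'
#' @param train,test Train/test [expression_dataset()]s.
#' @param ft A `frequency_table`.
#' @param spec A [classifier_spec()].
#' @param ks Positive integers; each at most the number of table genes
#'   present in both datasets.
#' @return A data.frame with columns `k`, `accuracy`, plus attribute
#'   `"skipped"` (genes absent from the test set).
#' @export
accuracy_vs_topk <- function(train, test, ft, spec, ks) {
  if (any(ks < 1)) stop("k must be >= 1 (an empty feature set is not a classifier)")
  usable <- ft$gene_id[ft$gene_id %in% train$gene_ids &
                       ft$gene_id %in% test$gene_ids]
  skipped <- setdiff(ft$gene_id, usable)
  if (!length(usable)) stop("no table gene is present in both datasets")
  if (max(ks) > length(usable))
    stop("max(ks) exceeds the ", length(usable),
         " ranked genes present in both datasets")
  acc <- vapply(ks, function(k) {
    genes <- usable[seq_len(k)]
    pred <- if (spec$kind == "knn") {
      knn_predict(restrict_genes(train, genes),
                  test$values[, genes, drop = FALSE], spec$knn_k)
    } else {
      svm_subset_predict(train, test, genes, spec, mode = "unbiased")
    }
    mean(pred == test$labels)
  }, numeric(1))
  out <- data.frame(k = ks, accuracy = acc)
  attr(out, "skipped") <- skipped
  out
}

#' Power-law diagnostic of a frequency table
#'
#' Ordinary least squares of log(frequency) on log(rank), rank = 1..n in
#' table order. A near-linear log-log relationship (r-squared close to 1)
#' indicates the occurrence frequencies follow a power law
#' frequency ~ rank^slope — few genes dominate the optimal subsets.
#'
#' @param ft A `frequency_table` with at least 3 genes of positive count.
#' @return A `powerlaw_fit` list: `slope`, `intercept`, `r2`.
#' @export
powerlaw_fit <- function(ft) {
  pos <- ft$count > 0
  if (sum(pos) < 3) stop("need at least 3 genes with positive frequency")
  lx <- log(ft$rank[pos])
  ly <- log(ft$count[pos])
  fit <- stats::lm(ly ~ lx)
  sstot <- sum((ly - mean(ly))^2)
  r2 <- if (sstot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sstot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("powerlaw_fit: slope %.4f, intercept %.4f, r2 %.4f\n",
              x$slope, x$intercept, x$r2))
  invisible(x)
}

#' Write a frequency table as TSV
#'
#' Columns `rank`, `gene_id`, `count`, `kwrst_p`.
#'
#' @param ft A `frequency_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_frequency <- function(ft, path) {
  utils::write.table(ft, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
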