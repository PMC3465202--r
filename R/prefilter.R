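#' Kruskal-Wallis gene ranking
#'
#' Scores every gene with the tie-corrected Kruskal-Wallis rank sum test
#' across the dataset's classes and returns the genes ranked by ascending
#' p-value. The test is nonparametric and valid for any number of classes
#' (for two classes it is equivalent to the two-sided normal-approximation
#' Wilcoxon rank-sum test). A gene constant across all samples carries no
#' rank information and is assigned p = 1.
#'
#' @param ds An [expression_dataset()] with k >= 2 classes, each non-empty.
#' @return An object of class `gene_ranking`: list with `gene_ids`,
#'   `pvalues`, `statistic` (the H statistics) and `order` (permutation
#'   sorting p ascending, ties broken by original column index).
#' @export
kwrst_pvalues <- function(ds) {
  if (ds$k < 2) stop("need at least 2 classes")
  g <- ds$labels
  n <- ds$n
  p <- numeric(n)
  h <- numeric(n)
  for (j in seq_len(n)) {
    x <- ds$values[, j]
    if (max(x) == min(x)) {           # constant gene: no separation
      h[j] <- 0; p[j] <- 1
    } else {
      kt <- stats::kruskal.test(x, g)
      h[j] <- unname(kt$statistic)
      p[j] <- kt$p.value
    }
  }
  ord <- order(p, seq_len(n))
  structure(list(gene_ids = ds$gene_ids, pvalues = p, statistic = h,
                 order = ord),
            class = "gene_ranking")
}

#' @export
print.gene_ranking <- function(x, ...) {
  cat("gene_ranking over", length(x$gene_ids), "genes; best p =",
      format(min(x$pvalues), digits = 4), "\n")
  invisible(x)
}

#' Pre-select the top-ranked genes
#'
#' Returns the `p` genes with the smallest Kruskal-Wallis p-values, the
#' candidate pool for the beam search. Ties are broken by original column
#' index, so the selection is deterministic.
#'
#' @param ranking A `gene_ranking` from [kwrst_pvalues()].
#' @param p Number of genes to keep (default 300).
#' @return Character vector of `p` gene ids, ordered by ascending p-value.
#' @export
preselect <- function(ranking, p = 300) {
  n <- length(ranking$gene_ids)
  if (p < 1 || p > n)
    stop("p must be between 1 and the number of genes (", n, ")")
  ranking$gene_ids[ranking$order[seq_len(p)]]
}

# Position (1 = best) of each gene id in the ranking; used by the search
# tie-break. Genes absent from the ranking get rank Inf.
kwrst_rank_of <- function(ranking, gene_ids) {
  pos <- match(gene_ids, ranking$gene_ids[ranking$order])
  pos[is.na(pos)] <- Inf
  pos
}

#' Write a gene ranking as a two-column TSV
#'
#' @param ranking A `gene_ranking`.
#' @param path Output path; columns `gene_id`, `pvalue`, sorted ascending.
#' @param top Optional number of top genes to write (default all).
#' @return Invisibly, `path`.
#' @export
write_ranking <- function(ranking, path, top = NULL) {
  ord <- ranking$order
  if (!is.null(top)) ord <- ord[seq_len(min(top, length(ord)))]
  writeLines(c("gene_id\tpvalue",
               paste(ranking$gene_ids[ord],
                     formatC(ranking$pvalues[ord], digits = 17, format = "g"),
                     sep = "\t")),
             path)
  invisible(path)
}
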