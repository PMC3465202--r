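#' Labeled expression dataset
#'
#' Container for a samples x genes expression matrix with per-sample class
#' labels. Rows are samples, columns are genes (the in-memory orientation;
#' on-disk TSVs use the microarray genes-as-rows convention, see
#' [read_expression()]).
#'
#' @param values Numeric matrix, m samples x n genes, all values finite.
#' @param sample_ids Character vector of m unique sample identifiers.
#' @param gene_ids Character vector of n unique gene identifiers.
#' @param labels Character (or factor) vector of m class labels; every class
#'   must have at least one sample and there must be at least two classes for
#'   downstream classification (a single-class dataset is permitted at
#'   construction for plumbing, but rejected by the test and search
#'   functions).
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `sample_ids`, `gene_ids`, `labels` (factor) and the derived
#'   sizes `m`, `n`, `k`.
#' @examples
#' x <- matrix(rnorm(12), 4, 3)
#' ds <- expression_dataset(x, paste0("s", 1:4), paste0("g", 1:3),
#'                          c("A", "A", "B", "B"))
#' ds$m; ds$n; ds$k
#' @export
expression_dataset <- function(values, sample_ids, gene_ids, labels) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(values) != length(sample_ids))
    stop("number of matrix rows (", nrow(values), ") != number of sample ids (",
         length(sample_ids), ")")
  if (ncol(values) != length(gene_ids))
    stop("number of matrix columns (", ncol(values), ") != number of gene ids (",
         length(gene_ids), ")")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  if (length(labels) != length(sample_ids))
    stop("labels length != number of samples")
  if (anyNA(labels)) stop("every sample must have a non-missing label")
  labels <- factor(as.character(labels))
  if (any(tabulate(labels, nbins = nlevels(labels)) == 0))
    stop("every class must have at least one sample")
  rownames(values) <- sample_ids
  colnames(values) <- gene_ids
  structure(
    list(values = values, sample_ids = sample_ids, gene_ids = gene_ids,
         labels = labels, m = nrow(values), n = ncol(values),
         k = nlevels(labels)),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset: ", x$m, " samples x ", x$n, " genes, ",
      x$k, " classes (", paste(levels(x$labels), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Restrict a dataset to a gene subset
#'
#' @param ds An [expression_dataset()].
#' @param genes Character vector of gene ids, all present in `ds`.
#' @return The dataset restricted to `genes`, in the order given.
#' @export
restrict_genes <- function(ds, genes) {
  genes <- as.character(genes)
  missing <- setdiff(genes, ds$gene_ids)
  if (length(missing))
    stop("unknown gene id(s): ", paste(missing, collapse = ", "))
  expression_dataset(ds$values[, genes, drop = FALSE], ds$sample_ids,
                     genes, ds$labels)
}

#' Read an expression matrix and its labels from TSV files
#'
#' The expression file is genes-as-rows: first column `gene_id`, header row of
#' sample ids. The labels file has two columns, `sample_id` and `class`.
#' Labels are matched to samples by id, not by file order.
#'
#' @param path Path to the expression TSV.
#' @param labels_path Path to the labels TSV.
#' @return An [expression_dataset()] with samples as rows.
#' @export
read_expression <- function(path, labels_path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2) stop("expression file needs a gene_id column and >= 1 sample")
  gene_ids <- tab[[1L]]
  sample_ids <- colnames(tab)[-1L]
  vals <- matrix(NA_real_, nrow = length(gene_ids), ncol = length(sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(tab[[j + 1L]]))
    bad <- which(is.na(v) & !is.na(tab[[j + 1L]]))
    if (length(bad))
      stop("non-numeric value '", tab[[j + 1L]][bad[1L]], "' at gene '",
           gene_ids[bad[1L]], "', sample '", sample_ids[j], "'")
    vals[, j] <- v
  }
  lab <- utils::read.delim(labels_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(lab) < 2) stop("labels file needs columns sample_id, class")
  lab_ids <- lab[[1L]]
  if (anyDuplicated(lab_ids))
    stop("duplicate sample ids in labels file")
  missing_lab <- setdiff(sample_ids, lab_ids)
  if (length(missing_lab))
    stop("sample(s) missing from labels file: ",
         paste(missing_lab, collapse = ", "))
  extra_lab <- setdiff(lab_ids, sample_ids)
  if (length(extra_lab))
    stop("sample(s) in labels file but not in expression file: ",
         paste(extra_lab, collapse = ", "))
  labels <- lab[[2L]][match(sample_ids, lab_ids)]
  expression_dataset(t(vals), sample_ids, gene_ids, labels)
}

#' Write an expression dataset to TSV files
#'
#' Inverse of [read_expression()]: genes-as-rows expression TSV plus a
#' two-column labels TSV. Values are written with 17 significant digits so a
#' read/write round trip is lossless for doubles.
#'
#' @param ds An [expression_dataset()].
#' @param path Output path for the expression TSV.
#' @param labels_path Output path for the labels TSV.
#' @return Invisibly, `c(path, labels_path)`.
#' @export
write_expression <- function(ds, path, labels_path) {
  vals <- t(ds$values)                      # genes as rows on disk
  lines <- c(
    paste(c("gene_id", ds$sample_ids), collapse = "\t"),
    vapply(seq_len(nrow(vals)), function(i) {
      paste(c(ds$gene_ids[i],
              formatC(vals[i, ], digits = 17, format = "g")),
            collapse = "\t")
    }, character(1)))
  writeLines(lines, path)
  writeLines(c("sample_id\tclass",
               paste(ds$sample_ids, as.character(ds$labels), sep = "\t")),
             labels_path)
  invisible(c(path, labels_path))
}

#' Per-gene z-score normalization
#'
#' Centers and scales each gene column to sample mean 0 and standard
#' deviation 1 (denominator m - 1). Constant columns become all zeros.
#'
#' @param ds An [expression_dataset()] with m >= 2 samples.
#' @return The normalized dataset.
#' @export
zscore_normalize <- function(ds) {
  if (ds$m < 2) stop("z-score normalization needs at least 2 samples")
  mu <- colMeans(ds$values)
  sdv <- apply(ds$values, 2, stats::sd)
  out <- sweep(ds$values, 2, mu, "-")
  pos <- sdv > 0
  out[, pos] <- sweep(out[, pos, drop = FALSE], 2, sdv[pos], "/")
  out[, !pos] <- 0
  expression_dataset(out, ds$sample_ids, ds$gene_ids, ds$labels)
}

#' Per-gene 0-1 (min-max) normalization
#'
#' Maps each gene column to `[0, 1]` via (x - min) / (max - min). Constant
#' columns map to 0.5.
#'
#' @inheritParams zscore_normalize
#' @return The normalized dataset.
#' @export
minmax_normalize <- function(ds) {
  if (ds$m < 2) stop("min-max normalization needs at least 2 samples")
  lo <- apply(ds$values, 2, min)
  hi <- apply(ds$values, 2, max)
  rng <- hi - lo
  out <- sweep(ds$values, 2, lo, "-")
  pos <- rng > 0
  out[, pos] <- sweep(out[, pos, drop = FALSE], 2, rng[pos], "/")
  out[, !pos] <- 0.5
  expression_dataset(out, ds$sample_ids, ds$gene_ids, ds$labels)
}

#' Align a cross-platform dataset pair on shared genes
#'
#' Restricts both datasets to the intersection of their gene ids, in
#' identical (lexicographic) column order, so a classifier trained on one
#' platform can be applied to the other.
#'
#' @param train,test Two [expression_dataset()] objects.
#' @return A list with elements `train`, `test` (the aligned datasets) and
#'   `n_shared` (the shared-gene count).
#' @export
align_cross_platform <- function(train, test) {
  shared <- sort(intersect(train$gene_ids, test$gene_ids))
  if (!length(shared))
    stop("no shared genes between the two datasets")
  list(train = restrict_genes(train, shared),
       test = restrict_genes(test, shared),
       n_shared = length(shared))
}
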