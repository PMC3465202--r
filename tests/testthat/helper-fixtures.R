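# Small programmatic fixtures shared across test files.

# A tiny deterministic dataset: m samples, n genes, 2 classes.
tiny_dataset <- function(m = 6, n = 4, seed = 42) {
  genebeam:::with_seed(seed, {
    x <- matrix(rnorm(m * n), m, n)
    expression_dataset(x, paste0("s", seq_len(m)), paste0("g", seq_len(n)),
                       rep(c("A", "B"), length.out = m))
  })
}

# Two well-separated classes on every gene: any subset classifies perfectly.
separable_dataset <- function(m_per_class = 6, n = 3, gap = 10, seed = 1) {
  genebeam:::with_seed(seed, {
    m <- 2 * m_per_class
    x <- matrix(rnorm(m * n, sd = 0.1), m, n)
    x[seq_len(m_per_class), ] <- x[seq_len(m_per_class), ] + gap
    expression_dataset(x, paste0("s", seq_len(m)), paste0("g", seq_len(n)),
                       rep(c("pos", "neg"), each = m_per_class))
  })
}

# Independent brute-force k-NN: full distance sort per query.
oracle_knn <- function(train_x, train_y, query_x, k) {
  train_y <- factor(train_y)
  out <- character(nrow(query_x))
  for (q in seq_len(nrow(query_x))) {
    d <- sqrt(colSums((t(train_x) - query_x[q, ])^2))
    nb <- order(d, seq_along(d))[seq_len(k)]
    tab <- table(train_y[nb])
    top <- names(tab)[tab == max(tab)]
    out[q] <- if (length(top) == 1) top else
      as.character(train_y[nb[which(as.character(train_y[nb]) %in% top)[1]]])
  }
  factor(out, levels = levels(train_y))
}

# Exhaustively score every size-`size` subset of `genes` with cv_accuracy.
oracle_exhaustive <- function(ds, genes, size, spec, fold) {
  combos <- utils::combn(genes, size, simplify = FALSE)
  vapply(combos, function(g) cv_accuracy(ds, g, spec, fold = fold), numeric(1))
}

# Exact hypergeometric tail by enumerating all K-subsets of the universe.
oracle_hyper <- function(N, M, K, x, tail = "upper") {
  idx <- seq_len(N)
  inpath <- idx <= M
  combos <- utils::combn(N, K, simplify = FALSE)
  hits <- vapply(combos, function(cc) sum(inpath[cc]), integer(1))
  if (tail == "lower") mean(hits <= x) else mean(hits >= x)
}
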