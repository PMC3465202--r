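# Seeded synthetic expression data with planted class-informative genes,
# noise genes, optional correlated blocks, and cross-platform companions.
# Stands in for real microarray cohorts so every stage of the pipeline is
# testable with known ground truth.

#' Simulation configuration
#'
#' Gaussian class-conditional expression model: noise genes are
#' Normal(0, sigma) identically across classes; each planted informative
#' gene gets class-specific means spaced `effect` expression units apart
#' (class-to-mean assignment permuted per gene, so multi-class structure is
#' not symmetric across genes). Optional blocks share a latent factor
#' giving within-block pairwise correlation `block_rho`.
#'
#' @param n_classes Number of classes k >= 2 (default 2).
#' @param n_per_class Samples per class (default 30).
#' @param n_genes Total genes (default 200).
#' @param n_informative Planted informative genes (default 4).
#' @param effect Between-class mean shift, in units of `sigma` times 1
#'   (expression units; default 3, a strong microarray-like marker).
#' @param sigma Within-class standard deviation (default 1).
#' @param block_size,block_rho Optional correlated-block structure: genes
#'   are grouped into consecutive blocks of `block_size` sharing pairwise
#'   correlation `block_rho` in `[0, 1)` (default: no blocks).
#' @param heavy_tails If `TRUE`, noise is log-normal-tailed (sign-symmetric
#'   exponentiated normal, rescaled to `sigma`) instead of Gaussian, for
#'   robustness checks.
#' @param seed Integer seed; the dataset is a pure function of the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_classes = 2, n_per_class = 30, n_genes = 200,
                       n_informative = 4, effect = 3, sigma = 1,
                       block_size = NULL, block_rho = 0,
                       heavy_tails = FALSE, seed = 1) {
  if (n_classes < 2) stop("need at least 2 classes")
  if (n_informative > n_genes) stop("n_informative cannot exceed n_genes")
  if (effect < 0) stop("effect must be >= 0")
  if (sigma <= 0) stop("sigma must be positive")
  if (!is.null(block_size) && block_size > n_genes)
    stop("block_size cannot exceed n_genes")
  if (block_rho < 0 || block_rho >= 1) stop("block_rho must be in [0, 1)")
  structure(list(n_classes = as.integer(n_classes),
                 n_per_class = as.integer(n_per_class),
                 n_genes = as.integer(n_genes),
                 n_informative = as.integer(n_informative),
                 effect = effect, sigma = sigma,
                 block_size = block_size, block_rho = block_rho,
                 heavy_tails = heavy_tails, seed = as.integer(seed)),
            class = "sim_config")
}

sim_noise <- function(n, sigma, heavy) {
  if (!heavy) return(stats::rnorm(n, 0, sigma))
  z <- stats::rnorm(n)
  x <- sign(z) * (exp(abs(z)) - 1)
  x / stats::sd(x) * sigma
}

#' Simulate a labeled expression dataset
#'
#' @param config A [sim_config()].
#' @return A `sim_result`: list with `dataset` (an [expression_dataset()]),
#'   `truth` (data.frame of planted gene ids and their per-class means) and
#'   `config`.
#' @export
simulate_expression <- function(config) {
  with_seed(config$seed, {
    k <- config$n_classes
    m <- k * config$n_per_class
    n <- config$n_genes
    labels <- factor(rep(paste0("class", seq_len(k)), each = config$n_per_class))
    x <- matrix(sim_noise(m * n, config$sigma, config$heavy_tails), m, n)
    if (!is.null(config$block_size) && config$block_rho > 0) {
      bs <- config$block_size
      rho <- config$block_rho
      starts <- seq(1, n, by = bs)
      for (s in starts) {
        cols <- s:min(s + bs - 1, n)
        latent <- stats::rnorm(m, 0, config$sigma)
        x[, cols] <- sqrt(rho) * latent +
          sqrt(1 - rho) * x[, cols, drop = FALSE]
      }
    }
    gene_ids <- sprintf("g%04d", seq_len(n))
    info <- seq_len(config$n_informative)
    truth_means <- matrix(0, nrow = config$n_informative, ncol = k,
                          dimnames = list(gene_ids[info],
                                          paste0("class", seq_len(k))))
    for (j in info) {
      perm <- sample.int(k)            # per-gene class-to-mean assignment
      mu <- config$effect * (perm - 1)
      truth_means[j, ] <- mu
      x[, j] <- x[, j] + mu[as.integer(labels)]
    }
    ds <- expression_dataset(x, sprintf("s%03d", seq_len(m)), gene_ids, labels)
    structure(list(dataset = ds,
                   truth = data.frame(gene_id = gene_ids[info],
                                      truth_means,
                                      stringsAsFactors = FALSE),
                   config = config),
              class = "sim_result")
  })
}

#' Simulate a cross-platform companion dataset
#'
#' Draws new independent samples from the same class-conditional model as a
#' simulated source dataset, keeps a random fraction of the gene ids (the
#' "shared" genes measurable on both platforms), applies an affine platform
#' distortion x * scale + shift, and appends platform-only noise genes with
#' fresh ids.
#'
#' @param src A `sim_result` from [simulate_expression()].
#' @param shared_fraction Fraction of source genes retained, in (0, 1].
#' @param scale,shift Affine platform distortion (defaults 1, 0).
#' @param n_extra_genes Platform-only noise genes appended (default 0).
#' @param n_per_class Samples per class (default: as the source).
#' @param seed Integer seed (independent of the source seed).
#' @return An [expression_dataset()] for the companion platform.
#' @export
simulate_cross_platform <- function(src, shared_fraction = 1, scale = 1,
                                    shift = 0, n_extra_genes = 0,
                                    n_per_class = NULL, seed = 1) {
  cfg <- src$config
  if (shared_fraction <= 0 || shared_fraction > 1)
    stop("shared_fraction must be in (0, 1]")
  n_shared <- max(1L, floor(shared_fraction * cfg$n_genes))
  if (is.null(n_per_class)) n_per_class <- cfg$n_per_class
  with_seed(seed, {
    k <- cfg$n_classes
    m <- k * n_per_class
    keep <- sort(sample.int(cfg$n_genes, n_shared))
    gene_ids <- src$dataset$gene_ids[keep]
    labels <- factor(rep(paste0("class", seq_len(k)), each = n_per_class))
    x <- matrix(sim_noise(m * n_shared, cfg$sigma, cfg$heavy_tails),
                m, n_shared)
    # planted genes that fall in the shared set keep their class means
    info_ids <- src$truth$gene_id
    for (j in seq_len(n_shared)) {
      ti <- match(gene_ids[j], info_ids)
      if (!is.na(ti)) {
        mu <- as.numeric(src$truth[ti, -1])
        x[, j] <- x[, j] + mu[as.integer(labels)]
      }
    }
    x <- x * scale + shift
    if (n_extra_genes > 0) {
      extra <- matrix(sim_noise(m * n_extra_genes, cfg$sigma,
                                cfg$heavy_tails) * scale + shift,
                      m, n_extra_genes)
      x <- cbind(x, extra)
      gene_ids <- c(gene_ids, sprintf("x%04d", seq_len(n_extra_genes)))
    }
    expression_dataset(x, sprintf("t%03d", seq_len(m)), gene_ids, labels)
  })
}
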